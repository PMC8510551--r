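# Pooled-screen fitness: spacer counting from reads, the relative-fitness
# statistic, and per-well contamination QC.

#' Construct a sample_counts object
#'
#' Per-sample spacer counts plus the unmapped/ambiguous tallies.
#'
#' @param spacer character vector of spacers.
#' @param count nonnegative counts, same length.
#' @param sample_id sample label.
#' @param condition one of `"t0"`, `"uninduced"`, `"induced"`.
#' @param replicate replicate index.
#' @param unmapped,ambiguous read tallies that matched zero / >= 2 spacers.
#' @return object of class `sample_counts`.
#' @export
new_sample_counts <- function(spacer, count, sample_id = "sample",
                              condition = c("t0", "uninduced", "induced"),
                              replicate = 1L, unmapped = 0L, ambiguous = 0L) {
  condition <- match.arg(condition)
  stopifnot(length(spacer) == length(count), all(count >= 0))
  obj <- list(sample_id = sample_id, condition = condition,
              replicate = replicate,
              counts = data.frame(spacer = as.character(spacer),
                                  count = as.numeric(count),
                                  stringsAsFactors = FALSE),
              unmapped = unmapped, ambiguous = ambiguous,
              total_reads = sum(count) + unmapped + ambiguous)
  class(obj) <- "sample_counts"
  obj
}

#' @export
print.sample_counts <- function(x, ...) {
  cat("<sample_counts> ", x$sample_id, " (", x$condition, ")\n", sep = "")
  cat("  spacers: ", nrow(x$counts), ", mapped reads: ", sum(x$counts$count),
      ", unmapped: ", x$unmapped, ", ambiguous: ", x$ambiguous, "\n", sep = "")
  invisible(x)
}

#' Read a spacer library table
#'
#' CSV with columns strain_id, spacer, gene, category. Spacers must be
#' unique 20-nt uppercase ACGT strings; categories must be one of
#' essential, nonessential, control.
#'
#' @param path CSV file path, or a data.frame with the same columns.
#' @return validated library data.frame.
#' @export
read_spacer_library <- function(path) {
  lib <- if (is.data.frame(path)) path
         else utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("strain_id", "spacer", "gene", "category")
  if (!all(req %in% names(lib)))
    stop("library must have columns: ", paste(req, collapse = ", "))
  lib$spacer <- toupper(lib$spacer)
  if (anyDuplicated(lib$spacer)) stop("duplicate spacers in library")
  if (any(nchar(lib$spacer) != 20)) stop("spacers must be exactly 20 nt")
  if (any(grepl("[^ACGT]", lib$spacer))) stop("spacers must be ACGT only")
  bad <- setdiff(unique(lib$category), c("essential", "nonessential", "control"))
  if (length(bad)) stop("unknown category: ", paste(bad, collapse = ", "))
  lib
}

#' Count spacer occurrences in sequencing reads
#'
#' Exact substring matching of each 20-nt library spacer against each read:
#' a read increments exactly one spacer's count when exactly one library
#' spacer occurs within it; reads matching zero or several distinct spacers
#' are tallied as unmapped / ambiguous respectively. No mismatches are
#' tolerated.
#'
#' @param reads a FASTQ path (optionally gzipped), a character vector of
#'   read sequences, or a `Biostrings::DNAStringSet`.
#' @param library spacer library (data.frame or CSV path; see
#'   [read_spacer_library()]).
#' @param sample_id,condition,replicate sample metadata.
#' @return a [sample_counts] object aligned to the library spacer order.
#' @export
count_spacers <- function(reads, library, sample_id = "sample",
                          condition = "t0", replicate = 1L) {
  lib <- read_spacer_library(library)
  if (nrow(lib) == 0) stop("empty spacer library")
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    reads <- Biostrings::readDNAStringSet(reads, format = "fastq")
  }
  if (is.character(reads)) reads <- Biostrings::DNAStringSet(reads)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(lib$spacer))
  hits <- Biostrings::vwhichPDict(pd, reads)
  nhits <- lengths(hits)
  mapped <- nhits == 1L
  counts <- tabulate(unlist(hits[mapped]), nbins = nrow(lib))
  new_sample_counts(lib$spacer, counts, sample_id = sample_id,
                    condition = match.arg(condition,
                                          c("t0", "uninduced", "induced")),
                    replicate = replicate,
                    unmapped = sum(nhits == 0L),
                    ambiguous = sum(nhits > 1L))
}

#' Relative fitness from paired spacer counts
#'
#' For each strain, counts are converted to within-sample frequencies with a
#' pseudocount, the log2 fold change \eqn{L_i = \log_2(f_{end,i}/f_{t0,i})}
#' is normalized by the median log2 fold change of the nontargeting controls
#' and adjusted by the number of doublings D:
#' \deqn{RF_i = 1 + (L_i - \mathrm{median}_{ctrl}(L)) / D.}
#' RF is the strain's number of doublings relative to the controls; the
#' median control has RF exactly 1 and RF is not clamped (negative values
#' mean depletion faster than dilution).
#'
#' @param t0,t_end [sample_counts] for the start and end of the competition.
#' @param library spacer library (see [read_spacer_library()]).
#' @param doublings number of control doublings D (> 0).
#' @param pseudocount added to every count before frequency computation
#'   (default 0.5; 0 is allowed but errors on zero counts).
#' @param condition condition label attached to the result.
#' @return data.frame (class `fitness_result`) with strain_id, gene,
#'   category, condition, replicate, log2fc, rf.
#' @export
relative_fitness <- function(t0, t_end, library, doublings = 15,
                             pseudocount = 0.5, condition = NULL) {
  lib <- read_spacer_library(library)
  stopifnot(doublings > 0, pseudocount >= 0)
  get_f <- function(sc) {
    m <- match(lib$spacer, sc$counts$spacer)
    if (anyNA(m)) stop("sample does not cover the library")
    cnt <- sc$counts$count[m] + pseudocount
    if (any(cnt <= 0)) stop("zero count with pseudocount 0: log2fc undefined")
    cnt / sum(cnt)
  }
  f0 <- get_f(t0)
  f1 <- get_f(t_end)
  L <- log2(f1 / f0)
  ctrl <- lib$category == "control"
  if (!any(ctrl)) stop("no control strains in library")
  rf <- 1 + (L - stats::median(L[ctrl])) / doublings
  out <- data.frame(strain_id = lib$strain_id, gene = lib$gene,
                    category = lib$category,
                    condition = if (is.null(condition)) t_end$condition else condition,
                    replicate = t_end$replicate,
                    log2fc = L, rf = rf, stringsAsFactors = FALSE)
  class(out) <- c("fitness_result", "data.frame")
  out
}

#' Per-well cross-contamination report
#'
#' The contamination fraction is the share of a well's mapped reads carried
#' by the most abundant spacer other than the expected one; wells strictly
#' above the cutoff are called contaminated.
#'
#' @param well_counts [sample_counts] for one arrayed well.
#' @param expected_spacer the spacer the well should contain.
#' @param cutoff contamination-fraction threshold (default 1e-4, strict >).
#' @return one-row data.frame (class `contamination_report`) with well_id,
#'   expected_spacer, major_contaminant_spacer, contaminant_fraction,
#'   contaminated.
#' @export
contamination_report <- function(well_counts, expected_spacer, cutoff = 1e-4) {
  stopifnot(inherits(well_counts, "sample_counts"))
  cnt <- well_counts$counts
  if (!expected_spacer %in% cnt$spacer) stop("expected spacer not in library")
  tot <- sum(cnt$count)
  if (tot <= 0) stop("well has no mapped reads")
  others <- cnt[cnt$spacer != expected_spacer, , drop = FALSE]
  if (nrow(others) == 0 || max(others$count) == 0) {
    major <- NA_character_
    cf <- 0
  } else {
    major <- others$spacer[which.max(others$count)]
    cf <- max(others$count) / tot
  }
  out <- data.frame(well_id = well_counts$sample_id,
                    expected_spacer = expected_spacer,
                    major_contaminant_spacer = major,
                    contaminant_fraction = cf,
                    contaminated = cf > cutoff,
                    stringsAsFactors = FALSE)
  class(out) <- c("contamination_report", "data.frame")
  out
}

#' Average replicate fitness tables
#'
#' Replicates are analyzed separately and RF is combined across replicates
#' by the mean, per strain and condition.
#'
#' @param ... fitness_result data.frames (or a single list of them).
#' @return data.frame with strain_id, gene, category, condition, rf (mean),
#'   n_replicates.
#' @export
combine_fitness_replicates <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1 && is.list(tabs[[1]]) && !is.data.frame(tabs[[1]]))
    tabs <- tabs[[1]]
  all <- do.call(rbind, tabs)
  agg <- stats::aggregate(rf ~ strain_id + gene + category + condition,
                          data = all, FUN = mean)
  n <- stats::aggregate(cbind(n_replicates = rf) ~ strain_id + condition,
                        data = all, FUN = length)
  merge(agg, n, by = c("strain_id", "condition"))
}
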