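# Robust screen-level statistics: median/MAD summaries, >k-SD outlier
# classification, exact hypergeometric enrichment, and outlier-resistant
# linear regression.

#' Robust location/scale summary
#'
#' Location is the median; scale is 1.4826 times the median absolute
#' deviation from the median, which estimates the standard deviation for
#' Gaussian data.
#'
#' @param values numeric vector, n >= 1 (NAs dropped).
#' @return object of class `robust_summary`: list(n, median, robust_sd).
#' @export
robust_summary <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("empty input")
  out <- list(n = length(values), median = stats::median(values),
              robust_sd = stats::mad(values))  # mad() default constant 1.4826
  class(out) <- "robust_summary"
  out
}

#' @export
print.robust_summary <- function(x, ...) {
  cat(sprintf("<robust_summary> n = %d, median = %.4g, robust SD = %.4g\n",
              x$n, x$median, x$robust_sd))
  invisible(x)
}

#' Flag outliers against a robust reference
#'
#' Robust z-scores are (value - reference median) / reference robust SD;
#' values strictly more than k SD from the median are flagged `low` or
#' `high` (the `side` argument restricts which direction is called).
#'
#' @param values numeric vector.
#' @param reference a [robust_summary()] (of the nontargeting controls, or
#'   of all strains, depending on the screen metric).
#' @param k SD multiple (default 3, strict inequality).
#' @param side `"both"`, `"low"` or `"high"`.
#' @param ids optional identifiers for the values.
#' @return data.frame (class `outlier_calls`): id, value, z_robust, flag.
#' @export
call_outliers <- function(values, reference, k = 3,
                          side = c("both", "low", "high"), ids = NULL) {
  side <- match.arg(side)
  stopifnot(inherits(reference, "robust_summary"))
  if (reference$robust_sd <= 0)
    stop("reference robust_sd is 0; outlier z-scores are undefined ",
         "(>= 50% ties at the median) - choose a different reference")
  if (is.null(ids)) ids <- if (!is.null(names(values))) names(values)
                           else as.character(seq_along(values))
  z <- (values - reference$median) / reference$robust_sd
  flag <- rep("normal", length(z))
  if (side %in% c("both", "low")) flag[z < -k] <- "low"
  if (side %in% c("both", "high")) flag[z > k] <- "high"
  out <- data.frame(id = ids, value = values, z_robust = z, flag = flag,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("outlier_calls", "data.frame")
  out
}

#' Upper-tail hypergeometric enrichment test
#'
#' Probability of selecting at least `k` members of a `K`-member category
#' when drawing `n` items without replacement from a population of `N`.
#'
#' @param N population size.
#' @param K category size.
#' @param n number selected.
#' @param k selected items in the category.
#' @return object of class `enrichment_test`: list(N, K, n, k, p_value).
#' @export
hypergeom_enrichment <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(K, n) ||
      k < max(0, n - (N - K)))
    stop("inconsistent counts for hypergeometric test")
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- list(N = N, K = K, n = n, k = k, p_value = p)
  class(out) <- "enrichment_test"
  out
}

#' @export
print.enrichment_test <- function(x, ...) {
  cat(sprintf("<enrichment_test> %d/%d selected in a %d/%d category: P(X >= %d) = %.3g\n",
              x$k, x$n, x$K, x$N, x$k, x$p_value))
  invisible(x)
}

# repeated-median slope/intercept: high-breakdown deterministic start
repeated_median_line <- function(x, y) {
  n <- length(x)
  slopes <- vapply(seq_len(n), function(i) {
    dx <- x[-i] - x[i]
    dy <- y[-i] - y[i]
    ok <- abs(dx) > 1e-12
    if (!any(ok)) return(NA_real_)
    stats::median(dy[ok] / dx[ok])
  }, numeric(1))
  b <- stats::median(slopes, na.rm = TRUE)
  a <- stats::median(y - b * x)
  c(intercept = a, slope = b)
}

#' Outlier-resistant linear regression
#'
#' Robust line fit: a deterministic high-breakdown repeated-median start,
#' refined by iteratively reweighted least squares with the Tukey bisquare
#' loss (c = 4.685) at a fixed robust residual scale (1.4826 x MAD of the
#' starting residuals) — an MM-type estimator. The Pearson correlation of
#' the raw pairs and its two-sided p-value are reported alongside, since
#' both are standard companions of the fitted line.
#'
#' @param x,y numeric vectors, n >= 3.
#' @param c_tuning bisquare tuning constant.
#' @param max_iter,tol IRLS controls.
#' @return object of class `robust_fit`: list(slope, intercept, pearson_r,
#'   p_value, n, iterations).
#' @export
fit_robust <- function(x, y, c_tuning = 4.685, max_iter = 100, tol = 1e-10) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("zero variance in x")
  start <- repeated_median_line(x, y)
  a <- start["intercept"]; b <- start["slope"]
  res <- y - a - b * x
  scale <- stats::mad(res, center = 0)
  if (scale <= 0) scale <- stats::sd(res)
  if (scale <= 0) scale <- 1e-12  # exact fit; weights all 1
  for (it in seq_len(max_iter)) {
    u <- (y - a - b * x) / (c_tuning * scale)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w) < 3 || sum(w * (x - sum(w * x) / sum(w))^2) <= 0) break
    xw <- sum(w * x) / sum(w)
    yw <- sum(w * y) / sum(w)
    b_new <- sum(w * (x - xw) * (y - yw)) / sum(w * (x - xw)^2)
    a_new <- yw - b_new * xw
    delta <- max(abs(b_new - b), abs(a_new - a))
    a <- a_new; b <- b_new
    if (delta < tol * (1 + abs(b))) break
  }
  ct <- stats::cor.test(x, y)
  out <- list(slope = unname(b), intercept = unname(a),
              pearson_r = unname(ct$estimate), p_value = ct$p.value,
              n = n, iterations = it)
  class(out) <- "robust_fit"
  out
}

#' @export
print.robust_fit <- function(x, ...) {
  cat(sprintf("<robust_fit> y = %.4g + %.4g x (n = %d); Pearson r = %.3f, p = %.3g\n",
              x$intercept, x$slope, x$n, x$pearson_r, x$p_value))
  invisible(x)
}

#' Screen-level classification of strain phenotypes
#'
#' Applies the robust >k-SD classifiers used for screen calls:
#' \itemize{
#'   \item fitness: strains more than k SD \emph{below} the nontargeting
#'     controls (the reference is the control RF distribution), counted per
#'     annotation category;
#'   \item lag: strains more than k SD above the median of all strains;
#'   \item morphology: strains more than k SD longer and/or wider than the
#'     median of all strains (per condition), plus the joint long-and-wide
#'     count;
#'   \item enrichment: upper-tail hypergeometric test of each annotation
#'     group among the flagged wide strains.
#' }
#'
#' @param fitness data.frame with strain_id, condition, rf (e.g. from
#'   [combine_fitness_replicates()]).
#' @param growth optional data.frame with strain_id and lag_norm.
#' @param morphology optional data.frame with strain_id, condition and
#'   length/width columns (corrected_length/corrected_width when present,
#'   otherwise median_length/median_width).
#' @param annotations data.frame with strain_id, category (essential /
#'   nonessential / control), optionally `group` for enrichment.
#' @param k SD multiple for every call (default 3).
#' @return object of class `screen_classification`: list of call tables,
#'   a per-condition summary data.frame, and enrichment results.
#' @export
classify_screen <- function(fitness, growth = NULL, morphology = NULL,
                            annotations, k = 3) {
  stopifnot(all(c("strain_id", "category") %in% names(annotations)))
  res <- list(k = k)

  # fitness: reference = nontargeting controls, one-sided low
  fit_calls <- NULL
  summary_rows <- list()
  if (!is.null(fitness)) {
    fitness <- merge(fitness, annotations[c("strain_id", "category")],
                     by = "strain_id", suffixes = c("", ".ann"))
    if ("category.ann" %in% names(fitness)) fitness$category <- fitness$category.ann
    for (cond in unique(fitness$condition)) {
      d <- fitness[fitness$condition == cond, ]
      ctrl <- d$rf[d$category == "control"]
      if (length(ctrl) == 0) stop("no control strains for condition ", cond)
      ref <- robust_summary(ctrl)
      calls <- call_outliers(d$rf, ref, k = k, side = "low", ids = d$strain_id)
      calls$condition <- cond
      calls$category <- d$category
      fit_calls <- rbind(fit_calls, calls)
      for (cat_ in c("essential", "nonessential")) {
        dc <- calls[calls$category == cat_, ]
        summary_rows[[length(summary_rows) + 1L]] <- data.frame(
          condition = cond, metric = "fitness_defect", category = cat_,
          n_strains = nrow(dc), n_flagged = sum(dc$flag == "low"),
          median_value = stats::median(dc$value), stringsAsFactors = FALSE)
      }
    }
  }
  res$fitness_calls <- fit_calls

  # lag: reference = all strains, one-sided high
  if (!is.null(growth) && "lag_norm" %in% names(growth)) {
    ref <- robust_summary(growth$lag_norm)
    lag_calls <- call_outliers(growth$lag_norm, ref, k = k, side = "high",
                               ids = growth$strain_id)
    res$lag_calls <- lag_calls
    summary_rows[[length(summary_rows) + 1L]] <- data.frame(
      condition = "uninduced", metric = "long_lag", category = "all",
      n_strains = nrow(lag_calls), n_flagged = sum(lag_calls$flag == "high"),
      median_value = stats::median(growth$lag_norm), stringsAsFactors = FALSE)
  }

  # morphology: reference = all strains, one-sided high per dimension
  enr <- NULL
  if (!is.null(morphology)) {
    len_col <- if ("corrected_length" %in% names(morphology)) "corrected_length" else "median_length"
    wid_col <- if ("corrected_width" %in% names(morphology)) "corrected_width" else "median_width"
    if (!"condition" %in% names(morphology)) morphology$condition <- "uninduced"
    morph_calls <- NULL
    for (cond in unique(morphology$condition)) {
      d <- morphology[morphology$condition == cond &
                        !is.na(morphology[[len_col]]), ]
      ref_l <- robust_summary(d[[len_col]])
      ref_w <- robust_summary(d[[wid_col]])
      if (ref_l$robust_sd <= 0 || ref_w$robust_sd <= 0) {
        warning("degenerate morphology reference (robust SD 0) for ",
                cond, "; skipping shape calls")
        next
      }
      lc <- call_outliers(d[[len_col]], ref_l, k = k,
                          side = "high", ids = d$strain_id)
      wc <- call_outliers(d[[wid_col]], ref_w, k = k,
                          side = "high", ids = d$strain_id)
      mc <- data.frame(strain_id = d$strain_id, condition = cond,
                       length = d[[len_col]], width = d[[wid_col]],
                       z_length = lc$z_robust, z_width = wc$z_robust,
                       long = lc$flag == "high", wide = wc$flag == "high",
                       stringsAsFactors = FALSE)
      morph_calls <- rbind(morph_calls, mc)
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        condition = cond, metric = "morphology", category = "all",
        n_strains = nrow(mc),
        n_flagged = sum(mc$long | mc$wide),
        median_value = stats::median(mc$width), stringsAsFactors = FALSE)
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        condition = cond, metric = "long_and_wide", category = "all",
        n_strains = nrow(mc), n_flagged = sum(mc$long & mc$wide),
        median_value = NA_real_, stringsAsFactors = FALSE)

      # enrichment of annotation groups among wide strains
      if ("group" %in% names(annotations)) {
        ann <- annotations[annotations$strain_id %in% mc$strain_id, ]
        wide_ids <- mc$strain_id[mc$wide]
        for (g in setdiff(unique(ann$group), c(NA, ""))) {
          gk <- sum(ann$strain_id[ann$group == g] %in% wide_ids)
          test <- hypergeom_enrichment(N = nrow(ann),
                                       K = sum(ann$group == g),
                                       n = length(wide_ids), k = gk)
          enr <- rbind(enr, data.frame(condition = cond, group = g,
                                       N = test$N, K = test$K, n = test$n,
                                       k = test$k, p_value = test$p_value,
                                       stringsAsFactors = FALSE))
        }
      }
    }
    res$morphology_calls <- morph_calls
  }
  res$enrichment <- enr
  res$summary <- do.call(rbind, summary_rows)
  class(res) <- "screen_classification"
  res
}

#' @export
print.screen_classification <- function(x, ...) {
  cat("<screen_classification> (", x$k, "-SD robust calls)\n", sep = "")
  if (!is.null(x$summary)) {
    for (i in seq_len(nrow(x$summary))) {
      s <- x$summary[i, ]
      cat(sprintf("  %-10s %-15s %-12s %d/%d flagged", s$condition, s$metric,
                  s$category, s$n_flagged, s$n_strains))
      if (!is.na(s$median_value)) cat(sprintf(" (median %.3g)", s$median_value))
      cat("\n")
    }
  }
  if (!is.null(x$enrichment)) {
    cat("  enrichment among wide strains:\n")
    for (i in seq_len(nrow(x$enrichment))) {
      e <- x$enrichment[i, ]
      cat(sprintf("    %-10s %-20s %d/%d vs %d/%d: p = %.3g\n", e$condition,
                  e$group, e$k, e$n, e$K, e$N, e$p_value))
    }
  }
  invisible(x)
}
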