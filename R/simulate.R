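# Synthetic-data generators. Each simulator is a forward model of the
# statistical structure the analysis assumes, and returns its ground truth
# alongside the data so every downstream stage can be tested by parameter
# recovery, without any external data.

#' Configuration for a simulated pooled CRISPRi screen
#'
#' The pooled competition runs for `doublings` control doublings; a strain
#' with true per-control-doubling fitness \eqn{d_i} (in doublings) grows from
#' initial abundance \eqn{a_i} to \eqn{a_i 2^{d_i}}. Nontargeting controls
#' have \eqn{d_i = D}. Reads are multinomial draws from the final (and
#' initial) relative abundances at the requested depth; a Dirichlet
#' overdispersion parameter is available but off by default.
#'
#' @param n_essential,n_nonessential number of targeting strains per class.
#' @param n_controls number of nontargeting control strains (the screen this
#'   emulates carried about 50).
#' @param doublings number of control doublings D between the two samples.
#' @param read_depth reads per sample; `Inf` disables sampling noise and
#'   returns expected (continuous) counts at depth 1e8.
#' @param true_fitness optional vector of per-strain doubling numbers
#'   \eqn{d_i} for the targeting strains (recycled); by default essential
#'   strains draw \eqn{d_i} from a left-skewed distribution and
#'   nonessential strains sit near D.
#' @param overdispersion Dirichlet concentration multiplier; `Inf` (default)
#'   means pure multinomial sampling.
#' @param seed integer seed; fixing it fixes every generated artifact.
#' @return object of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_essential = 282, n_nonessential = 187,
                              n_controls = 50, doublings = 15,
                              read_depth = 1e6, true_fitness = NULL,
                              overdispersion = Inf, seed = 1) {
  stopifnot(n_controls >= 1, doublings > 0)
  if (!is.infinite(read_depth) && read_depth <= 0) stop("read_depth must be > 0")
  cfg <- list(n_essential = n_essential, n_nonessential = n_nonessential,
              n_controls = n_controls, doublings = doublings,
              read_depth = read_depth, true_fitness = true_fitness,
              overdispersion = overdispersion, seed = seed)
  class(cfg) <- "screen_sim_config"
  cfg
}

random_spacers <- function(n) {
  # unique 20-nt ACGT barcodes
  out <- character(0)
  while (length(out) < n) {
    new <- vapply(seq_len(n - length(out)), function(i)
      paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = ""),
      character(1))
    out <- unique(c(out, new))
  }
  out[seq_len(n)]
}

#' Simulate a pooled fitness screen
#'
#' Forward model for spacer-count deep sequencing before and after a pooled
#' competition: initial abundances are lognormal, final abundances are
#' \eqn{a_i 2^{d_i}}, and counts are multinomial at the configured depth.
#'
#' @param config a [screen_sim_config()].
#' @return list with elements `library` (spacer library data.frame),
#'   `t0` and `t_end` ([sample_counts] objects), and `truth` (data.frame with
#'   per-strain `d_i` and expected relative fitness `rf_true = d_i / D`).
#' @export
simulate_pooled_screen <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  set.seed(config$seed)
  n_t <- config$n_essential + config$n_nonessential
  n <- n_t + config$n_controls
  D <- config$doublings

  category <- c(rep("essential", config$n_essential),
                rep("nonessential", config$n_nonessential),
                rep("control", config$n_controls))
  strain_id <- sprintf("S%04d", seq_len(n))
  gene <- ifelse(category == "control", "none", sprintf("gene%04d", seq_len(n)))

  if (is.null(config$true_fitness)) {
    d <- numeric(n_t)
    ess <- seq_len(config$n_essential)
    # essential knockdowns: mostly mild defects, a left tail of strong ones
    d[ess] <- D * pmin(1.05, 1 - stats::rgamma(config$n_essential, 0.6, 12))
    d[-ess] <- D * stats::rnorm(config$n_nonessential, 1, 0.01)
  } else {
    d <- rep_len(config$true_fitness, n_t)
  }
  d <- c(d, rep(D, config$n_controls))

  lib <- data.frame(strain_id = strain_id, spacer = random_spacers(n),
                    gene = gene, category = category,
                    stringsAsFactors = FALSE)

  a0 <- stats::rlnorm(n, meanlog = 0, sdlog = 0.3)
  a_end <- a0 * 2^d
  draw <- function(weights, sample_id, condition) {
    p <- weights / sum(weights)
    if (is.infinite(config$read_depth)) {
      counts <- p * 1e8
    } else if (is.finite(config$overdispersion)) {
      g <- stats::rgamma(length(p), shape = p * config$overdispersion, rate = 1)
      counts <- as.vector(stats::rmultinom(1, config$read_depth, g / sum(g)))
    } else {
      counts <- as.vector(stats::rmultinom(1, config$read_depth, p))
    }
    new_sample_counts(lib$spacer, counts, sample_id = sample_id,
                      condition = condition)
  }
  t0 <- draw(a0, "t0", "t0")
  t_end <- draw(a_end, "t_end", "induced")
  truth <- data.frame(strain_id = strain_id, category = category,
                      d_i = d, rf_true = d / D, stringsAsFactors = FALSE)
  list(library = lib, t0 = t0, t_end = t_end, truth = truth)
}

#' Write spacer-bearing reads as FASTQ
#'
#' Emits `counts[i]` reads per spacer, each embedding the 20-nt spacer in a
#' constant vector scaffold, suitable for exercising [count_spacers()].
#'
#' @param counts a [sample_counts] object (counts are rounded).
#' @param path output FASTQ path.
#' @param scaffold_5p,scaffold_3p constant sequence flanking the spacer.
#' @return `path`, invisibly.
#' @export
write_screen_fastq <- function(counts, path,
                               scaffold_5p = "GTTTTAGAGCTAGAAATAGCAAG",
                               scaffold_3p = "TTAAAATAAGGCTAGTCCGTTATC") {
  stopifnot(inherits(counts, "sample_counts"))
  n <- round(counts$counts$count)
  seqs <- paste0(scaffold_5p, rep(counts$counts$spacer, n), scaffold_3p)
  qual <- strrep("I", nchar(scaffold_5p) + 20L + nchar(scaffold_3p))
  ids <- sprintf("@read%07d", seq_along(seqs))
  writeLines(as.vector(rbind(ids, seqs, "+", qual)), path)
  invisible(path)
}

#' Configuration for simulated plate-reader growth curves
#'
#' OD follows \eqn{OD(t) = OD_0 e^{M(t)} / (1 + OD_0(e^{M(t)}-1)/K)} where
#' \eqn{M(t) = \int_0^t \mu(s) ds} and the instantaneous rate
#' \eqn{\mu(t) = \mu_{max} / (1 + e^{-(t - lag)/\tau})} is a logistic ramp
#' whose half-maximum crossing is exactly at `lag_target`, making the
#' downstream lag definition exactly recoverable. Measurement noise is
#' additive Gaussian.
#'
#' @param mu_max maximum specific growth rate, 1/min.
#' @param lag_target time at which the rate first reaches half its maximum,
#'   minutes.
#' @param od0 inoculation OD600 (default 0.02, a 1:100 dilution of a
#'   saturated overnight culture).
#' @param sample_interval sampling interval, minutes (plate reader default
#'   8.5).
#' @param duration total run length, minutes.
#' @param noise_sd additive OD noise standard deviation.
#' @param carrying_capacity saturation OD (logistic cap; default 2.0, about
#'   the saturating OD600 of a shaken LB microplate culture).
#' @param ramp_tau time constant of the rate ramp, minutes; default half
#'   the sampling interval, a sharp lag exit that keeps the half-maximum
#'   crossing well defined.
#' @param seed integer seed.
#' @export
growth_sim_config <- function(mu_max = 0.03, lag_target = 60, od0 = 0.02,
                              sample_interval = 8.5, duration = 420,
                              noise_sd = 0.002, carrying_capacity = 2.0,
                              ramp_tau = NULL, seed = 1) {
  stopifnot(sample_interval > 0, od0 > 0, all(mu_max >= 0))
  cfg <- list(mu_max = mu_max, lag_target = lag_target, od0 = od0,
              sample_interval = sample_interval, duration = duration,
              noise_sd = noise_sd, carrying_capacity = carrying_capacity,
              ramp_tau = ramp_tau, seed = seed)
  class(cfg) <- "growth_sim_config"
  cfg
}

# closed-form OD for the logistic-ramp, logistic-capped growth model
od_curve_exact <- function(t, mu_max, lag, od0, K, tau) {
  # M(t) = mu_max * tau * [log(1 + e^{(t-lag)/tau}) - log(1 + e^{-lag/tau})]
  log1pexp <- function(z) ifelse(z > 35, z, log1p(exp(z)))
  M <- mu_max * tau * (log1pexp((t - lag) / tau) - log1pexp(-lag / tau))
  od0 * exp(M) / (1 + od0 * (exp(M) - 1) / K)
}

#' Simulate a plate of growth curves
#'
#' @param config a [growth_sim_config()]; `mu_max` and `lag_target` may be
#'   vectors (recycled over wells) to vary truth across the plate.
#' @param n_wells number of wells.
#' @return list with `curves` (long data.frame: well, time_min, od) and
#'   `truth` (well, mu_max, lag).
#' @export
simulate_growth_plate <- function(config, n_wells = 96) {
  stopifnot(inherits(config, "growth_sim_config"))
  if (config$duration < 2 * config$sample_interval)
    stop("duration must cover at least two sampling intervals")
  set.seed(config$seed)
  t <- seq(0, config$duration, by = config$sample_interval)
  mu <- rep_len(config$mu_max, n_wells)
  lag <- rep_len(config$lag_target, n_wells)
  tau <- config$ramp_tau
  well <- sprintf("W%03d", seq_len(n_wells))
  curves <- do.call(rbind, lapply(seq_len(n_wells), function(i) {
    tau_i <- if (is.null(tau)) config$sample_interval / 2 else tau
    od <- od_curve_exact(t, mu[i], lag[i], config$od0,
                         config$carrying_capacity, tau_i)
    od <- od + stats::rnorm(length(t), 0, config$noise_sd)
    data.frame(well = well[i], time_min = t, od = od,
               stringsAsFactors = FALSE)
  }))
  list(curves = curves,
       truth = data.frame(well = well, mu_max = mu, lag = lag,
                          stringsAsFactors = FALSE))
}

#' Configuration for a simulated cell population
#'
#' Cells are spherocylinders with lognormal-ish (here: truncated normal)
#' length and width distributions; per-plate additive offsets emulate
#' plate-to-plate imaging bias. Defaults emulate exponentially growing
#' E. coli in rich medium (length ~3 um CV ~0.2; width ~1 um CV ~0.06).
#'
#' @param n_cells cells to generate.
#' @param length_mean,length_sd,width_mean,width_sd population parameters,
#'   micrometres.
#' @param contour_points vertices per contour (>= 16).
#' @param plate_offsets named list: per-plate c(length, width) additive
#'   shifts in micrometres, e.g. `list(A = c(0, 0), B = c(0, 0.2))`; cells
#'   are assigned to plates round-robin.
#' @param pixel_size micrometres per pixel for optional raster masks
#'   (default 0.065, a typical 100x camera scale).
#' @param seed integer seed.
#' @export
cell_sim_config <- function(n_cells = 500, length_mean = 3, length_sd = 0.6,
                            width_mean = 1, width_sd = 0.06,
                            contour_points = 64, plate_offsets = list(A = c(0, 0)),
                            pixel_size = 0.065, seed = 1) {
  stopifnot(contour_points >= 16, n_cells >= 1, width_mean > 0)
  cfg <- list(n_cells = n_cells, length_mean = length_mean,
              length_sd = length_sd, width_mean = width_mean,
              width_sd = width_sd, contour_points = contour_points,
              plate_offsets = plate_offsets, pixel_size = pixel_size,
              seed = seed)
  class(cfg) <- "cell_sim_config"
  cfg
}

#' Simulate a population of rod-shaped cells
#'
#' Nonpositive or non-rod draws (width <= 0, or length < 1.2 width) are
#' resampled (documented behaviour; an error is raised if 1000 attempts per
#' cell are exhausted).
#'
#' @param config a [cell_sim_config()].
#' @param masks if TRUE, also return rasterized binary masks.
#' @return list with `contours` (list of contour matrices, named by cell id),
#'   `cells` (data.frame cell_id, plate, length_um, width_um), `offsets`
#'   (per-plate truth), and optionally `masks`.
#' @export
simulate_cell_population <- function(config, masks = FALSE) {
  stopifnot(inherits(config, "cell_sim_config"))
  set.seed(config$seed)
  n <- config$n_cells
  plates <- names(config$plate_offsets)
  plate <- rep_len(plates, n)

  draw_dims <- function(k, off) {
    L <- W <- numeric(k)
    for (i in seq_len(k)) {
      for (attempt in 1:1000) {
        li <- stats::rnorm(1, config$length_mean, config$length_sd) + off[1]
        wi <- stats::rnorm(1, config$width_mean, config$width_sd) + off[2]
        if (wi > 0 && li >= 1.2 * wi) { L[i] <- li; W[i] <- wi; break }
        if (attempt == 1000) stop("width distribution admits no valid draws")
      }
    }
    cbind(L, W)
  }
  dims <- matrix(0, n, 2)
  for (p in plates) {
    idx <- which(plate == p)
    dims[idx, ] <- draw_dims(length(idx), config$plate_offsets[[p]])
  }
  angle <- stats::runif(n, 0, pi)
  centers <- cbind(stats::runif(n, 0, 50), stats::runif(n, 0, 50))
  ids <- sprintf("cell%04d", seq_len(n))
  contours <- lapply(seq_len(n), function(i)
    spherocylinder_contour(dims[i, 1], dims[i, 2], config$contour_points,
                           center = centers[i, ], angle = angle[i]))
  names(contours) <- ids
  out <- list(
    contours = contours,
    cells = data.frame(cell_id = ids, plate = plate,
                       length_um = dims[, 1], width_um = dims[, 2],
                       stringsAsFactors = FALSE),
    offsets = data.frame(plate = plates,
                         length_offset = vapply(config$plate_offsets, `[`, 0, 1),
                         width_offset = vapply(config$plate_offsets, `[`, 0, 2),
                         stringsAsFactors = FALSE))
  if (masks) {
    out$masks <- lapply(contours, rasterize_polygon,
                        pixel_size = config$pixel_size)
  }
  out
}

#' Simulate a single-cell time-lapse track
#'
#' A spherocylindrical cell elongates at constant width so that its volume
#' follows \eqn{V(t) = V_0 e^{g t}} (exponential mode) or
#' \eqn{V(t) = V_0 + c t} (linear mode, with `c = g * V0` at t = 0).
#'
#' @param growth_rate g, 1/min.
#' @param frames number of frames (>= 3).
#' @param interval minutes between frames.
#' @param width constant cell width, micrometres.
#' @param length0 initial cell length, micrometres.
#' @param mode `"exponential"` or `"linear"` volume growth.
#' @param contour_points vertices per frame contour.
#' @return list with `contours` (per-frame list), `track` (data.frame frame,
#'   time_min, volume_true), and `growth_rate`.
#' @export
simulate_time_lapse <- function(growth_rate, frames = 20, interval = 2,
                                width = 1, length0 = 3,
                                mode = c("exponential", "linear"),
                                contour_points = 128) {
  stopifnot(frames >= 3)
  mode <- match.arg(mode)
  r <- width / 2
  vol_of_len <- function(L) pi * r^2 * (L - width) + (4 / 3) * pi * r^3
  len_of_vol <- function(V) (V - (4 / 3) * pi * r^3) / (pi * r^2) + width
  t <- (seq_len(frames) - 1) * interval
  V0 <- vol_of_len(length0)
  V <- if (mode == "exponential") V0 * exp(growth_rate * t)
       else V0 + growth_rate * V0 * t
  L <- len_of_vol(V)
  contours <- lapply(L, spherocylinder_contour, width = width,
                     n_points = contour_points)
  list(contours = contours,
       track = data.frame(frame = seq_len(frames), time_min = t,
                          volume_true = V),
       growth_rate = growth_rate)
}

#' Mix well counts to emulate cross-contamination
#'
#' Each output well's expected reads are a mixture of the source wells'
#' reads according to the mixing matrix (rows = destination wells, columns =
#' source wells, rows summing to 1).
#'
#' @param well_counts list of [sample_counts] objects (one per well, all over
#'   the same spacer universe).
#' @param mixing numeric matrix, `length(well_counts)` square, rows sum to 1.
#' @return list with `mixed` (list of sample_counts) and `truth` (data.frame
#'   well, expected major-contaminant fraction).
#' @export
simulate_contamination <- function(well_counts, mixing) {
  k <- length(well_counts)
  stopifnot(nrow(mixing) == k, ncol(mixing) == k)
  if (any(abs(rowSums(mixing) - 1) > 1e-8)) stop("mixing rows must sum to 1")
  spacers <- well_counts[[1]]$counts$spacer
  mat <- vapply(well_counts, function(w) w$counts$count, numeric(length(spacers)))
  mixed_mat <- mat %*% t(mixing)
  wells <- names(well_counts)
  if (is.null(wells)) wells <- sprintf("well%02d", seq_len(k))
  mixed <- lapply(seq_len(k), function(j)
    new_sample_counts(spacers, mixed_mat[, j], sample_id = wells[j],
                      condition = "t0"))
  names(mixed) <- wells
  # expected major-contaminant fraction: largest off-diagonal source share
  frac <- vapply(seq_len(k), function(j) {
    tot <- colSums(mat)
    contrib <- mixing[j, ] * tot
    own <- contrib[j]
    if (k == 1) 0 else max(contrib[-j]) / sum(contrib)
  }, numeric(1))
  list(mixed = mixed,
       truth = data.frame(well = wells, major_fraction = frac,
                          stringsAsFactors = FALSE))
}
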