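# Plate-reader growth-curve features: maximum specific growth rate and lag
# time from OD600 time series, with wild-type normalization matched on
# starting OD.

#' Centered moving-average smoothing
#'
#' At the edges the window shrinks symmetrically so the output has the same
#' length as the input and remains centered.
#'
#' @param x numeric series.
#' @param window odd window size >= 1.
#' @return smoothed series, same length as `x`.
#' @export
smooth_ma <- function(x, window = 5) {
  n <- length(x)
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  if (window > n) stop("window larger than series")
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  out <- numeric(n)
  for (i in seq_len(n)) {
    hi <- min(h, i - 1L, n - i)
    out[i] <- (cs[i + hi + 1L] - cs[i - hi]) / (2L * hi + 1L)
  }
  out
}

#' Extract growth features from one OD curve
#'
#' The instantaneous growth rate is the slope of ln(OD) with respect to
#' time: ln(OD) is smoothed with a centered moving average (window 5 by
#' default) and differentiated by central differences (one-sided at the
#' endpoints). The maximum growth rate is the largest instantaneous rate;
#' the lag time is the first time the rate reaches half of that maximum,
#' linearly interpolated between samples.
#'
#' @param times sampling times, minutes, strictly increasing.
#' @param od OD600 values, same length.
#' @param window moving-average window (odd).
#' @param blank optional blank OD subtracted before analysis.
#' @param od_floor OD values below this are floored before taking logs
#'   (guards against log of nonpositive noise).
#' @param smooth_log if TRUE (default) smoothing is applied to ln(OD);
#'   if FALSE, to OD before the log.
#' @return object of class `growth_features`: list with mu_max (1/min),
#'   lag (min), od_start, and the rate series.
#' @export
growth_features <- function(times, od, window = 5, blank = 0,
                            od_floor = 1e-4, smooth_log = TRUE) {
  stopifnot(length(times) == length(od), length(od) >= 2 * window)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  od_start <- od[1]
  odc <- pmax(od - blank, od_floor)
  if (any(odc <= 0)) stop("nonpositive OD after flooring")
  lod <- if (smooth_log) smooth_ma(log(odc), window)
         else log(pmax(smooth_ma(odc, window), od_floor))
  n <- length(lod)
  rate <- numeric(n)
  rate[1] <- (lod[2] - lod[1]) / (times[2] - times[1])
  rate[n] <- (lod[n] - lod[n - 1]) / (times[n] - times[n - 1])
  mid <- 2:(n - 1)
  rate[mid] <- (lod[mid + 1] - lod[mid - 1]) / (times[mid + 1] - times[mid - 1])
  mu_max <- max(rate)
  half <- mu_max / 2
  i <- which(rate >= half)[1]
  lag <- if (i == 1) times[1] else {
    t0 <- times[i - 1]; t1 <- times[i]
    r0 <- rate[i - 1]; r1 <- rate[i]
    t0 + (half - r0) / (r1 - r0) * (t1 - t0)
  }
  out <- list(mu_max = mu_max, lag = lag, od_start = od_start,
              times = times, rate = rate)
  class(out) <- "growth_features"
  out
}

#' @export
print.growth_features <- function(x, ...) {
  cat(sprintf("<growth_features> mu_max = %.4f /min, lag = %.1f min, od_start = %.4f\n",
              x$mu_max, x$lag, x$od_start))
  invisible(x)
}

#' Normalize growth features against matched wild-type replicates
#'
#' Selects the k wild-type wells whose starting OD is closest to the
#' strain's (ties broken by well order) and divides the strain's maximum
#' growth rate and lag by the medians of those wells (`mode = "ratio"`), or
#' subtracts them (`mode = "difference"`).
#'
#' @param features a [growth_features] object (or a list with mu_max, lag,
#'   od_start).
#' @param wt_features list of [growth_features] for the wild-type plate.
#' @param k number of matched wild-type wells (default 10).
#' @param mode `"ratio"` (default) or `"difference"`.
#' @return `features` with added `mu_norm` and `lag_norm`.
#' @export
normalize_to_wt <- function(features, wt_features, k = 10,
                            mode = c("ratio", "difference")) {
  mode <- match.arg(mode)
  if (length(wt_features) < k) stop("need at least k wild-type wells")
  od_wt <- vapply(wt_features, function(f) f$od_start, numeric(1))
  sel <- order(abs(od_wt - features$od_start))[seq_len(k)]
  mu_ref <- stats::median(vapply(wt_features[sel], function(f) f$mu_max, numeric(1)))
  lag_ref <- stats::median(vapply(wt_features[sel], function(f) f$lag, numeric(1)))
  if (mode == "ratio") {
    features$mu_norm <- features$mu_max / mu_ref
    features$lag_norm <- features$lag / lag_ref
  } else {
    features$mu_norm <- features$mu_max - mu_ref
    features$lag_norm <- features$lag - lag_ref
  }
  features$wt_index <- sel
  features
}

#' Analyze a whole plate of growth curves
#'
#' Convenience wrapper: extracts features for every well of a long-format
#' table and, when a plate map marks wild-type wells, normalizes each
#' strain well against its matched wild-type replicates.
#'
#' @param od_long data.frame with columns well, time_min, od.
#' @param plate_map optional data.frame with columns well, strain, is_wt
#'   (logical); when NULL no normalization is done.
#' @param window,k,mode passed to [growth_features()] / [normalize_to_wt()].
#' @return data.frame: well, strain, od_start, mu_max, lag (+ mu_norm,
#'   lag_norm when normalized).
#' @export
analyze_growth_plate <- function(od_long, plate_map = NULL, window = 5,
                                 k = 10, mode = "ratio") {
  wells <- unique(od_long$well)
  feats <- lapply(wells, function(w) {
    d <- od_long[od_long$well == w, ]
    d <- d[order(d$time_min), ]
    growth_features(d$time_min, d$od, window = window)
  })
  names(feats) <- wells
  tab <- data.frame(well = wells,
                    od_start = vapply(feats, `[[`, 0, "od_start"),
                    mu_max = vapply(feats, `[[`, 0, "mu_max"),
                    lag = vapply(feats, `[[`, 0, "lag"),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(plate_map)) {
    tab$strain <- plate_map$strain[match(tab$well, plate_map$well)]
    wt_wells <- plate_map$well[plate_map$is_wt]
    wt_feats <- feats[as.character(wt_wells[wt_wells %in% wells])]
    if (length(wt_feats) >= k) {
      normed <- lapply(feats, normalize_to_wt, wt_features = wt_feats,
                       k = k, mode = mode)
      tab$mu_norm <- vapply(normed, `[[`, 0, "mu_norm")
      tab$lag_norm <- vapply(normed, `[[`, 0, "lag_norm")
    }
  }
  tab
}
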