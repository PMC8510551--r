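# Strain-level morphology: width-window filtering, robust per-strain
# summaries with the minimum-cell rule, plate-effect correction, single-cell
# instantaneous growth rates, in-contour fluorescence, and segmentation of
# binary masks into contours.

#' Instantaneous single-cell growth rate, 1/V dV/dt
#'
#' Volumes are smoothed with a short centered moving average (window 3 by
#' default), differentiated by central differences (one-sided at the
#' endpoints) and divided by the smoothed volume: the relative rate of
#' volume expansion, comparable to bulk exponential growth rates.
#'
#' @param volumes per-frame cell volumes (cubic micrometres), >= 3 frames.
#' @param interval minutes between frames.
#' @param window smoothing window (odd; 1 disables smoothing).
#' @return numeric rate series (1/min), same length as `volumes`.
#' @export
instantaneous_growth <- function(volumes, interval, window = 3) {
  n <- length(volumes)
  if (n < 3) stop("need at least 3 frames")
  if (any(volumes <= 0)) stop("nonpositive volume")
  v <- smooth_ma(volumes, window)
  dv <- numeric(n)
  dv[1] <- (v[2] - v[1]) / interval
  dv[n] <- (v[n] - v[n - 1]) / interval
  mid <- 2:(n - 1)
  dv[mid] <- (v[mid + 1] - v[mid - 1]) / (2 * interval)
  dv / v
}

#' Measure a time-lapse track of contours
#'
#' @param contours list of per-frame cell contours.
#' @param interval minutes between frames.
#' @param window volume smoothing window for the rate.
#' @param ... passed to [cell_dimensions()].
#' @return data.frame (class `time_lapse_track`): frame, time_min,
#'   length_um, width_um, volume_um3, rate (1/min).
#' @export
measure_time_lapse <- function(contours, interval, window = 3, ...) {
  dims <- lapply(contours, cell_dimensions, ...)
  vol <- vapply(dims, `[[`, 0, "volume")
  out <- data.frame(frame = seq_along(contours),
                    time_min = (seq_along(contours) - 1) * interval,
                    length_um = vapply(dims, `[[`, 0, "length"),
                    width_um = vapply(dims, `[[`, 0, "width"),
                    volume_um3 = vol,
                    rate = instantaneous_growth(vol, interval, window))
  class(out) <- c("time_lapse_track", "data.frame")
  out
}

#' Background-subtracted fluorescence per unit projected area
#'
#' Sums (pixel - background) over pixels whose centers fall inside the
#' contour and divides by the projected cell area (number of enclosed
#' pixels times the pixel area).
#'
#' @param image intensity matrix (rows = y, columns = x; y-down raster).
#' @param contour cell contour in micrometres, same frame as the image.
#' @param background scalar background intensity.
#' @param pixel_size micrometres per pixel (default 1: contour given in
#'   pixel units).
#' @return mean background-subtracted intensity per unit area.
#' @export
cell_fluorescence <- function(image, contour, background = 0, pixel_size = 1) {
  xy <- as.matrix(contour[, 1:2])
  nr <- nrow(image); nc <- ncol(image)
  # restrict the test to the contour's bounding box
  cr <- range(xy[, 1]); rr <- range(xy[, 2])
  cols <- max(1L, floor(cr[1] / pixel_size)):min(nc, ceiling(cr[2] / pixel_size) + 1L)
  rows <- max(1L, floor(rr[1] / pixel_size)):min(nr, ceiling(rr[2] / pixel_size) + 1L)
  cc <- rep(cols, each = length(rows))
  rs <- rep(rows, times = length(cols))
  inside <- points_in_polygon((cc - 0.5) * pixel_size, (rs - 0.5) * pixel_size, xy)
  if (!any(inside)) stop("no pixel centers fall inside the contour")
  px <- image[cbind(rs[inside], cc[inside])]
  sum(px - background) / (sum(inside) * pixel_size^2)
}

#' Filter cells by width and summarize per strain
#'
#' Cells with widths outside [min_width, max_width] (strict elimination of
#' widths below/above the bounds) are removed; strains retaining fewer than
#' `min_cells` cells are flagged `excluded` and report NA medians.
#' Variability is the robust CV: 1.4826 x MAD divided by the median.
#'
#' @param dims data.frame with one row per cell: columns strain_id,
#'   length_um, width_um, and optionally plate and condition.
#' @param min_width,max_width retention bounds, micrometres (defaults 0.6
#'   and 2.0).
#' @param min_cells minimum surviving cells for a strain to be reported
#'   (default 100).
#' @return data.frame (class `strain_morphology`): strain_id (+ plate,
#'   condition if present), n_cells, median_length, median_width, cv_length,
#'   cv_width, excluded.
#' @export
filter_and_summarize <- function(dims, min_width = 0.6, max_width = 2.0,
                                 min_cells = 100) {
  stopifnot(all(c("strain_id", "length_um", "width_um") %in% names(dims)))
  keep <- !(dims$width_um < min_width | dims$width_um > max_width)
  kept <- dims[keep, , drop = FALSE]
  grp_cols <- intersect(c("strain_id", "condition", "plate"), names(dims))
  key_all <- interaction(dims[grp_cols], drop = FALSE)
  groups <- unique(dims[grp_cols])
  key_grp <- interaction(groups[grp_cols], drop = FALSE)
  key_kept <- interaction(kept[grp_cols], drop = FALSE)
  rcv <- function(x) 1.4826 * stats::mad(x, constant = 1) / stats::median(x)
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- kept[key_kept == key_grp[i], , drop = FALSE]
    n <- nrow(g)
    if (n >= min_cells) {
      data.frame(n_cells = n,
                 median_length = stats::median(g$length_um),
                 median_width = stats::median(g$width_um),
                 cv_length = rcv(g$length_um),
                 cv_width = rcv(g$width_um),
                 excluded = FALSE)
    } else {
      data.frame(n_cells = n, median_length = NA_real_,
                 median_width = NA_real_, cv_length = NA_real_,
                 cv_width = NA_real_, excluded = TRUE)
    }
  })
  out <- cbind(groups, do.call(rbind, rows))
  rownames(out) <- NULL
  class(out) <- c("strain_morphology", "data.frame")
  out
}

#' Correct strain morphology summaries for plate effects
#'
#' Median-centering: each strain's median length and width have the median
#' of its plate subtracted and the global median (over all non-excluded
#' strains) added back, independently per dimension. This equalizes plate
#' medians exactly while leaving the global median unchanged.
#'
#' @param summaries a [filter_and_summarize()] result with a `plate` column.
#' @return `summaries` with added corrected_length and corrected_width.
#' @export
plate_correct <- function(summaries) {
  stopifnot("plate" %in% names(summaries))
  ok <- !summaries$excluded
  if (!any(ok)) stop("no non-excluded strains to correct")
  g_len <- stats::median(summaries$median_length[ok])
  g_wid <- stats::median(summaries$median_width[ok])
  summaries$corrected_length <- NA_real_
  summaries$corrected_width <- NA_real_
  for (p in unique(summaries$plate)) {
    i <- summaries$plate == p & ok
    if (!any(i)) stop("plate ", p, " has no usable strains")
    summaries$corrected_length[i] <-
      summaries$median_length[i] - stats::median(summaries$median_length[i]) + g_len
    summaries$corrected_width[i] <-
      summaries$median_width[i] - stats::median(summaries$median_width[i]) + g_wid
  }
  summaries
}

#' Segment a binary mask into subpixel cell contours
#'
#' Extracts iso-0.5 boundaries by marching squares (linear interpolation on
#' the pixel grid), scales them to micrometres, and discards components
#' touching the image border (their boundary lines are not closed).
#'
#' @param mask binary matrix (rows = y, columns = x; y-down raster).
#' @param pixel_size micrometres per pixel.
#' @param min_vertices contours with fewer vertices are dropped.
#' @return list of contour matrices (columns x, y, micrometres).
#' @export
segment_mask <- function(mask, pixel_size = 0.065, min_vertices = 16) {
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  if (!any(m > 0)) return(list())
  # contourLines indexes the first matrix dimension with x; our rows are y
  cl <- grDevices::contourLines(x = (seq_len(nrow(m)) - 0.5),
                                y = (seq_len(ncol(m)) - 0.5),
                                z = m, levels = 0.5)
  out <- list()
  for (cc in cl) {
    yx <- cbind(cc$x, cc$y)   # rows (y), cols (x)
    k <- nrow(yx)
    closed <- k >= 4 && all(abs(yx[1, ] - yx[k, ]) < 1e-9)
    if (!closed) next  # open line: component touches the image border
    xy <- cbind(x = yx[, 2], y = yx[, 1]) * pixel_size
    xy <- drop_closing_vertex(xy)
    if (nrow(xy) < min_vertices) next
    out[[length(out) + 1L]] <- xy
  }
  out
}

#' Measure every cell of a contour collection
#'
#' @param contours named list of contours (one cell each).
#' @param labels optional data.frame keyed by cell_id carrying strain/plate
#'   labels to join onto the result.
#' @param ... passed to [cell_dimensions()].
#' @return data.frame: cell_id, length_um, width_um, area_um2, volume_um3,
#'   method (+ label columns).
#' @export
measure_cells <- function(contours, labels = NULL, ...) {
  ids <- names(contours)
  if (is.null(ids)) ids <- sprintf("cell%04d", seq_along(contours))
  dims <- lapply(contours, cell_dimensions, ...)
  out <- data.frame(cell_id = ids,
                    length_um = vapply(dims, `[[`, 0, "length"),
                    width_um = vapply(dims, `[[`, 0, "width"),
                    area_um2 = vapply(dims, `[[`, 0, "area"),
                    volume_um3 = vapply(dims, `[[`, 0, "volume"),
                    method = vapply(dims, `[[`, "", "method"),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(labels)) out <- merge(out, labels, by = "cell_id", sort = FALSE)
  out
}

#' Read / write contour tables
#'
#' Long-format CSV with columns cell_id, frame, vertex_index, x_um, y_um.
#'
#' @param path CSV path.
#' @return named list of contour matrices (`read_contours`); `path`
#'   invisibly (`write_contours`).
#' @export
read_contours <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("cell_id", "vertex_index", "x_um", "y_um") %in% names(d)))
  d <- d[order(d$cell_id, d$vertex_index), ]
  split_on <- d$cell_id
  lapply(split(d, split_on), function(g) cbind(x = g$x_um, y = g$y_um))
}

#' @param contours named list of contour matrices.
#' @rdname read_contours
#' @export
write_contours <- function(contours, path) {
  ids <- names(contours)
  if (is.null(ids)) ids <- sprintf("cell%04d", seq_along(contours))
  d <- do.call(rbind, lapply(seq_along(contours), function(i) {
    xy <- as.matrix(contours[[i]])
    data.frame(cell_id = ids[i], frame = 1L,
               vertex_index = seq_len(nrow(xy)),
               x_um = xy[, 1], y_um = xy[, 2], stringsAsFactors = FALSE)
  }))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
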