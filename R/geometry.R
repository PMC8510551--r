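# Internal planar-geometry helpers shared by the simulator and the
# morphometrics code. Coordinates are continuous micrometres; raster
# convention is y-down with pixel (r, c) centred at ((c-0.5)*px, (r-0.5)*px).

#' Signed area of a closed polygon (shoelace formula)
#'
#' Positive for counterclockwise vertex order in a y-up frame.
#'
#' @param xy two-column matrix of vertices (closed implicitly; a repeated
#'   final vertex is tolerated).
#' @return signed area.
#' @keywords internal
polygon_signed_area <- function(xy) {
  xy <- drop_closing_vertex(xy)
  x <- xy[, 1]; y <- xy[, 2]
  i2 <- c(seq_len(nrow(xy))[-1], 1L)
  sum(x * y[i2] - x[i2] * y) / 2
}

#' @keywords internal
polygon_area <- function(xy) abs(polygon_signed_area(xy))

# Remove a duplicated closing vertex, if present.
#' @keywords internal
drop_closing_vertex <- function(xy) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n > 1 && all(abs(xy[n, ] - xy[1, ]) < 1e-12)) xy <- xy[-n, , drop = FALSE]
  xy
}

#' Vectorized even-odd point-in-polygon test
#'
#' Crossing-number test; points exactly on an edge may fall on either side
#' (irrelevant at the resolutions used here).
#'
#' @param px,py point coordinates.
#' @param xy polygon vertex matrix.
#' @return logical vector.
#' @keywords internal
points_in_polygon <- function(px, py, xy) {
  xy <- drop_closing_vertex(xy)
  n <- nrow(xy)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xy[i, 1]; yi <- xy[i, 2]
    xj <- xy[j, 1]; yj <- xy[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Cumulative arc length of a polyline
#' @keywords internal
arc_length <- function(xy) {
  d <- sqrt(rowSums(diff(xy)^2))
  c(0, cumsum(d))
}

#' Resample a polyline at equally spaced arc-length positions
#'
#' @param xy polyline vertex matrix.
#' @param n number of output points (endpoints preserved).
#' @keywords internal
resample_polyline <- function(xy, n) {
  s <- arc_length(xy)
  total <- s[length(s)]
  target <- seq(0, total, length.out = n)
  cbind(stats::approx(s, xy[, 1], xout = target, ties = "ordered")$y,
        stats::approx(s, xy[, 2], xout = target, ties = "ordered")$y)
}

#' Build a tube contour around a centerline with semicircular end caps
#'
#' The contour is the boundary of the set of points within radius(s) of the
#' centerline: two offset sides plus semicircular caps whose radii equal the
#' local radius at the centerline endpoints. With a straight centerline and a
#' constant radius this is the standard spherocylinder (rod-cell) outline.
#'
#' @param centerline k x 2 matrix, the midline of the tube (cap centers at
#'   its endpoints; total cell length is the centerline length plus one
#'   diameter for a constant radius).
#' @param radius a single number or a function of arc length s returning the
#'   local half-width.
#' @param n_points approximate total number of contour vertices (>= 16).
#' @return counterclockwise closed contour matrix with columns x, y.
#' @keywords internal
tube_contour <- function(centerline, radius, n_points = 128) {
  stopifnot(n_points >= 16)
  cl <- as.matrix(centerline)
  if (nrow(cl) < 2) stop("centerline needs at least 2 points")
  rfun <- if (is.function(radius)) radius else function(s) rep(radius, length(s))
  s <- arc_length(cl)
  total <- s[length(s)]
  r_end <- rfun(c(0, total))

  # point budget proportional to feature length
  cap_len <- pi * r_end
  side_n <- max(4L, round(n_points * total / (2 * total + sum(cap_len))))
  cap_n <- pmax(4L, round(n_points * cap_len / (2 * total + sum(cap_len))))

  # dense resample of the centerline for smooth tangents
  dense <- resample_polyline(cl, max(side_n * 2, 64L))
  sd_ <- arc_length(dense)
  tang <- rbind(dense[2, ] - dense[1, ],
                (dense[-(1:2), ] - dense[1:(nrow(dense) - 2), ]) / 2,
                dense[nrow(dense), ] - dense[nrow(dense) - 1, ])
  tang <- tang / sqrt(rowSums(tang^2))
  norm <- cbind(-tang[, 2], tang[, 1])

  pick <- round(seq(1, nrow(dense), length.out = side_n))
  r_here <- rfun(sd_[pick])
  side1 <- dense[pick, , drop = FALSE] + norm[pick, , drop = FALSE] * r_here
  side2 <- dense[pick, , drop = FALSE] - norm[pick, , drop = FALSE] * r_here

  cap_arc <- function(center, t_dir, n_dir, r, n) {
    # semicircle from +n to -n sweeping through +t (the outward pole)
    ang <- seq(0, pi, length.out = n + 2)[2:(n + 1)]
    ctr <- matrix(center, n, 2, byrow = TRUE)
    ctr + r * (cos(ang) %o% n_dir + sin(ang) %o% t_dir)
  }
  nE <- nrow(dense)
  cap_end <- cap_arc(dense[nE, ], tang[nE, ], norm[nE, ], r_end[2], cap_n[2])
  cap_start <- cap_arc(dense[1, ], -tang[1, ], -norm[1, ], r_end[1], cap_n[1])

  contour <- rbind(side1, cap_end, side2[rev(seq_len(side_n)), ], cap_start)
  colnames(contour) <- c("x", "y")
  if (polygon_signed_area(contour) < 0) contour <- contour[rev(seq_len(nrow(contour))), ]
  contour
}

#' Spherocylinder outline
#'
#' Rod-cell idealization: a rectangle of length `length - width` capped by two
#' semicircles of diameter `width`. Total tip-to-tip extent is `length`.
#'
#' @param length total cell length (micrometres), must exceed `width` unless
#'   equal (degenerate circle).
#' @param width cell width (micrometres).
#' @param n_points number of contour vertices.
#' @param center,angle rigid-body placement of the cell.
#' @return counterclockwise contour matrix (columns x, y).
#' @export
#' @examples
#' xy <- spherocylinder_contour(4, 1, n_points = 64)
spherocylinder_contour <- function(length, width, n_points = 128,
                                   center = c(0, 0), angle = 0) {
  stopifnot(length >= width, width > 0)
  r <- width / 2
  if (length - width < 1e-9) {
    ang <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
    xy <- cbind(x = r * cos(ang), y = r * sin(ang))
  } else {
    cl <- rbind(c(-(length - width) / 2, 0), c((length - width) / 2, 0))
    xy <- tube_contour(cl, r, n_points)
  }
  rot <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  xy <- xy %*% rot
  xy <- sweep(xy, 2, center, "+")
  colnames(xy) <- c("x", "y")
  xy
}

#' Rasterize a polygon to a binary mask
#'
#' Pixel centers falling inside the polygon are set to 1 (even-odd rule).
#'
#' @param xy contour in micrometres.
#' @param pixel_size micrometres per pixel.
#' @param dim c(nrow, ncol) of the raster; defaults to a tight bounding box
#'   with one pixel of padding.
#' @param origin xy position of the raster's (0, 0) corner, micrometres.
#' @return integer matrix (rows = y, columns = x; y-down).
#' @keywords internal
rasterize_polygon <- function(xy, pixel_size = 0.065, dim = NULL, origin = NULL) {
  xy <- as.matrix(xy)
  if (is.null(origin)) {
    origin <- c(min(xy[, 1]), min(xy[, 2])) - 2 * pixel_size
  }
  if (is.null(dim)) {
    span <- c(max(xy[, 2]) - origin[2], max(xy[, 1]) - origin[1]) + 2 * pixel_size
    dim <- ceiling(span / pixel_size)
  }
  cc <- rep(seq_len(dim[2]), each = dim[1])
  rr <- rep(seq_len(dim[1]), times = dim[2])
  px <- origin[1] + (cc - 0.5) * pixel_size
  py <- origin[2] + (rr - 0.5) * pixel_size
  m <- matrix(0L, dim[1], dim[2])
  m[cbind(rr, cc)] <- as.integer(points_in_polygon(px, py, xy))
  m
}
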