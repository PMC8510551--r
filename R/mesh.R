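# Midline meshing of rod-cell contours: pole finding, rib construction by
# arc-length pairing, iterative relaxation until ribs are perpendicular to
# the midline, and the derived length/width/volume measures. Cells that are
# not rod-shaped raise a `rod_shape_error`, signalling the principal-axis
# fallback.

rod_shape_error <- function(msg) {
  stop(structure(class = c("rod_shape_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# all intersections of the line p + s*dir with the closed polygon boundary;
# returns the signed parameters s, the intersection points, and their
# boundary arc-length parameters
line_polygon_intersections <- function(p, dir, a, e, bparam = NULL) {
  den <- dir[1] * (-e[, 2]) - dir[2] * (-e[, 1])
  ok <- abs(den) > 1e-12
  dx <- a[, 1] - p[1]
  dy <- a[, 2] - p[2]
  s <- (dx * (-e[, 2]) - dy * (-e[, 1])) / den
  u <- (dir[1] * dy - dir[2] * dx) / den
  hit <- ok & u >= 0 & u < 1
  if (!any(hit)) return(NULL)
  out <- list(s = s[hit],
              pts = cbind(a[hit, 1] + u[hit] * e[hit, 1],
                          a[hit, 2] + u[hit] * e[hit, 2]))
  if (!is.null(bparam)) {
    seglen <- sqrt(rowSums(e^2))
    out$t <- bparam[hit] + u[hit] * seglen[hit]
  }
  out
}

# split a closed boundary at arc-length parameters t1 < t2 into the two
# pole-to-pole arcs, both running from t1 to t2, with exact endpoints
split_boundary <- function(xy, bparam, total, t1, t2) {
  point_at <- function(t) {
    t <- t %% total
    i <- findInterval(t, bparam, rightmost.closed = TRUE)
    nxt <- if (i == nrow(xy)) 1L else i + 1L
    seg <- xy[nxt, ] - xy[i, ]
    len <- sqrt(sum(seg^2))
    xy[i, ] + seg * if (len > 0) (t - bparam[i]) / len else 0
  }
  p1 <- point_at(t1); p2 <- point_at(t2)
  idx <- seq_len(nrow(xy))
  fwd <- idx[bparam > t1 & bparam < t2]
  bwd <- c(idx[bparam > t2], idx[bparam < t1])
  arc_a <- rbind(p1, xy[fwd, , drop = FALSE], p2)
  arc_b <- rbind(p1, xy[rev(bwd), , drop = FALSE], p2)
  list(a = arc_a, b = arc_b, p1 = p1, p2 = p2)
}

# the chord of the polygon through p along dir: nearest boundary hits on the
# positive and negative side of p
chord_through <- function(p, dir, a, e) {
  hits <- line_polygon_intersections(p, dir, a, e)
  if (is.null(hits)) return(NULL)
  pos <- hits$s > 0
  if (!any(pos) || all(pos)) return(NULL)
  i1 <- which(pos)[which.min(hits$s[pos])]
  i2 <- which(!pos)[which.max(hits$s[!pos])]
  list(a = hits$pts[i1, ], b = hits$pts[i2, ])
}

# light smoothing of an open polyline, endpoints fixed
smooth_polyline <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(xy)
  out <- xy
  mid <- 2:(n - 1)
  out[mid, ] <- (xy[mid - 1, ] + xy[mid, ] + xy[mid + 1, ]) / 3
  out
}

polyline_self_intersects <- function(xy) {
  n <- nrow(xy) - 1
  if (n < 3) return(FALSE)
  a <- xy[1:n, , drop = FALSE]
  b <- xy[2:(n + 1), , drop = FALSE]
  for (i in 1:(n - 2)) {
    js <- (i + 2):n
    d1 <- (b[i, 1] - a[i, 1]) * (a[js, 2] - a[i, 2]) -
          (b[i, 2] - a[i, 2]) * (a[js, 1] - a[i, 1])
    d2 <- (b[i, 1] - a[i, 1]) * (b[js, 2] - a[i, 2]) -
          (b[i, 2] - a[i, 2]) * (b[js, 1] - a[i, 1])
    d3 <- (b[js, 1] - a[js, 1]) * (a[i, 2] - a[js, 2]) -
          (b[js, 2] - a[js, 2]) * (a[i, 1] - a[js, 1])
    d4 <- (b[js, 1] - a[js, 1]) * (b[i, 2] - a[js, 2]) -
          (b[js, 2] - a[js, 2]) * (b[i, 1] - a[js, 1])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Mesh a rod-cell contour with a midline and perpendicular ribs
#'
#' Poles are the two contour points with maximal separation; the boundary is
#' split into two pole-to-pole arcs, ribs join arc-length-matched point
#' pairs, and the rib endpoints are iteratively relaxed (re-intersected
#' along midline normals) until every rib is within `angle_tol` degrees of
#' perpendicular to the midline. The midline runs pole to pole through the
#' rib midpoints, so its arc length includes the polar caps.
#'
#' Non-convergence, a self-intersecting midline, or an aspect ratio at or
#' below `aspect_min` (midline length vs. largest rib width; a circle has
#' ratio 1) raise a `rod_shape_error`, the cue for callers to fall back to
#' principal-axis dimensions.
#'
#' @param contour closed polygon: matrix or data.frame with columns x, y in
#'   micrometres, >= 16 vertices.
#' @param n_ribs number of ribs; default scales with contour resolution.
#' @param max_iter relaxation iteration cap.
#' @param angle_tol maximum deviation from perpendicularity, degrees.
#' @param aspect_min minimal midline-length / max-rib-width ratio accepted
#'   as rod-like.
#' @param septum_frac ribs in a local width minimum below this fraction of
#'   the median rib width are flagged as septation sites.
#' @return object of class `midline_mesh`: list with `midline` (pole to
#'   pole), `rib_a`, `rib_b` (rib endpoint matrices), `rib_widths`,
#'   `rib_pos` (arc-length position of each rib along the midline),
#'   `pole_ribs` and `septum_ribs` (logical flags), `length` (midline arc
#'   length) and `iterations`.
#' @export
mesh_contour <- function(contour, n_ribs = NULL, max_iter = 60,
                         angle_tol = 5, aspect_min = 1.1,
                         septum_frac = 0.75) {
  xy <- drop_closing_vertex(as.matrix(contour[, 1:2]))
  n <- nrow(xy)
  if (n < 16) stop("contour must have >= 16 vertices")
  if (polygon_signed_area(xy) < 0) xy <- xy[rev(seq_len(n)), ]

  if (is.null(n_ribs)) n_ribs <- max(11L, min(round(n / 4), 96L))
  M <- n_ribs

  # closed-boundary representation: per-vertex arc-length parameter and
  # segment vectors, for chord casting and arc splitting
  segs_a <- xy
  segs_e <- xy[c(2:n, 1), , drop = FALSE] - xy
  seglen <- sqrt(rowSums(segs_e^2))
  bparam <- c(0, cumsum(seglen))[seq_len(n)]
  total <- sum(seglen)

  pair_arcs <- function(t1, t2) {
    sp <- split_boundary(xy, bparam, total, t1, t2)
    A <- resample_polyline(sp$a, M + 2)
    B <- resample_polyline(sp$b, M + 2)
    list(A = A[2:(M + 1), , drop = FALSE], B = B[2:(M + 1), , drop = FALSE],
         pole1 = sp$p1, pole2 = sp$p2)
  }

  # stage 1: rough poles (maximally separated vertex pair), rough midline
  d2 <- as.matrix(stats::dist(xy))^2
  ij <- arrayInd(which.max(d2), dim(d2))
  t1 <- bparam[min(ij)]; t2 <- bparam[max(ij)]
  pr <- pair_arcs(t1, t2)
  mid <- (pr$A + pr$B) / 2

  # stage 2: refine the poles. Maximal-separation poles sit on cap corners
  # for bent cells, which skews the arc pairing; iterate taking the midline
  # tangent just beyond each polar cap and moving the pole to the boundary
  # support point in that direction (the true cap tip, where the boundary
  # normal aligns with the midline axis).
  for (rep in 1:3) {
    widths <- sqrt(rowSums((pr$A - pr$B)^2))
    cap <- stats::median(widths) / 2
    pos <- arc_length(rbind(pr$pole1, mid, pr$pole2))[2:(M + 1)]
    mlen <- sum(sqrt(rowSums(diff(rbind(pr$pole1, mid, pr$pole2))^2)))
    good <- which(pos > cap & pos < mlen - cap)
    if (length(good) < 5) break
    q1 <- min(good); q2 <- max(good)
    d1 <- mid[q1, ] - mid[min(q1 + 3, q2), ]
    d2 <- mid[q2, ] - mid[max(q2 - 3, q1), ]
    d1 <- d1 / sqrt(sum(d1^2)); d2 <- d2 / sqrt(sum(d2^2))
    nt1 <- bparam[which.max(xy %*% d1)]
    nt2 <- bparam[which.max(xy %*% d2)]
    lo <- min(nt1, nt2); hi <- max(nt1, nt2)
    if (hi - lo < 1e-9) break
    changed <- abs(lo - t1) > 1e-9 || abs(hi - t2) > 1e-9
    t1 <- lo; t2 <- hi
    pr <- pair_arcs(t1, t2)
    mid <- (pr$A + pr$B) / 2
    if (!changed) break
  }
  A <- pr$A; B <- pr$B
  pole1 <- pr$pole1; pole2 <- pr$pole2
  mid <- (A + B) / 2

  # stage 3: relax the midline. Each iteration casts, for every interior
  # midline point, the boundary chord perpendicular to the local midline
  # tangent (a pure normal-direction constraint: the chord midpoint lies on
  # the normal through the point) and moves the point part-way toward the
  # chord midpoint, followed by light smoothing (damping suppresses the
  # zigzag instability of the naive update). Ribs are recast from the
  # relaxed midline; convergence is judged on body ribs, since ribs inside
  # the polar caps wobble by construction and are excluded from the width.
  damp <- 0.7
  cast_ribs <- function(mid, widths_prev = NULL) {
    ml <- rbind(pole1, mid, pole2)
    tang <- ml[3:(M + 2), ] - ml[1:M, ]
    tang <- tang / sqrt(rowSums(tang^2))
    normal <- cbind(-tang[, 2], tang[, 1])
    A <- mid; B <- mid
    okw <- rep(FALSE, M)
    for (k in seq_len(M)) {
      ch <- chord_through(mid[k, ], normal[k, ], segs_a, segs_e)
      if (is.null(ch)) next
      A[k, ] <- ch$a; B[k, ] <- ch$b
      okw[k] <- TRUE
    }
    rib <- B - A
    ribn <- sqrt(rowSums(rib^2))
    cosang <- abs(rowSums(rib * tang)) / pmax(ribn, 1e-12)
    list(A = A, B = B, widths = ribn, ok = okw,
         dev = asin(pmin(cosang, 1)) * 180 / pi, ml = ml)
  }
  max_dev <- Inf
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    rc <- cast_ribs(mid)
    w_med <- stats::median(rc$widths[rc$ok])
    chord_mid <- (rc$A + rc$B) / 2
    move <- rc$ok & rc$widths < 2.5 * w_med   # ignore cross-cell chords
    shift <- chord_mid[move, , drop = FALSE] - mid[move, , drop = FALSE]
    max_move <- if (any(move)) sqrt(max(rowSums(shift^2))) else 0
    mid[move, ] <- mid[move, , drop = FALSE] + damp * shift
    mid <- smooth_polyline(rbind(pole1, mid, pole2))[2:(M + 1), , drop = FALSE]
    s <- arc_length(rc$ml)
    cap <- w_med / 2
    body <- s[2:(M + 1)] > cap & (s[M + 2] - s[2:(M + 1)]) > cap
    max_dev <- if (any(body)) max(rc$dev[body]) else max(rc$dev)
    if (max_dev < angle_tol && max_move < 5e-3 * w_med) break
  }
  if (max_dev >= angle_tol)
    rod_shape_error(sprintf("mesh did not converge (max rib deviation %.1f deg)",
                            max_dev))
  # regularize point spacing (relaxation can bunch points at the cap
  # boundary), then cast the final ribs from the clean midline
  mid <- resample_polyline(smooth_polyline(rbind(pole1, mid, pole2)),
                           M + 2)[2:(M + 1), , drop = FALSE]
  rc <- cast_ribs(mid)
  A <- rc$A; B <- rc$B  # midline stays the relaxed one; chords give widths
  midline <- rbind(pole1, mid, pole2)
  rownames(midline) <- NULL
  if (polyline_self_intersects(midline))
    rod_shape_error("midline self-intersects (cell not rod-shaped)")
  widths <- sqrt(rowSums((B - A)^2))
  if (any(widths <= 0)) rod_shape_error("degenerate rib of zero width")
  mlen <- sum(sqrt(rowSums(diff(midline)^2)))
  if (mlen <= aspect_min * max(widths))
    rod_shape_error(sprintf("aspect ratio %.2f too low for a rod", mlen / max(widths)))

  s <- arc_length(midline)
  rib_pos <- s[2:(M + 1)]
  # pole exclusion: ribs within half the interior median width of either
  # pole, with one refinement pass of the width estimate
  pole_flag <- rep(FALSE, M)
  for (pass in 1:2) {
    w_est <- stats::median(widths[!pole_flag])
    cap <- w_est / 2
    pole_flag <- rib_pos < cap | (mlen - rib_pos) < cap
  }
  body <- widths[!pole_flag]
  w_med <- stats::median(body)
  septum_flag <- rep(FALSE, M)
  if (any(!pole_flag)) {
    low <- !pole_flag & widths < septum_frac * w_med
    # extend each low run by one neighbouring rib on each side
    if (any(low)) {
      idx <- which(low)
      nb <- unique(c(idx, pmax(idx - 1, 1), pmin(idx + 1, M)))
      septum_flag[nb] <- TRUE
      septum_flag <- septum_flag & !pole_flag
    }
  }
  out <- list(midline = midline, rib_a = A, rib_b = B, rib_widths = widths,
              rib_pos = rib_pos, pole_ribs = pole_flag,
              septum_ribs = septum_flag, length = mlen, iterations = it)
  class(out) <- "midline_mesh"
  out
}

#' @export
print.midline_mesh <- function(x, ...) {
  cat(sprintf("<midline_mesh> %d ribs, length %.3f um, median width %.3f um (%d pole, %d septal ribs)\n",
              length(x$rib_widths), x$length,
              stats::median(x$rib_widths[!x$pole_ribs & !x$septum_ribs]),
              sum(x$pole_ribs), sum(x$septum_ribs)))
  invisible(x)
}

principal_axis_dims <- function(xy) {
  xy <- drop_closing_vertex(as.matrix(xy))
  ctr <- colMeans(xy)
  cxy <- sweep(xy, 2, ctr)
  ev <- eigen(stats::cov(cxy), symmetric = TRUE)
  p1 <- cxy %*% ev$vectors[, 1]
  p2 <- cxy %*% ev$vectors[, 2]
  c(length = diff(range(p1)), width = diff(range(p2)))
}

#' Length, width, area and volume of a cell contour
#'
#' Mesh path: length is the pole-to-pole midline arc length; width is the
#' mean rib width excluding ribs within the polar caps and ribs flagged as
#' septation sites; volume comes from [cell_volume()]. When the contour is
#' not rod-shaped (the mesh raises a `rod_shape_error`, e.g. for round
#' cells) the fallback reports the extents along the major and minor
#' principal axes of the contour vertices and an ellipsoid-of-revolution
#' volume. `force_principal_axes` applies the fallback unconditionally
#' (useful for datasets of round cells, where no width filtering applies).
#'
#' @param contour closed polygon matrix/data.frame (x, y in micrometres).
#' @param force_principal_axes bypass meshing entirely.
#' @param ... passed to [mesh_contour()].
#' @return object of class `cell_dims`: list with length, width, area,
#'   volume (micrometres^k) and method (`"mesh"` or `"principal_axes"`).
#' @export
cell_dimensions <- function(contour, force_principal_axes = FALSE, ...) {
  xy <- drop_closing_vertex(as.matrix(contour[, 1:2]))
  area <- polygon_area(xy)
  if (area <= 0) stop("degenerate polygon")
  mk <- function(len, wid, vol, method)
    structure(list(length = len, width = wid, area = area, volume = vol,
                   method = method), class = "cell_dims")
  if (!force_principal_axes) {
    mesh <- tryCatch(mesh_contour(xy, ...), rod_shape_error = function(e) NULL)
    if (!is.null(mesh)) {
      keep <- !mesh$pole_ribs & !mesh$septum_ribs
      wid <- mean(mesh$rib_widths[keep])
      return(mk(mesh$length, wid, cell_volume(mesh), "mesh"))
    }
  }
  pa <- principal_axis_dims(xy)
  vol <- pi / 6 * pa["length"] * pa["width"]^2
  mk(unname(pa["length"]), unname(pa["width"]), unname(vol), "principal_axes")
}

#' @export
print.cell_dims <- function(x, ...) {
  cat(sprintf("<cell_dims> length %.3f um, width %.3f um, area %.3f um2, volume %.3f um3 [%s]\n",
              x$length, x$width, x$area, x$volume, x$method))
  invisible(x)
}

#' Cell volume from a midline mesh
#'
#' Solid of revolution about the midline: conical frustums between adjacent
#' ribs (radius = half rib width), closed by frustums tapering to zero
#' radius at the pole points — the discrete analogue of revolving the polar
#' caps into hemispheres.
#'
#' @param mesh a [mesh_contour()] result.
#' @return volume in cubic micrometres.
#' @export
cell_volume <- function(mesh) {
  stopifnot(inherits(mesh, "midline_mesh"))
  if (length(mesh$rib_widths) < 3) stop("need at least 3 ribs")
  r <- c(0, mesh$rib_widths / 2, 0)
  h <- sqrt(rowSums(diff(mesh$midline)^2))
  k <- seq_len(length(r) - 1)
  sum(pi / 3 * h * (r[k]^2 + r[k] * r[k + 1] + r[k + 1]^2))
}
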