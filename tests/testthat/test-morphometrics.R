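test_that("meshing an analytic spherocylinder recovers its dimensions", {
  xy <- spherocylinder_contour(4, 1, n_points = 256)
  m <- mesh_contour(xy)
  expect_equal(m$length, 4, tolerance = 0.01)
  body <- m$rib_widths[!m$pole_ribs & !m$septum_ribs]
  expect_true(all(abs(body - 1) < 0.01))
  d <- cell_dimensions(xy)
  expect_identical(d$method, "mesh")
  expect_equal(d$length, 4, tolerance = 0.01)
  expect_equal(d$width, 1, tolerance = 0.01)
})

test_that("round cells raise a rod-shape error and fall back to principal axes", {
  circ <- spherocylinder_contour(2, 2, n_points = 64)  # circle diameter 2
  expect_error(mesh_contour(circ), class = "rod_shape_error")
  d <- cell_dimensions(circ)
  expect_identical(d$method, "principal_axes")
  expect_equal(d$length, 2, tolerance = 0.01)
  expect_equal(d$width, 2, tolerance = 0.01)
  expect_equal(cell_dimensions(spherocylinder_contour(1, 1, 64))$volume,
               0.524, tolerance = 0.01)  # sphere diameter 1
})

test_that("bent rods keep their width and midline arc length", {
  xy <- banana_contour(radius = 3, half_angle_deg = 35, width = 1)
  truth_len <- 3 * 70 * pi / 180 + 1   # centerline arc plus the two caps
  m <- mesh_contour(xy)
  expect_equal(m$length, truth_len, tolerance = 0.02)
  body <- m$rib_widths[!m$pole_ribs]
  expect_true(all(abs(body - 1) < 0.02))
})

test_that("septal ribs are excluded from the width of constricted cells", {
  xy <- dumbbell_contour(total_length = 4, width = 1, neck = 0.5)
  m <- mesh_contour(xy)
  expect_gt(sum(m$septum_ribs), 0)
  d <- cell_dimensions(xy)
  expect_equal(d$width, 1, tolerance = 0.03)   # not the pooled mean with 0.5
  expect_lt(min(m$rib_widths), 0.6)            # the neck is in the mesh
})

test_that("mesh dimensions are rigid-motion invariant", {
  dims <- sapply(seq(0, pi, length.out = 12), function(a) {
    d <- cell_dimensions(spherocylinder_contour(4, 1, 256, angle = a,
                                                center = c(3, -2)))
    c(d$length, d$width)
  })
  expect_lt(diff(range(dims[1, ])) / mean(dims[1, ]), 0.005)
  expect_lt(diff(range(dims[2, ])) / mean(dims[2, ]), 0.005)
})

test_that("mesh and principal-axis dimensions agree on straight rods", {
  for (L in c(2, 3, 5)) {
    xy <- spherocylinder_contour(L, 1, 128)
    dm <- cell_dimensions(xy)
    dp <- cell_dimensions(xy, force_principal_axes = TRUE)
    expect_identical(dp$method, "principal_axes")
    expect_lt(abs(dm$length - dp$length) / dp$length, 0.03)
    expect_lt(abs(dm$width - dp$width) / dp$width, 0.03)
  }
})

test_that("revolved mesh volume matches the closed form and scales cubically", {
  v_true <- sphero_volume(4, 1)
  expect_equal(v_true, 2.8798, tolerance = 1e-4)
  m <- mesh_contour(spherocylinder_contour(4, 1, 256))
  expect_equal(cell_volume(m), v_true, tolerance = 0.02 * v_true)
  # doubling all linear dimensions multiplies volume by 8
  m2 <- mesh_contour(spherocylinder_contour(8, 2, 256))
  expect_equal(cell_volume(m2) / cell_volume(m), 8, tolerance = 0.01)
  # error shrinks monotonically with contour resolution
  errs <- sapply(c(64, 128, 256, 512), function(np)
    abs(cell_volume(mesh_contour(spherocylinder_contour(4, 1, np))) - v_true))
  expect_true(all(diff(errs) < 0))
})

test_that("instantaneous growth rate recovers exponential and linear volumes", {
  tl <- simulate_time_lapse(0.03, frames = 20, interval = 2)
  tr <- measure_time_lapse(tl$contours, interval = 2)
  expect_true(all(abs(tr$rate[4:17] - 0.03) < 0.05 * 0.03))
  flat <- instantaneous_growth(rep(2.5, 10), interval = 2)
  expect_true(all(abs(flat) < 1e-12))
  lin <- simulate_time_lapse(0.03, frames = 15, interval = 2, mode = "linear")
  rl <- measure_time_lapse(lin$contours, interval = 2)
  expect_true(all(diff(rl$rate[2:14]) < 0))
  expect_error(instantaneous_growth(c(1, 2), 2), "3 frames")
  expect_error(instantaneous_growth(c(1, -1, 2), 2), "nonpositive")
})

test_that("fluorescence is background-subtracted and area-normalized", {
  img <- matrix(10, 40, 40)
  sq <- cbind(x = c(2, 12, 12, 2), y = c(2, 2, 12, 12))
  expect_equal(cell_fluorescence(img, sq, background = 2), 8)
  expect_equal(cell_fluorescence(img, sq, background = 10), 0)
  # two-level image: result independent of contour placement
  img2 <- matrix(2, 40, 40)
  img2[5:15, 5:15] <- 12
  inner <- cbind(x = c(6, 13, 13, 6), y = c(6, 6, 13, 13))
  expect_equal(cell_fluorescence(img2, inner, background = 2), 10)
  inner2 <- inner + 1
  expect_equal(cell_fluorescence(img2, inner2, background = 2), 10)
  far <- cbind(x = c(100, 101, 101, 100), y = c(100, 100, 101, 101))
  expect_error(cell_fluorescence(img, far, background = 0), "inside")
})

test_that("width filtering, the 100-cell rule and robust CVs are enforced", {
  dims <- data.frame(strain_id = "a",
                     length_um = c(2, 2, 2, 2),
                     width_um = c(0.5, 0.7, 1.0, 2.5))
  s <- filter_and_summarize(dims, min_cells = 2)
  expect_equal(s$n_cells, 2)
  # 99 surviving cells: flagged excluded
  d99 <- data.frame(strain_id = "b", length_um = rep(3, 99),
                    width_um = rep(1, 99))
  s99 <- filter_and_summarize(d99, min_cells = 100)
  expect_true(s99$excluded)
  expect_true(is.na(s99$median_length))
  # hand-computed robust CV
  dcv <- data.frame(strain_id = "c", length_um = c(1, 2, 3, 4, 100),
                    width_um = rep(1, 5))
  scv <- filter_and_summarize(dcv, min_cells = 1)
  expect_equal(scv$median_length, 3)
  expect_equal(scv$cv_length, 1.4826 / 3, tolerance = 1e-9)
})

test_that("plate correction equalizes plate medians and is translation invariant", {
  s <- data.frame(strain_id = sprintf("s%d", 1:4),
                  plate = c("A", "A", "B", "B"),
                  n_cells = 200, median_length = c(3, 3.2, 3.4, 3.6),
                  median_width = c(1.0, 1.2, 1.4, 1.6),
                  cv_length = 0.2, cv_width = 0.05, excluded = FALSE)
  out <- plate_correct(s)
  expect_equal(out$corrected_width, c(1.2, 1.4, 1.2, 1.4))
  expect_equal(stats::median(out$corrected_width), stats::median(s$median_width))
  for (p in c("A", "B"))
    expect_equal(stats::median(out$corrected_width[out$plate == p]),
                 stats::median(s$median_width))
  # single plate: unchanged
  one <- plate_correct(s[s$plate == "A", ])
  expect_equal(one$corrected_length, one$median_length)
  # shifting a minority plate that sits clear of the global median leaves
  # the other plates' corrected output unchanged
  s3 <- data.frame(strain_id = sprintf("t%d", 1:9),
                   plate = rep(c("A", "B", "C"), each = 3),
                   n_cells = 200, median_length = 3,
                   median_width = c(1.00, 1.10, 1.20,
                                    1.05, 1.15, 1.25,
                                    1.30, 1.35, 1.40),
                   cv_length = 0.2, cv_width = 0.05, excluded = FALSE)
  base <- plate_correct(s3)
  s4 <- s3
  s4$median_width[s4$plate == "C"] <- s4$median_width[s4$plate == "C"] + 5
  shifted <- plate_correct(s4)
  keep <- s3$plate != "C"
  expect_equal(shifted$corrected_width[keep], base$corrected_width[keep])
})

test_that("population medians, CVs and plate offsets are recovered end to end", {
  cfg <- cell_sim_config(n_cells = 500, length_mean = 3, length_sd = 0.6,
                         width_mean = 1, width_sd = 0.06,
                         contour_points = 64, seed = 21)
  pop <- simulate_cell_population(cfg)
  dims <- measure_cells(pop$contours,
                        labels = pop$cells[c("cell_id", "plate")])
  true_med_l <- stats::median(pop$cells$length_um)
  true_med_w <- stats::median(pop$cells$width_um)
  dims$strain_id <- "s1"
  s <- filter_and_summarize(dims, min_width = 0, max_width = Inf,
                            min_cells = 100)
  expect_lt(abs(s$median_length - true_med_l) / true_med_l, 0.01)
  expect_lt(abs(s$median_width - true_med_w) / true_med_w, 0.01)
  true_cv_l <- 1.4826 * stats::mad(pop$cells$length_um, constant = 1) /
    stats::median(pop$cells$length_um)
  expect_lt(abs(s$cv_length - true_cv_l) / true_cv_l, 0.10)
})

test_that("binary masks segment into subpixel contours with the border rule", {
  px <- 0.065
  m1 <- phenoscreen:::rasterize_polygon(
    spherocylinder_contour(3, 1, 128, center = c(5, 4), angle = 0.6),
    px, dim = c(160, 160), origin = c(0, 0))
  ct <- segment_mask(m1, px)
  expect_length(ct, 1)
  d <- cell_dimensions(ct[[1]])
  expect_lt(abs(d$length - 3), 0.02 * 3 + px)
  expect_lt(abs(d$width - 1), 0.02 + px)
  # two separated cells
  m2 <- phenoscreen:::rasterize_polygon(
    spherocylinder_contour(2, 0.8, 64, center = c(2, 2)),
    px, dim = c(160, 160), origin = c(0, 0))
  expect_length(segment_mask(pmax(m1, m2), px), 2)
  # a cell on the image edge is dropped
  mb <- phenoscreen:::rasterize_polygon(
    spherocylinder_contour(3, 1, 64, center = c(1, 0.4)),
    px, dim = c(160, 160), origin = c(0, 0))
  expect_length(segment_mask(mb, px), 0)
  expect_length(segment_mask(matrix(0, 10, 10), px), 0)
})

test_that("contour tables round-trip through CSV", {
  pop <- simulate_cell_population(cell_sim_config(n_cells = 3, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_contours(pop$contours, path)
  back <- read_contours(path)
  expect_setequal(names(back), names(pop$contours))
  for (id in names(back))
    expect_equal(unname(back[[id]]), unname(pop$contours[[id]]),
                 tolerance = 1e-9)
})
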