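test_that("fixing the seed fixes every generated artifact", {
  cfg <- screen_sim_config(n_essential = 5, n_nonessential = 3,
                           n_controls = 3, read_depth = 1e4, seed = 42)
  a <- simulate_pooled_screen(cfg)
  b <- simulate_pooled_screen(cfg)
  expect_identical(a, b)
  g <- growth_sim_config(seed = 42)
  expect_identical(simulate_growth_plate(g, 4), simulate_growth_plate(g, 4))
  cc <- cell_sim_config(n_cells = 5, seed = 42)
  expect_identical(simulate_cell_population(cc), simulate_cell_population(cc))
})

test_that("same growth config under two seeds shares truth, not noise", {
  g1 <- growth_sim_config(mu_max = 0.03, lag_target = 60, seed = 1)
  g2 <- growth_sim_config(mu_max = 0.03, lag_target = 60, seed = 2)
  a <- simulate_growth_plate(g1, 3)
  b <- simulate_growth_plate(g2, 3)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$curves$od, b$curves$od))
})

test_that("noise-free pooled screen yields RF equal to d_i/D downstream", {
  cfg <- screen_sim_config(n_essential = 10, n_nonessential = 5,
                           n_controls = 5, read_depth = Inf, seed = 3)
  sim <- simulate_pooled_screen(cfg)
  rf <- relative_fitness(sim$t0, sim$t_end, sim$library,
                         doublings = cfg$doublings, pseudocount = 0)
  expect_lt(max(abs(rf$rf - sim$truth$rf_true)), 1e-12)
  # uniform fitness: RF = 1 for every strain
  cfg1 <- screen_sim_config(n_essential = 4, n_nonessential = 0,
                            n_controls = 3, read_depth = Inf,
                            true_fitness = 15, seed = 5)
  sim1 <- simulate_pooled_screen(cfg1)
  rf1 <- relative_fitness(sim1$t0, sim1$t_end, sim1$library, 15, 0)
  expect_equal(rf1$rf, rep(1, 7), tolerance = 1e-12)
  # single depleted strain, hand arithmetic: d = 12 -> RF = 0.8
  cfg2 <- screen_sim_config(n_essential = 1, n_nonessential = 0,
                            n_controls = 5, read_depth = Inf,
                            true_fitness = 12, seed = 6)
  sim2 <- simulate_pooled_screen(cfg2)
  rf2 <- relative_fitness(sim2$t0, sim2$t_end, sim2$library, 15, 0)
  expect_equal(rf2$rf[1], 0.8, tolerance = 1e-12)
})

test_that("finite-depth RF estimates sit within propagated sampling error", {
  d_true <- c(seq(7.5, 16.5, length.out = 7))
  reps <- 100
  est <- matrix(NA_real_, reps, 12)
  for (i in seq_len(reps)) {
    cfg <- screen_sim_config(n_essential = 7, n_nonessential = 0,
                             n_controls = 5, read_depth = 1e6,
                             true_fitness = d_true, seed = 1000 + i)
    sim <- simulate_pooled_screen(cfg)
    rf <- relative_fitness(sim$t0, sim$t_end, sim$library, 15)
    est[i, ] <- rf$rf
  }
  truth <- c(d_true / 15, rep(1, 5))
  se_mean <- apply(est, 2, stats::sd) / sqrt(reps)
  expect_true(all(abs(colMeans(est) - truth) < pmax(3 * se_mean, 0.005)))
})

test_that("noise-free growth curves are nondecreasing and bounded", {
  g <- growth_sim_config(mu_max = 0.03, lag_target = 45, noise_sd = 0, seed = 1)
  sim <- simulate_growth_plate(g, 1)
  od <- sim$curves$od
  expect_true(all(diff(od) >= -1e-12))
  expect_true(all(od <= g$carrying_capacity + 1e-9))
  expect_error(simulate_growth_plate(growth_sim_config(duration = 8), 1),
               "two sampling intervals")
})

test_that("generated contours are simple closed polygons with analytic area", {
  cfg <- cell_sim_config(n_cells = 20, contour_points = 64, seed = 8)
  pop <- simulate_cell_population(cfg)
  for (i in seq_len(20)) {
    xy <- pop$contours[[i]]
    area <- phenoscreen:::polygon_area(xy)
    L <- pop$cells$length_um[i]; W <- pop$cells$width_um[i]
    analytic <- W * (L - W) + pi * (W / 2)^2
    expect_lt(abs(area - analytic) / analytic, 0.005)
    # closed ring of distinct vertices, no self-intersection
    expect_gte(nrow(xy), 16)
    expect_false(phenoscreen:::polyline_self_intersects(
      rbind(xy, xy[1, , drop = FALSE])))
  }
})

test_that("plate offsets are applied to dimensions before generation", {
  cfg <- cell_sim_config(n_cells = 200, width_sd = 0.01, length_sd = 0.05,
                         plate_offsets = list(A = c(0, 0), B = c(0, 0.2)),
                         seed = 12)
  pop <- simulate_cell_population(cfg)
  wA <- stats::median(pop$cells$width_um[pop$cells$plate == "A"])
  wB <- stats::median(pop$cells$width_um[pop$cells$plate == "B"])
  expect_equal(wB - wA, 0.2, tolerance = 0.01)
})

test_that("time-lapse tracks encode the requested volume dynamics", {
  tl <- simulate_time_lapse(0.03, frames = 10, interval = 2)
  expect_equal(tl$track$volume_true,
               tl$track$volume_true[1] * exp(0.03 * tl$track$time_min))
  lin <- simulate_time_lapse(0.05, frames = 8, interval = 3, mode = "linear")
  expect_equal(diff(lin$track$volume_true),
               rep(0.05 * lin$track$volume_true[1] * 3, 7))
  expect_error(simulate_time_lapse(0.03, frames = 2), "frames")
})

test_that("contamination mixing has exact truth in the identity and bleed cases", {
  lib <- toy_library(1, 2)
  wells <- list(W1 = new_sample_counts(lib$spacer, c(1e6, 0, 0), sample_id = "W1"),
                W2 = new_sample_counts(lib$spacer, c(0, 1e6, 0), sample_id = "W2"))
  ident <- simulate_contamination(wells, diag(2))
  expect_equal(ident$truth$major_fraction, c(0, 0))
  mix <- rbind(c(0.99, 0.01), c(0, 1))
  out <- simulate_contamination(wells, mix)
  expect_equal(out$truth$major_fraction[1], 0.01)
  rep1 <- contamination_report(out$mixed[[1]], lib$spacer[1])
  expect_equal(rep1$contaminant_fraction, 0.01, tolerance = 1e-9)
  expect_error(simulate_contamination(wells, rbind(c(0.5, 0.4), c(0, 1))),
               "sum to 1")
})
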