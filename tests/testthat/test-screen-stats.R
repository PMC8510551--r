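test_that("robust summaries use the median and 1.4826 x MAD", {
  rs <- robust_summary(c(1, 2, 3, 4, 100))
  expect_equal(rs$median, 3)
  expect_equal(rs$robust_sd, 1.4826)
  expect_equal(robust_summary(rep(7, 9))$robust_sd, 0)
  expect_error(robust_summary(numeric(0)), "empty")
  # consistency on Gaussian data
  set.seed(101)
  rs2 <- robust_summary(stats::rnorm(1e5))
  expect_equal(rs2$robust_sd, 1, tolerance = 0.02)
})

test_that("robust summaries are permutation invariant and affine equivariant", {
  set.seed(13)
  x <- stats::rexp(101)
  a <- robust_summary(x)
  b <- robust_summary(sample(x))
  expect_equal(a$median, b$median)
  expect_equal(a$robust_sd, b$robust_sd)
  y <- robust_summary(3 * x - 2)
  expect_equal(y$median, 3 * a$median - 2)
  expect_equal(y$robust_sd, 3 * a$robust_sd, tolerance = 1e-12)
})

test_that("outlier calls use strict k-SD thresholds", {
  ref <- robust_summary(c(0, -1, 1, -2, 2, 0.5, -0.5))
  sd <- ref$robust_sd
  calls <- call_outliers(c(ref$median - 3.1 * sd, ref$median - 3.0 * sd,
                           ref$median + 3.5 * sd), ref, k = 3)
  expect_equal(calls$flag, c("low", "normal", "high"))
  one_sided <- call_outliers(ref$median + c(-4, 4) * sd, ref, k = 3,
                             side = "low")
  expect_equal(one_sided$flag, c("low", "normal"))
  expect_error(call_outliers(1, robust_summary(rep(1, 5))), "robust_sd")
})

test_that("false-positive rate on Gaussian nulls approaches 2*pnorm(-3)", {
  set.seed(31)
  v <- stats::rnorm(1e4)
  calls <- call_outliers(v, robust_summary(v), k = 3)
  expect_lt(abs(mean(calls$flag != "normal") - 2 * stats::pnorm(-3)), 0.002)
})

test_that("hypergeometric p matches exhaustive enumeration for small N", {
  expect_equal(hypergeom_enrichment(10, 4, 5, 4)$p_value, 6 / 252,
               tolerance = 1e-12)
  pick <- function(lo, hi) if (lo >= hi) lo else sample(lo:hi, 1)
  set.seed(5)
  for (i in 1:25) {
    N <- pick(2, 12)
    K <- pick(0, N)
    n <- pick(1, N)
    k <- pick(max(0, n - (N - K)), min(K, n))
    expect_equal(hypergeom_enrichment(N, K, n, k)$p_value,
                 hyper_enum(N, K, n, k), tolerance = 1e-10,
                 info = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
  }
  expect_equal(hypergeom_enrichment(20, 5, 6, 0)$p_value, 1)
  expect_equal(hypergeom_enrichment(9, 9, 9, 9)$p_value, 1)
  expect_error(hypergeom_enrichment(10, 4, 5, 5), "inconsistent")
})

test_that("robust regression resists gross outliers where OLS does not", {
  x <- seq(0, 10, length.out = 50)
  y <- 2 * x + 1
  f <- fit_robust(x, y)
  expect_equal(f$slope, 2, tolerance = 1e-8)
  expect_equal(f$intercept, 1, tolerance = 1e-8)
  expect_equal(f$pearson_r, 1, tolerance = 1e-12)
  y2 <- y; y2[7] <- 60
  f2 <- fit_robust(x, y2)
  ols <- stats::lm(y2 ~ x)
  expect_lt(abs(f2$slope - 2) / 2, 0.02)
  expect_gt(abs(stats::coef(ols)[2] - 2) / 2, 0.05)  # OLS is pulled away
  expect_error(fit_robust(rep(1, 5), 1:5), "variance")
})

test_that("robust regression tolerates 20% planted contamination", {
  set.seed(77)
  x <- stats::runif(100, 0, 10)
  y <- 1.5 * x - 2 + stats::rnorm(100, 0, 0.1)
  bad <- sample(100, 20)
  y[bad] <- stats::runif(20, 30, 60)
  f <- fit_robust(x, y)
  expect_lt(abs(f$slope - 1.5) / 1.5, 0.05)
})

test_that("robust regression agrees with an established MM fit", {
  set.seed(19)
  x <- stats::runif(80, 0, 5)
  y <- 0.7 * x + 2 + stats::rnorm(80, 0, 0.3)
  y[1:8] <- y[1:8] + 10
  f <- fit_robust(x, y)
  mm <- MASS::rlm(y ~ x, method = "MM")
  expect_equal(f$slope, unname(stats::coef(mm)[2]), tolerance = 0.03)
  expect_equal(f$intercept, unname(stats::coef(mm)[1]), tolerance = 0.1)
})

test_that("correlation on shuffled pairs is near zero", {
  set.seed(23)
  x <- stats::rnorm(1000)
  y <- sample(stats::rnorm(1000))
  f <- fit_robust(x, y)
  expect_lt(abs(f$pearson_r), 0.1)
})

test_that("screen classification flags planted outliers and enrichments", {
  set.seed(3)
  ann <- data.frame(strain_id = sprintf("s%02d", 1:60),
                    category = c(rep("essential", 30),
                                 rep("nonessential", 20),
                                 rep("control", 10)),
                    group = c(rep("membrane", 5), rep("other", 55)),
                    stringsAsFactors = FALSE)
  rf <- c(stats::rnorm(50, 1, 0.01), stats::rnorm(10, 1, 0.01))
  rf[c(3, 17)] <- 0.5  # two strains far below the controls
  fitness <- data.frame(strain_id = ann$strain_id, condition = "induced",
                        rf = rf)
  width <- stats::rnorm(55, 1, 0.01)
  morph <- data.frame(strain_id = ann$strain_id[1:55], condition = "induced",
                      median_length = stats::rnorm(55, 3, 0.02),
                      median_width = width)
  morph$median_width[1:5] <- 1.4  # the whole membrane group is wide
  cls <- classify_screen(fitness, morphology = morph, annotations = ann)
  flagged <- cls$fitness_calls$id[cls$fitness_calls$flag == "low"]
  expect_setequal(flagged, c("s03", "s17"))
  wide <- cls$morphology_calls$strain_id[cls$morphology_calls$wide]
  expect_setequal(wide, sprintf("s%02d", 1:5))
  enr <- cls$enrichment[cls$enrichment$group == "membrane", ]
  expect_equal(enr$p_value, hyper_enum(55, 5, 5, 5), tolerance = 1e-9)
  # all-identical values: zero outliers (robust sd 0 is an error by contract)
  expect_error(call_outliers(rep(1, 10), robust_summary(rep(1, 10))))
})
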