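test_that("full-basis PCA is an orthonormal change of coordinates", {
  withr::with_seed(1, {
    xb <- matrix(rnorm(600 * 4), ncol = 4)
    yb <- 0.7 * xb + 0.3 * matrix(rnorm(600 * 4), ncol = 4)
  })
  pc <- pca_condition(xb, yb, N = 4)
  expect_equal(pc$variance_explained, 1)
  # MI is invariant under the full rotation (up to estimator noise)
  a <- knn_mutual_information(xb, yb, 3)$value
  b <- knn_mutual_information(pc$x, pc$y, 3)$value
  expect_lt(abs(a - b), 0.12)
})

test_that("a sinusoid's delay embedding concentrates on two components", {
  s <- sin(2 * pi * (1:3000) / 37)
  xb <- embed_blocks(s, d = 8L)
  pc <- pca_condition(xb, xb, N = 2)
  expect_gt(pc$variance_explained, 0.999)
  expect_error(pca_condition(xb, xb, N = 5), "rank")
  expect_error(pca_condition(xb, xb, N = 9), "1..d")
})

test_that("component count follows the cumulative variance rule", {
  expect_identical(suggest_N(c(0.97, 0.02, 0.01)), 2L)
  expect_identical(suggest_N(c(1, 0, 0)), 1L)
  expect_identical(suggest_N(c(0.5, 0.3, 0.15, 0.05), threshold = 0.8), 2L)
  expect_error(suggest_N(c(0.5, 0.2)), "sum to 1")
  # noise-floor variant counts only the above-floor excess: 2 signal
  # components over an 8-component noise floor
  fr <- c(0.4, 0.3, rep(0.3 / 8, 8))
  expect_identical(suggest_N(fr, above_floor = TRUE), 2L)
  expect_gt(suggest_N(fr), 2L)
})

test_that("rate fit recovers an exact line and flags degenerate slopes", {
  curve <- data.frame(d = 10:14, mi_bits = 0.1 * (10:14) + 0.5,
                      variance_explained = 1)
  est <- fit_rate(curve, fit_range = c(10, 14), dt = 0.001)
  expect_s3_class(est, "rate_estimate")
  expect_equal(est$slope_bits_per_sample, 0.1)
  expect_equal(est$rate_bits_per_s, 100)
  expect_equal(est$intercept, 0.5)
  expect_equal(est$r_squared, 1)
  expect_false(est$negative_slope)

  flat <- data.frame(d = 1:5, mi_bits = rep(2, 5))
  est <- fit_rate(flat, fit_range = c(1, 5), dt = 0.01)
  expect_equal(est$rate_bits_per_s, 0)

  dec <- data.frame(d = 1:5, mi_bits = -0.02 * (1:5))
  expect_warning(est <- fit_rate(dec, fit_range = c(1, 5), dt = 0.01), "negative")
  expect_true(est$negative_slope)
  expect_equal(est$rate_bits_per_s, -2)

  expect_error(fit_rate(curve, fit_range = c(20, 30), dt = 1), "fewer than 2")
  expect_error(fit_rate(curve, fit_range = c(10, 14)), "dt")
})

test_that("fit-range finder spans a perfectly linear admissible range", {
  curve <- data.frame(d = 2:25, mi_bits = 0.2 * (2:25) + 0.3,
                      variance_explained = 1)
  class(curve) <- c("mi_curve", "data.frame")
  attr(curve, "N") <- 2L
  fr <- suggest_fit_range(curve, delay = 20, L = 5)
  expect_identical(as.integer(fr), c(5L, 20L))
  expect_false(attr(fr, "second_region"))
  expect_error(suggest_fit_range(curve[1:3, ], delay = 20, L = 5), "4 curve")
})

test_that("fit-range finder rejects a saturating curve", {
  # rises then levels off far below the latency: no linear region
  d <- 2:25
  curve <- data.frame(d = d, mi_bits = 1 - exp(-d / 3),
                      variance_explained = 1)
  class(curve) <- c("mi_curve", "data.frame")
  attr(curve, "N") <- 2L
  expect_error(suggest_fit_range(curve, delay = 20, L = 2), "linear region")
})

test_that("fit-range finder flags a spurious steep region at large d", {
  d <- 4:30
  mi <- ifelse(d <= 20, 0.1 * d, 2 + 0.3 * (d - 20))
  curve <- data.frame(d = d, mi_bits = mi, variance_explained = 1)
  class(curve) <- c("mi_curve", "data.frame")
  attr(curve, "N") <- 4L
  fr <- suggest_fit_range(curve, delay = 20, L = 4)
  expect_true(attr(fr, "second_region"))
})

test_that("MI curve is flat near zero for independent signals", {
  withr::with_seed(17, {
    x <- timeseries(rnorm(12000), dt = 0.001)
    y <- timeseries(rnorm(12000), dt = 0.001)
  })
  cv <- mi_curve(x, y, d_values = c(2, 4, 6, 8), delay = 0, N = 2, k = 3)
  expect_s3_class(cv, "mi_curve")
  expect_true(all(abs(cv$mi_bits) < 0.05))
  est <- fit_rate(cv, fit_range = c(2, 8), dt = 0.001)
  expect_lt(abs(est$slope_bits_per_sample), 0.01)
})

test_that("the fitted object exposes the standard modelling interface", {
  sp <- channel_spec(make_lowpass_filter(17, 0.3), noise_variance = 0.3,
                     n = 12000, seed = 23)     # group delay 8 samples
  sim <- simulate_gaussian_channel(sp)
  fit <- suppressWarnings(
    information_rate(sim$x, sim$y, k = 3, max_lag = 20, seed = 23))
  expect_s3_class(fit, "inforate_fit")
  expect_identical(fit$delay, 8L)
  expect_gt(fit$rate_bits_per_s, 0)
  expect_equal(fit$rate_bits_per_s, fit$slope_bits_per_sample / fit$dt)

  co <- coef(fit)
  expect_named(co, c("intercept", "slope"))
  expect_equal(unname(co["slope"]), fit$slope_bits_per_sample)

  pr <- predict(fit, newdata = c(5, 10))
  expect_equal(pr[2] - pr[1], 5 * fit$slope_bits_per_sample)

  res <- residuals(fit)
  expect_length(res, sum(fit$curve$d >= fit$fit_range[1] &
                           fit$curve$d <= fit$fit_range[2]))
  expect_lt(max(abs(res)), 0.5)

  expect_output(print(fit), "rate")
  expect_output(summary(fit), "MI curve")

  rep <- as_report(fit)
  expect_true(all(c("rate_bits_per_s", "mi_curve", "cmif", "seed",
                    "package_version") %in% names(rep)))

  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("pipeline validates its inputs and reports the null case", {
  expect_error(information_rate(rnorm(100), rnorm(100)), "dt is required")
  expect_error(information_rate(timeseries(rnorm(100), 0.1),
                                timeseries(rnorm(100), 0.2)), "inconsistent dt")
  expect_error(information_rate(timeseries(rnorm(100), 0.1),
                                timeseries(rnorm(50), 0.1)), "lengths differ")
  expect_error(information_rate(timeseries(c(1, NA, rnorm(50)), 0.1),
                                timeseries(rnorm(52), 0.1)), "interpolate")

  withr::with_seed(31, {
    x <- timeseries(rnorm(11000), dt = 0.01)
    y <- timeseries(rnorm(11000), dt = 0.01)
  })
  expect_warning(fit <- information_rate(x, y, max_lag = 30, seed = 31),
                 "CMIF peak|linear region")
  expect_lt(abs(fit$rate_bits_per_s), 3)   # bits/s at dt = 0.01
  expect_true(length(fit$notes) > 0)
})

test_that("identical seeds reproduce the fit exactly", {
  dc <- delayed_copy(11000, delay = 5, noise_sd = 0.8, seed = 40)
  a <- suppressWarnings(information_rate(dc$x, dc$y, max_lag = 15, seed = 7))
  b <- suppressWarnings(information_rate(dc$x, dc$y, max_lag = 15, seed = 7))
  expect_identical(a$rate_bits_per_s, b$rate_bits_per_s)
  expect_identical(a$curve$mi_bits, b$curve$mi_bits)
})
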