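test_that("filter design: DC gain, identity case, validation", {
  taps <- make_lowpass_filter(41)
  expect_length(taps, 41L)
  expect_lt(abs(sum(taps) - 1), 1e-3)          # unit response at DC
  expect_identical(make_lowpass_filter(1), 1)  # identity filter
  expect_true(all(abs(taps - rev(taps)) < 1e-12))  # linear phase
  expect_error(make_lowpass_filter(41, 1.5), "cutoff")
  expect_error(make_lowpass_filter(0), "n_taps")
})

test_that("channel simulation honours the output equation", {
  sp <- channel_spec(filter_taps = 1, noise_variance = 0, n = 500, seed = 3)
  sim <- simulate_gaussian_channel(sp)
  expect_identical(sim$x$values, sim$y$values)   # identity channel, no noise

  taps <- make_lowpass_filter(21, 0.3)
  sp <- channel_spec(taps, noise_variance = 0.5, n = 60000, seed = 5)
  sim <- simulate_gaussian_channel(sp)
  expect_length(sim$x, 60000L - 20L)
  # var(y) = sum(a_i^2) * var(x) + noise variance
  expect_lt(abs(var(sim$y$values) - (sum(taps^2) + 0.5)) / (sum(taps^2) + 0.5),
            0.05)
  # y is exactly the filtered x plus noise with the right variance
  z <- sim$y$values - as.numeric(
    stats::filter(c(rep(NA, 20), sim$x$values), taps, sides = 1))[-(1:20)]
  expect_lt(abs(var(z, na.rm = TRUE) - 0.5) / 0.5, 0.05)

  # reproducible under the seed
  again <- simulate_gaussian_channel(sp)
  expect_identical(sim$x$values, again$x$values)
  expect_identical(sim$y$values, again$y$values)

  expect_error(channel_spec(filter_taps = c(0, 0)), "non-zero")
  expect_error(channel_spec(noise_variance = -1), "noise_variance")
})

test_that("coherence: identity, independence, FIR closed form", {
  withr::with_seed(9, x <- timeseries(rnorm(40000), dt = 0.001))
  ch <- coherence_function(x, x)
  expect_true(all(ch$coherence > 0.99))
  expect_true(all(ch$coherence < 1))

  withr::with_seed(10, y <- timeseries(rnorm(40000), dt = 0.001))
  ch0 <- coherence_function(x, y)
  expect_lt(mean(ch0$coherence), 0.05)

  # known FIR + white noise: coherence = |A|^2 / (|A|^2 + noise variance)
  taps <- make_lowpass_filter(41, 0.3)
  sp <- channel_spec(taps, noise_variance = 0.1, n = 200000, seed = 11)
  sim <- simulate_gaussian_channel(sp)
  ch <- coherence_function(sim$x, sim$y)
  j <- seq_along(taps) - 1
  a2 <- vapply(ch$frequencies, function(f)
    Mod(sum(taps * exp(-2i * pi * f * j * 0.001)))^2, numeric(1))
  expected <- a2 / (a2 + 0.1)
  band <- ch$frequencies < 120   # passband, where the estimate is stable
  expect_lt(max(abs(ch$coherence[band] - expected[band])), 0.05)

  expect_warning(coherence_function(timeseries(rnorm(5000), 0.001),
                                    timeseries(rnorm(5000), 0.001)),
                 "segments")
})

test_that("capacity integral matches closed forms", {
  f <- seq(1, 500, by = 1)
  expect_equal(gaussian_capacity(f, rep(0, 500)), 0)
  expect_equal(gaussian_capacity(f, rep(0.5, 500)), 500)    # 500 * log2(2)
  expect_equal(gaussian_capacity(f, rep(0.75, 500)), 1000)  # 500 * log2(4)
  expect_error(gaussian_capacity(f, rep(1, 500)), "diverges")
  expect_error(gaussian_capacity(f, rep(-0.1, 500)), ">= 0")
})

test_that("analytic capacity: flat-SNR closed form and noise monotonicity", {
  sp <- channel_spec(filter_taps = 1, noise_variance = 1, n = 100, dt = 0.001)
  expect_equal(analytic_capacity(sp), 500, tolerance = 1e-6)  # SNR 1, 500 Hz

  caps <- vapply(c(0.01, 0.1, 1, 10), function(nv)
    analytic_capacity(channel_spec(noise_variance = nv, n = 100)), numeric(1))
  expect_true(all(diff(caps) < 0))
  expect_lt(caps[4], 0.2 * caps[3])   # capacity -> 0 as noise grows

  expect_error(analytic_capacity(channel_spec(noise_variance = 0, n = 100)),
               "infinite")
})

test_that("Welch capacity converges to the analytic oracle with n", {
  sp0 <- channel_spec(noise_variance = 0.1, seed = 13)
  target <- analytic_capacity(sp0)
  err <- vapply(c(10000L, 40000L, 160000L), function(n) {
    sim <- simulate_gaussian_channel(channel_spec(noise_variance = 0.1,
                                                  n = n, seed = 13))
    ch <- coherence_function(sim$x, sim$y, segment_length = 1024L)
    abs(gaussian_capacity(ch$frequencies, ch$coherence) - target) / target
  }, numeric(1))
  expect_lt(err[2], 0.05)
  expect_lt(err[3], err[1])
})

test_that("noise calibration inverts the capacity map", {
  nv <- calibrate_noise_variance(220)
  sp <- channel_spec(noise_variance = nv, n = 100)
  expect_equal(analytic_capacity(sp), 220, tolerance = 1e-4)
})

test_that("agreement limit reads the largest prefix-consistent capacity", {
  tab <- data.frame(analytic_capacity = c(50, 100, 200, 400),
                    rel_error = c(0.02, 0.05, 0.08, 0.30))
  expect_equal(agreement_limit(tab), 200)
  tab$rel_error <- c(0.2, 0.05, 0.08, 0.30)
  expect_equal(agreement_limit(tab), 0)    # first point already off
  tab$rel_error <- rep(0.01, 4)
  expect_equal(agreement_limit(tab), 400)
  # a failure in the middle caps the prefix even if later points agree
  tab$rel_error <- c(0.01, 0.2, 0.01, 0.01)
  expect_equal(agreement_limit(tab), 50)
})

test_that("simulated channel delay equals the filter group delay", {
  sp <- channel_spec(make_lowpass_filter(21, 0.3), noise_variance = 0.05,
                     n = 20000, seed = 19)
  sim <- simulate_gaussian_channel(sp)
  cm <- cross_mi_function(standardize(sim$x), standardize(sim$y),
                          max_lag = 30, k = 6)
  expect_identical(cm$delay, 10L)   # (21 - 1) / 2
})
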