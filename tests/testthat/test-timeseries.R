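test_that("constructor enforces the container invariants", {
  ts <- timeseries(c(1, 2, 3), dt = 0.001, label = "demo")
  expect_s3_class(ts, "timeseries")
  expect_length(ts, 3L)
  expect_identical(as.numeric(ts), c(1, 2, 3))
  expect_error(timeseries(1, dt = 0.1), "at least 2")
  expect_error(timeseries(c(1, 2), dt = 0), "positive")
  expect_error(timeseries(c(1, 2), dt = 0.1, missing = TRUE), "length")
  expect_error(timeseries(c(1, Inf), dt = 0.1), "finite")
  # NA values are absorbed into the mask
  expect_identical(timeseries(c(1, NA, 3), dt = 1)$missing, c(FALSE, TRUE, FALSE))
})

test_that("reader parses plain, gappy and multi-column files", {
  p <- write_fixture(c("1.0", "2.0", "3.0"))
  ts <- read_timeseries(p, dt = 0.001)
  expect_length(ts, 3L)
  expect_false(any(ts$missing))
  expect_identical(ts$values, c(1, 2, 3))

  # empty cells and NaN tokens mark missing samples
  p <- write_fixture(c("1.0", "", "3.0", "NaN", "5"))
  ts <- read_timeseries(p, dt = 60)
  expect_identical(ts$missing, c(FALSE, TRUE, FALSE, TRUE, FALSE))

  # second column of a CSV, first ignored
  p <- write_fixture(c("9,1.5", "9,2.5", "9,3.5"), ext = "csv")
  ts <- read_timeseries(p, dt = 1, column = 2L)
  expect_identical(ts$values, c(1.5, 2.5, 3.5))

  expect_error(read_timeseries(tempfile(), dt = 1), "not found")
  p <- write_fixture(c("a", "b"))
  expect_error(read_timeseries(p, dt = 1), "no numeric")
})

test_that("series round-trip through the writer preserves values and gaps", {
  ts <- timeseries(c(1.25, NA, 3.5), dt = 60)
  p <- tempfile(fileext = ".txt")
  write_timeseries(ts, p)
  back <- read_timeseries(p, dt = 60)
  expect_identical(back$values[!back$missing], c(1.25, 3.5))
  expect_identical(back$missing, ts$missing)
})

test_that("gap interpolation is shape-preserving and leaves data untouched", {
  ts <- timeseries(c(1, 2, 3), dt = 1)
  expect_identical(interpolate_missing(ts), ts)

  # interior gap: PCHIP cannot overshoot the bracketing observations
  ts <- timeseries(c(0, NA, 2), dt = 1)
  out <- interpolate_missing(ts)
  expect_false(any(out$missing))
  expect_gte(out$values[2L], 0)
  expect_lte(out$values[2L], 2)
  expect_identical(out$values[c(1L, 3L)], c(0, 2))

  # constant data stays constant
  out <- interpolate_missing(timeseries(c(5, NA, NA, 5), dt = 1))
  expect_equal(out$values, rep(5, 4))

  # edge gaps extend the nearest observation
  out <- interpolate_missing(timeseries(c(NA, NA, 3, 4, NA), dt = 1))
  expect_equal(out$values, c(3, 3, 3, 4, 4))

  expect_error(interpolate_missing(timeseries(c(NA, NA), dt = 1)), "all samples")

  # observed samples are bit-identical on a larger gappy record
  withr::with_seed(4, {
    v <- cumsum(rnorm(200))
    gap <- sort(sample(2:199, 40))
    vm <- v; vm[gap] <- NA
    out <- interpolate_missing(timeseries(vm, dt = 1))
    expect_identical(out$values[-gap], v[-gap])
  })
})

test_that("downsampling decimates with anti-aliasing and no group delay", {
  ts <- timeseries(rnorm(5000), dt = 60)
  expect_identical(downsample(ts, 1L), ts)

  out <- downsample(ts, 10L)
  expect_equal(out$dt, 600)
  expect_equal(length(out), 500L)

  # a sinusoid well inside the new passband keeps its amplitude (within 1%)
  # and, because filtering is zero-phase, its phase
  t <- seq_len(6000)
  s <- timeseries(sin(2 * pi * t / 400), dt = 1)
  out <- downsample(s, 10L)
  ref <- sin(2 * pi * t[seq(1, 6000, 10)] / 400)
  mid <- 100:450
  expect_lt(max(abs(out$values[mid] - ref[mid])), 0.01)

  expect_error(downsample(timeseries(c(1, NA, 3), dt = 1), 2L), "missing")
  expect_error(downsample(timeseries(rnorm(50), dt = 1), 10L), "too short")

  # chained decimation lands on the same sampling interval as one step
  a <- downsample(downsample(ts, 2L), 5L)
  b <- downsample(ts, 10L)
  expect_equal(a$dt, b$dt)
})

test_that("sliding windows advance by the overlap-determined stride", {
  ts <- timeseries(1:10, dt = 1)
  w <- sliding_windows(ts, 4L, 0.5)
  expect_identical(attr(w, "starts"), c(1L, 3L, 5L, 7L))
  expect_true(all(vapply(w, length, 1L) == 4L))

  w <- sliding_windows(ts, 4L, 0)
  expect_identical(attr(w, "starts"), c(1L, 5L))   # trailing partial dropped

  # floor((n - w) / stride) + 1 windows at 50% overlap
  ts <- timeseries(rnorm(400), dt = 1)
  w <- sliding_windows(ts, 100L, 0.5)
  expect_length(w, floor((400 - 100) / 50) + 1)

  # interior samples are covered by 1/(1 - overlap) windows
  counts <- integer(400)
  for (s in attr(w, "starts")) counts[s:(s + 99L)] <- counts[s:(s + 99L)] + 1L
  expect_true(all(counts[100:300] == 2L))

  expect_error(sliding_windows(ts, 1L), ">= 2")
  expect_error(sliding_windows(ts, 500L), "longer")
})

test_that("standardization gives exact zero mean and unit variance", {
  ts <- standardize(timeseries(c(1, 2, 3), dt = 1))
  expect_equal(mean(ts$values), 0)
  expect_equal(sd(ts$values), 1)
  # idempotent up to floating tolerance
  expect_equal(standardize(ts)$values, ts$values, tolerance = 1e-12)
  expect_error(standardize(timeseries(rep(2, 5), dt = 1)), "constant")
})

test_that("delay embedding enumerates consecutive blocks", {
  b <- embed_blocks(c(1, 2, 3, 4), d = 2L)
  expect_identical(unname(b[, 1]), c(1, 2, 3))
  expect_identical(unname(b[, 2]), c(2, 3, 4))

  # d = 1 with no shift reproduces the series
  v <- rnorm(20)
  expect_identical(as.numeric(embed_blocks(v, 1L)), v)

  expect_error(embed_blocks(1:3, d = 5L), "usable")

  # aligned embeddings pair x-block at i with y-block at i + delay
  x <- 1:10; y <- 101:110
  al <- embed_aligned(x, y, d = 3L, delay = 2L)
  expect_identical(nrow(al$x), nrow(al$y))
  expect_identical(unname(al$x[1, ]), c(1, 2, 3))
  expect_identical(unname(al$y[1, ]), c(103, 104, 105))
  # negative delay shifts the other way
  al <- embed_aligned(x, y, d = 3L, delay = -2L)
  expect_identical(unname(al$x[1, ]), c(3, 4, 5))
  expect_identical(unname(al$y[1, ]), c(101, 102, 103))
})
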