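#' Linear-phase windowed-sinc low-pass filter taps
#'
#' Designs the FIR low-pass used by the packaged validation channel: a
#' Hamming-windowed sinc of `n_taps` coefficients with cutoff expressed as a
#' fraction of the Nyquist frequency.  Being symmetric, the filter delays
#' its input by exactly `(n_taps - 1) / 2` samples, which is the ground-truth
#' latency the CMIF must recover.
#'
#' The default cutoff, 0.19 of Nyquist, is anchored to the worked example of
#' the validation sweep: with ten log-spaced noise variances from 0.0025 to
#' 2.26 it places the fourth operating point (in ascending capacity) at an
#' analytic capacity of about 220 bits/s with millisecond sampling.
#'
#' @param n_taps number of coefficients (odd lengths give integer group
#'   delay); `n_taps = 1` is the identity filter.
#' @param cutoff_fraction cutoff as a fraction of Nyquist, in (0, 1).
#' @return Numeric vector of taps with unit DC gain.
#' @export
make_lowpass_filter <- function(n_taps = 41L, cutoff_fraction = 0.19) {
  n_taps <- as.integer(n_taps)
  if (n_taps < 1L) stop("n_taps must be >= 1")
  if (cutoff_fraction <= 0 || cutoff_fraction >= 1)
    stop("cutoff_fraction must be in (0, 1)")
  if (n_taps == 1L) return(1)
  b <- as.numeric(signal::fir1(n_taps - 1L, cutoff_fraction, type = "low"))
  b / sum(b)   # exact unit gain at DC
}

#' Specification of a simulated Gaussian channel
#'
#' Bundles everything that defines the validation channel: the FIR taps
#' `a(i)` applied to the standard-normal input, the variance of the additive
#' Gaussian output noise `z(t)`, the number of input samples, the sampling
#' interval and the generator seed.  The analytic information capacity of
#' the channel follows from the taps and the noise variance alone
#' ([analytic_capacity()]).
#'
#' @param filter_taps FIR coefficients; at least one non-zero.
#' @param noise_variance variance of the additive Gaussian noise, >= 0.
#' @param n number of input samples (>= 2).
#' @param dt sampling interval in seconds.
#' @param seed integer generator seed.
#' @return An object of class `"channel_spec"`.
#' @export
channel_spec <- function(filter_taps = make_lowpass_filter(),
                         noise_variance = 0.025, n = 40000L, dt = 0.001,
                         seed = 1L) {
  filter_taps <- as.numeric(filter_taps)
  if (length(filter_taps) < 1L || all(filter_taps == 0))
    stop("need at least one non-zero filter tap")
  if (noise_variance < 0) stop("noise_variance must be >= 0")
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2")
  if (dt <= 0) stop("dt must be positive")
  structure(list(filter_taps = filter_taps, noise_variance = noise_variance,
                 n = n, dt = dt, seed = as.integer(seed)),
            class = "channel_spec")
}

#' @export
print.channel_spec <- function(x, ...) {
  cat(sprintf("<channel_spec: %d taps, noise var %.4g, n = %d, dt = %g s, seed %d>\n",
              length(x$filter_taps), x$noise_variance, x$n, x$dt, x$seed))
  invisible(x)
}

#' Simulate the filtered-Gaussian validation channel
#'
#' Draws an i.i.d. standard-normal input `x(t)` and produces the output
#' `y(t) = sum_i a(i) x(t - i) + z(t)` with `z` i.i.d. Gaussian noise of the
#' specified variance.  The leading samples of `y` that would require input
#' history before the start of the record are dropped from both series
#' equally, so the returned pair is aligned sample-for-sample.
#'
#' @param spec a [channel_spec()].
#' @return List with [timeseries] elements `x` and `y`, each of length
#'   `n - (length(filter_taps) - 1)`.
#' @export
simulate_gaussian_channel <- function(spec) {
  stopifnot(inherits(spec, "channel_spec"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  m <- length(spec$filter_taps) - 1L
  if (spec$n - m < 2L) stop("n too small for the filter length")
  x <- stats::rnorm(spec$n)
  y <- as.numeric(stats::filter(x, spec$filter_taps, method = "convolution",
                                sides = 1L))
  if (spec$noise_variance > 0)
    y <- y + stats::rnorm(spec$n, sd = sqrt(spec$noise_variance))
  keep <- (m + 1L):spec$n
  list(x = timeseries(x[keep], spec$dt, label = "channel input"),
       y = timeseries(y[keep], spec$dt, label = "channel output"))
}

#' Welch magnitude-squared coherence
#'
#' Estimates the frequency-resolved squared coherence between two signals
#' from segment-averaged periodograms (Hann-tapered segments with fractional
#' overlap).  Coherence quantifies the linear dependence between the signals
#' at each frequency and feeds the Gaussian-channel information capacity.
#'
#' @param x,y [timeseries] (or numeric vectors; then `dt` is required) of
#'   equal length.
#' @param segment_length samples per segment (power of two recommended).
#' @param overlap fractional overlap between segments, in `[0, 1)`.
#' @param dt sampling interval if `x` is a plain vector.
#' @return List with `frequencies` (Hz, spanning (0, Nyquist]), `coherence`
#'   (clipped to `[0, 1 - 1e-10]`), `segments` (number averaged).  Fewer
#'   than 8 segments trigger a bias warning.
#' @export
coherence_function <- function(x, y, segment_length = 2048L, overlap = 0.5,
                               dt = NULL) {
  vx <- if (inherits(x, "timeseries")) x$values else as.numeric(x)
  vy <- if (inherits(y, "timeseries")) y$values else as.numeric(y)
  if (is.null(dt)) {
    if (!inherits(x, "timeseries")) stop("dt required for plain vectors")
    dt <- x$dt
  }
  if (length(vx) != length(vy)) stop("series lengths differ")
  segment_length <- as.integer(segment_length)
  n <- length(vx)
  if (n < 2L * segment_length)
    stop("need at least two segments of data")
  step <- max(1L, as.integer(round(segment_length * (1 - overlap))))
  starts <- seq.int(1L, n - segment_length + 1L, by = step)
  if (length(starts) < 8L)
    warning("fewer than 8 segments: coherence estimate is biased upward")
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(segment_length) / (segment_length + 1))
  nf <- segment_length %/% 2L
  sxx <- syy <- numeric(nf)
  sxy <- complex(nf)
  for (s in starts) {
    i <- s:(s + segment_length - 1L)
    fx <- stats::fft(w * (vx[i] - mean(vx[i])))[2:(nf + 1L)]
    fy <- stats::fft(w * (vy[i] - mean(vy[i])))[2:(nf + 1L)]
    sxx <- sxx + Mod(fx)^2
    syy <- syy + Mod(fy)^2
    sxy <- sxy + Conj(fx) * fy
  }
  coh <- Mod(sxy)^2 / (sxx * syy)
  coh <- pmin(pmax(coh, 0), 1 - 1e-10)
  freqs <- (1:nf) / (segment_length * dt)
  list(frequencies = freqs, coherence = coh, segments = length(starts))
}

#' Coherence-based Gaussian information capacity
#'
#' Shannon capacity of a linear Gaussian channel from its squared coherence:
#' `C = -integral over (0, Nyquist] of log2(1 - coherence(f)) df`, evaluated
#' by the trapezoid rule on the supplied grid (the strip between 0 and the
#' first grid frequency is taken at the first coherence value).
#'
#' @param frequencies frequency grid in Hz, strictly increasing, spanning
#'   (0, Nyquist].
#' @param coherence squared coherence on the grid, each value in `[0, 1)`.
#' @return Capacity in bits/s.
#' @export
gaussian_capacity <- function(frequencies, coherence) {
  if (length(frequencies) != length(coherence)) stop("grid length mismatch")
  if (any(coherence < 0)) stop("coherence must be >= 0")
  if (any(coherence >= 1))
    stop("coherence reaches 1: capacity diverges; clip the estimate first")
  integrand <- -log2(1 - coherence)
  pracma::trapz(frequencies, integrand) + frequencies[1L] * integrand[1L]
}

#' Analytic capacity of a specified channel
#'
#' Ground-truth information capacity of a [channel_spec()], from the exact
#' filter frequency response rather than estimated spectra: with unit input
#' variance the squared coherence is `|A(f)|^2 / (|A(f)|^2 + noise_variance)`
#' where `A(f)` is the filter transfer function, and the capacity integral is
#' evaluated on a fine grid.
#'
#' @param spec a [channel_spec()] with `noise_variance > 0`.
#' @param n_freq number of grid points up to Nyquist.
#' @return Capacity in bits/s.
#' @export
analytic_capacity <- function(spec, n_freq = 4096L) {
  stopifnot(inherits(spec, "channel_spec"))
  if (spec$noise_variance <= 0)
    stop("zero noise variance: capacity is infinite")
  nyq <- 1 / (2 * spec$dt)
  freqs <- seq_len(n_freq) / n_freq * nyq
  j <- seq_along(spec$filter_taps) - 1
  a2 <- vapply(freqs, function(f)
    Mod(sum(spec$filter_taps * exp(-2i * pi * f * j * spec$dt)))^2, numeric(1))
  coh <- a2 / (a2 + spec$noise_variance)
  gaussian_capacity(freqs, coh)
}

#' Noise variance giving a target analytic capacity
#'
#' Inverts [analytic_capacity()] in the noise variance by bisection, handy
#' for placing a validation channel at a prescribed capacity.
#'
#' @param target_capacity desired capacity in bits/s.
#' @param filter_taps,dt channel filter and sampling interval.
#' @return Noise variance (scalar).
#' @export
calibrate_noise_variance <- function(target_capacity,
                                     filter_taps = make_lowpass_filter(),
                                     dt = 0.001) {
  f <- function(lv) {
    sp <- channel_spec(filter_taps, exp(lv), n = 100L, dt = dt)
    analytic_capacity(sp) - target_capacity
  }
  r <- stats::uniroot(f, lower = log(1e-8), upper = log(1e4), tol = 1e-10)
  exp(r$root)
}

#' Validation sweep: estimated rate against analytic capacity
#'
#' Simulates the validation channel over a grid of additive-noise variances,
#' runs the full information-rate pipeline on each realization, and tabulates
#' the estimated rate against the analytic capacity oracle together with a
#' Welch-coherence capacity estimate from the same realization.  The
#' agreement limit -- the largest capacity below which the estimated rate
#' tracks the capacity within the given relative tolerance -- summarises
#' where the estimator's sample-size-limited plateau sets in.
#'
#' @param noise_variances noise-variance grid; default 10 log-spaced values
#'   from 0.0025 to 2.26.
#' @param n,dt,filter_taps channel configuration (input length, sampling
#'   interval, FIR taps).
#' @param k neighbour count passed to the estimator.
#' @param seed seed for the channel realizations and jitter.
#' @param tolerance relative-error threshold defining agreement.
#' @param welch compute the Welch-coherence capacity column (slightly
#'   slower)?
#' @param d_stride,d_tail,max_lag,cmif_points estimator grid economies for
#'   the sweep: the MI curve is evaluated on every third block length and
#'   stops at the detected latency, the CMIF scan is confined to lags just
#'   past the filter length (the group delay cannot exceed it) and is
#'   computed on a 30000-sample stride of the overlap; all are forwarded to
#'   [information_rate()] and can be overridden.
#' @param ... further arguments passed to [information_rate()].
#' @return A data.frame with columns `noise_variance`, `analytic_capacity`,
#'   `welch_capacity`, `estimated_rate`, `rel_error`, sorted as supplied,
#'   with the agreement limit in attribute `"agreement_limit"` (bits/s).
#' @export
validate_channel <- function(noise_variances = NULL, n = 40000L, dt = 0.001,
                             filter_taps = make_lowpass_filter(), k = 3L,
                             seed = 1L, tolerance = 0.1, welch = TRUE,
                             d_stride = 3L, d_tail = 0L,
                             max_lag = length(filter_taps) + 4L,
                             cmif_points = 30000L, ...) {
  if (is.null(noise_variances))
    noise_variances <- exp(seq(log(0.0025), log(2.26), length.out = 10L))
  rows <- lapply(seq_along(noise_variances), function(i) {
    sp <- channel_spec(filter_taps, noise_variances[i], n = n, dt = dt,
                       seed = seed * 1000L + i)
    sim <- simulate_gaussian_channel(sp)
    cap <- analytic_capacity(sp)
    wc <- if (welch) {
      ch <- coherence_function(sim$x, sim$y)
      gaussian_capacity(ch$frequencies, ch$coherence)
    } else NA_real_
    fit <- information_rate(sim$x, sim$y, k = k, seed = sp$seed,
                            d_stride = d_stride, d_tail = d_tail,
                            max_lag = max_lag, cmif_points = cmif_points, ...)
    data.frame(noise_variance = noise_variances[i],
               analytic_capacity = cap,
               welch_capacity = wc,
               estimated_rate = fit$rate_bits_per_s,
               rel_error = abs(fit$rate_bits_per_s - cap) / cap)
  })
  out <- do.call(rbind, rows)
  attr(out, "agreement_limit") <- agreement_limit(out, tolerance)
  out
}

#' Agreement limit of a validation sweep
#'
#' Largest analytic capacity `c*` in the sweep such that every operating
#' point with capacity at most `c*` has relative error below the tolerance.
#' Returns 0 when even the lowest-capacity point disagrees.
#'
#' @param sweep data.frame from [validate_channel()].
#' @param tolerance relative-error threshold (default 10%).
#' @return Capacity in bits/s (scalar).
#' @export
agreement_limit <- function(sweep, tolerance = 0.1) {
  ord <- order(sweep$analytic_capacity)
  caps <- sweep$analytic_capacity[ord]
  ok <- sweep$rel_error[ord] < tolerance
  bad <- which(!ok)
  if (length(bad) == 0L) return(caps[length(caps)])
  if (bad[1L] == 1L) return(0)
  caps[bad[1L] - 1L]
}
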