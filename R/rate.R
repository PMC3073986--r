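#' PCA conditioning of aligned block embeddings
#'
#' Reduces a pair of aligned d-dimensional block embeddings to their `N`
#' leading principal components before MI estimation.  The eigenbasis is
#' computed from the covariance of the (latency-shifted) second signal's
#' blocks and applied to both signals, so the two projected sets live in the
#' same coordinates; this focuses the estimator on the components that carry
#' the signal variance and keeps the kNN statistics in a manageable
#' dimension.  An alternative per-signal basis (each signal projected on its
#' own eigenvectors) is available behind `basis = "each"`.
#'
#' @param x_blocks,y_blocks aligned block matrices with equal row counts and
#'   `d` columns (see [embed_aligned()]); `y_blocks` is the shifted signal
#'   that defines the basis.
#' @param N number of components to keep, `1 <= N <= d`.
#' @param basis `"y"` (default: y-eigenvectors applied to both) or `"each"`.
#' @return List with `x` and `y` (projected matrices, `N` columns),
#'   `variance_explained` (fraction of total y-block eigenvalue mass in the
#'   top `N`), and `eigenvalue_fractions` (all d fractions).
#' @export
pca_condition <- function(x_blocks, y_blocks, N, basis = c("y", "each")) {
  basis <- match.arg(basis)
  if (nrow(x_blocks) != nrow(y_blocks)) stop("row counts differ")
  d <- ncol(y_blocks)
  if (ncol(x_blocks) != d) stop("block dimensions differ")
  N <- as.integer(N)
  if (N < 1L || N > d) stop("N must be in 1..d")
  ey <- eigen(stats::cov(y_blocks), symmetric = TRUE)
  frac <- ey$values / sum(ey$values)
  if (N > sum(ey$values > max(ey$values) * 1e-12))
    stop("N exceeds the rank of the block covariance")
  vy <- ey$vectors[, seq_len(N), drop = FALSE]
  vx <- if (basis == "y") vy else
    eigen(stats::cov(x_blocks), symmetric = TRUE)$vectors[, seq_len(N), drop = FALSE]
  center <- function(m) sweep(m, 2L, colMeans(m))
  list(x = center(x_blocks) %*% vx,
       y = center(y_blocks) %*% vy,
       variance_explained = sum(frac[seq_len(N)]),
       eigenvalue_fractions = frac)
}

#' Number of principal components for a variance target
#'
#' Smallest `N` whose cumulative eigenvalue fraction reaches the threshold
#' (default 98% of the variance, the recommended working point; too few
#' components bias the rate downward, far too many invite a spurious linear
#' region at large block lengths).
#'
#' For an output carrying broadband observation noise the plain cumulative
#' rule degenerates (the noise floor spreads eigenvalue mass over all
#' components and forces `N` toward `d`), so it must be loosened: with
#' `above_floor = TRUE` the threshold is applied to the eigenvalue mass in
#' excess of the noise floor, taken as the median eigenvalue, which counts
#' only the signal-bearing components.
#'
#' @param eigenvalue_fractions eigenvalue fractions summing to 1 (descending).
#' @param threshold cumulative-variance target in (0, 1].
#' @param above_floor apply the threshold to the above-noise-floor excess
#'   mass rather than the total (default `FALSE`).
#' @return Integer `N >= 1`.
#' @export
suggest_N <- function(eigenvalue_fractions, threshold = 0.98,
                      above_floor = FALSE) {
  if (abs(sum(eigenvalue_fractions) - 1) > 1e-6)
    stop("eigenvalue fractions must sum to 1")
  f <- eigenvalue_fractions
  if (above_floor) {
    ex <- pmax(f - stats::median(f), 0)
    # a near-flat spectrum has no compressible structure; fall back to the
    # plain cumulative rule rather than pretending one component suffices
    if (sum(ex) >= 0.05) f <- ex / sum(ex)
  }
  which(cumsum(f) >= threshold - 1e-12)[1L]
}

#' Mutual information as a function of embedding dimension
#'
#' Core curve of the rate estimator: for each block length `d`, the two
#' series are delay-embedded (the second shifted by the latency `delay`),
#' conditioned to `N` principal components (basis re-fit at every `d`), and
#' their kNN mutual information estimated.  Under the finite-memory
#' (Markov) approximation the curve grows linearly in `d` once `d` exceeds
#' the process memory, with slope equal to the per-sample information rate.
#'
#' @param x,y [timeseries] or numeric vectors of equal length (already
#'   standardized/jittered by the calling pipeline, or raw).
#' @param d_values strictly increasing block lengths to evaluate.
#' @param delay latency shift (samples) applied to `y`.
#' @param N principal components kept at every `d` (`N <= min(d_values)`).
#' @param k neighbour count for the MI estimates.
#' @param basis PCA basis mode, see [pca_condition()].
#' @param whiten rescale every projected component to unit variance before
#'   the MI estimate (default `TRUE`).  Mutual information is invariant
#'   under per-coordinate scaling, but the max-norm neighbourhoods of the
#'   kNN estimator behave best when no component dominates the metric.
#' @param theiler dynamic-correlation exclusion window for the kNN search,
#'   in samples (0, the default, searches all blocks), or `"auto"` (twice
#'   the block length at each `d`).  Consecutive overlapping blocks are
#'   serially dependent samples of the embedded distribution; excluding
#'   temporal neighbours removes the resulting recurrence bias of the kNN
#'   statistics at low signal-to-noise, at the price of deviating from the
#'   plain estimator and losing part of the small-`N` compensation it
#'   enjoys.  See the methods vignette before changing this.
#' @return An object of class `"mi_curve"`: data.frame with columns `d`,
#'   `mi_bits`, `variance_explained`, plus attributes `delay`, `N`, `k`,
#'   `dt`, `n`.
#' @export
mi_curve <- function(x, y, d_values, delay = 0L, N = 1L, k = 3L,
                     basis = "y", whiten = TRUE, theiler = 0L) {
  vx <- if (inherits(x, "timeseries")) x$values else as.numeric(x)
  vy <- if (inherits(y, "timeseries")) y$values else as.numeric(y)
  dt <- if (inherits(x, "timeseries")) x$dt else NA_real_
  if (length(vx) != length(vy)) stop("series lengths differ")
  if (length(vx) < 10000L)
    warning("fewer than 10000 samples; multivariate MI estimates may be unreliable")
  d_values <- sort(unique(as.integer(d_values)))
  if (any(d_values < N)) stop("every d must be >= N")
  rows <- lapply(d_values, function(d) {
    emb <- embed_aligned(vx, vy, d, delay)
    pc <- pca_condition(emb$x, emb$y, N, basis = basis)
    px <- pc$x; py <- pc$y
    if (whiten) {
      px <- sweep(px, 2L, apply(px, 2L, stats::sd), `/`)
      py <- sweep(py, 2L, apply(py, 2L, stats::sd), `/`)
    }
    w <- if (identical(theiler, "auto")) 2L * d else as.integer(theiler)
    mi <- knn_mutual_information(px, py, k = k, theiler = w)
    data.frame(d = d, mi_bits = mi$value,
               variance_explained = pc$variance_explained)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("mi_curve", "data.frame")
  attr(out, "delay") <- as.integer(delay)
  attr(out, "N") <- as.integer(N)
  attr(out, "k") <- as.integer(k)
  attr(out, "dt") <- dt
  attr(out, "n") <- length(vx)
  out
}

#' @export
print.mi_curve <- function(x, ...) {
  cat(sprintf("<mi_curve: d = %d..%d, N = %d, k = %d, delay = %d>\n",
              min(x$d), max(x$d), attr(x, "N"), attr(x, "k"), attr(x, "delay")))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Information rate from the linear part of an MI curve
#'
#' Ordinary least-squares line through the `(d, MI)` points inside the fit
#' range.  The slope is the information rate in bits per sample
#' (bits/transmission); dividing by the sampling interval converts it to
#' bits per second.  The intercept absorbs the initial-condition constant of
#' the underlying recursion and carries no further interpretation.  A
#' negative slope (possible for independent signals, where the curve is
#' noise around zero) is reported as-is with a warning flag.
#'
#' @param curve an `"mi_curve"` (or data.frame with `d` and `mi_bits`).
#' @param fit_range length-2 vector `(d_min, d_max)`; points with
#'   `d_min <= d <= d_max` enter the fit (at least 2 required).
#' @param dt sampling interval in seconds; defaults to the curve's.
#' @return An object of class `"rate_estimate"`: list with
#'   `slope_bits_per_sample`, `rate_bits_per_s`, `intercept`, `fit_range`,
#'   `r_squared`, `slope_se`, `n_points`, `negative_slope`.
#' @export
fit_rate <- function(curve, fit_range = range(curve$d), dt = attr(curve, "dt")) {
  if (is.null(dt) || is.na(dt)) stop("sampling interval dt is required")
  sel <- curve$d >= fit_range[1L] & curve$d <= fit_range[2L]
  if (sum(sel) < 2L) stop("fewer than 2 curve points inside the fit range")
  d <- curve$d[sel]; mi <- curve$mi_bits[sel]
  fit <- stats::lm(mi ~ d)
  slope <- unname(stats::coef(fit)[2L])
  sm <- suppressWarnings(summary(fit))   # exact fits trip summary.lm
  se <- sm$coefficients[2L, 2L]
  r2 <- if (length(d) > 2L) sm$r.squared else 1
  if (slope < 0) warning("negative fitted slope: no net information transfer detected")
  structure(list(
    slope_bits_per_sample = slope,
    rate_bits_per_s = slope / dt,
    intercept = unname(stats::coef(fit)[1L]),
    fit_range = c(fit_range[1L], fit_range[2L]),
    r_squared = r2,
    slope_se = se,
    n_points = length(d),
    negative_slope = slope < 0
  ), class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("rate = %.4g bits/s  (slope %.4g bits/sample over d = %d..%d, R^2 = %.4f)\n",
              x$rate_bits_per_s, x$slope_bits_per_sample,
              x$fit_range[1L], x$fit_range[2L], x$r_squared))
  invisible(x)
}

#' Automatic fit range for the MI curve
#'
#' Implements the recipe for choosing the linear-fit window from the local
#' increments of the MI curve.  Below the joint process memory the curve is
#' still bending upward (increments rising); beyond the latency, and
#' wherever the kNN estimates saturate, it bends over (increments falling).
#' The linear region is therefore the contiguous run of block lengths,
#' inside `[max(L, N), delay]`, whose (lightly smoothed) per-`d` increment
#' stays within a fraction `slack` of the largest increment.  Fitting that
#' run operationalizes "from where the curve becomes linear to where it
#' deviates from linearity" without visual judgment.
#'
#' Two pathologies are detected rather than silently fitted: a curve with no
#' such run (too few principal components -- the curve never straightens)
#' raises a "no clear linear region" error, and a second, steeper straight
#' stretch beyond the latency (too many components) sets the
#' `second_region` attribute.
#'
#' @param curve an `"mi_curve"`.
#' @param delay latency `T` in samples; defaults to the curve's.
#' @param L memory order; the lower fit edge is at least `max(L, N)`.
#' @param slack admissible fractional drop of the local increment relative
#'   to its maximum (default 0.25).
#' @return Length-2 integer vector `(d_min, d_max)` with attribute
#'   `"second_region"` (logical).
#' @export
suggest_fit_range <- function(curve, delay = attr(curve, "delay"),
                              L = attr(curve, "N"), slack = 0.25) {
  if (nrow(curve) < 4L) stop("need at least 4 curve points")
  N <- attr(curve, "N")
  d_floor <- max(L, N)
  d_cap <- if (!is.null(delay) && delay >= d_floor + 1L) delay else max(curve$d)
  adm <- which(curve$d >= d_floor & curve$d <= d_cap)
  if (length(adm) < 3L)
    stop("fewer than 3 admissible d values between max(L, N) and the delay")
  d <- curve$d[adm]; mi <- curve$mi_bits[adm]
  m <- length(adm)

  g <- diff(mi) / diff(d)                      # local increments, bits per d
  gs <- vapply(seq_along(g), function(i)       # 3-point running mean
    mean(g[max(1L, i - 1L):min(length(g), i + 1L)]), numeric(1))
  gmax <- max(gs)
  if (gmax <= 0)
    stop("no clear linear region in the MI curve (no rising stretch); ",
         "increase N or inspect the curve")
  # when estimator noise dominates the increment differences the whole
  # admissible range is effectively linear: widen the window accordingly
  sigma_mi <- if (m >= 4L) stats::mad(diff(mi, differences = 2L)) / sqrt(6) else 0
  sigma_g <- sqrt(2 / 3) * sigma_mi / mean(diff(d))
  ok <- gs >= gmax - max(slack * gmax, 3 * sigma_g)
  imax <- which.max(gs)
  lo <- imax; while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
  hi <- imax; while (hi < length(gs) && ok[hi + 1L]) hi <- hi + 1L
  # increments index segments [j, j+1]; the window covers points lo..hi+1
  if (hi - lo + 1L < 2L && m >= 5L)
    stop("no clear linear region in the MI curve; ",
         "increase N (too few principal components) or inspect the curve")
  # saturation inside the admissible range: a narrow rising stretch whose
  # continuation levels off well before the latency is not a rate estimate
  # (the signature of too few principal components)
  post <- gs[seq_along(gs) > hi]
  span_frac <- (d[hi + 1L] - d[lo]) / max(d[m] - d[1L], 1L)
  if (length(post) >= 2L && mean(gs[lo:hi]) > 0 &&
      mean(post) < 0.4 * mean(gs[lo:hi]) && span_frac < 0.6)
    stop("no clear linear region: the MI curve saturates inside the ",
         "admissible range; increase N (too few principal components)")
  out <- c(d[lo], d[hi + 1L])

  # beyond the latency the curve should level off; a second straight,
  # steeper stretch there indicates too many principal components
  tail_idx <- which(curve$d > d_cap)
  second <- FALSE
  if (length(tail_idx) >= 3L) {
    td <- curve$d[tail_idx]; tmi <- curve$mi_bits[tail_idx]
    tslope <- stats::coef(stats::lm(tmi ~ td))[2L]
    main_slope <- stats::coef(stats::lm(mi[lo:(hi + 1L)] ~ d[lo:(hi + 1L)]))[2L]
    if (is.finite(tslope) && tslope > 0 && tslope > 1.3 * max(main_slope, 0))
      second <- TRUE
  }
  attr(out, "second_region") <- second
  out
}

#' Estimate the information transfer rate between two signals
#'
#' The full estimation pipeline, assuming only stationarity and ergodicity
#' of the two signals: (1) standardize and add tie-breaking jitter; (2) scan
#' the cross mutual information function to detect the latency `T` between
#' the signals; (3) take the memory order `L` from the half-width of the
#' CMIF peak; (4) choose the number of principal components `N` so the
#' retained eigenvalue mass of the shifted output blocks reaches the
#' variance threshold; (5) compute the MI curve over block lengths `d`,
#' PCA-conditioned at every `d`; (6) fit a line to the curve between
#' `max(L, N)` and `T` and read the information rate off its slope.  All
#' intermediates are kept on the returned object for audit.
#'
#' @param x,y input and output signals: [timeseries] objects or numeric
#'   vectors (then `dt` is required) of equal length.  At least 10000
#'   samples are recommended for the multivariate MI statistics.
#' @param dt sampling interval in seconds when `x`, `y` are plain vectors.
#' @param k neighbour count of the MI estimator (2--6 work well; larger k
#'   underestimates high MI, k = 1 is noisy).
#' @param delay latency in samples, or `"auto"` (CMIF argmax).
#' @param n_pcs number of principal components `N`, or `"auto"` (smallest N
#'   reaching `variance_threshold` at the lower fit edge).
#' @param L memory order, or `"auto"` (CMIF peak half-width).  When the CMIF
#'   shows no significant peak (independent signals) the pipeline falls back
#'   to `delay = 0`, `L = 5` with a warning and reports the (null) rate.
#' @param d_values block lengths for the MI curve; default every `d_stride`-th
#'   integer from `max(2, N)` to `delay + 5` (so the saturation beyond the
#'   latency stays visible for diagnostics).
#' @param d_stride spacing of the default `d_values` grid (default 1; a
#'   coarser grid costs little slope accuracy and halves the computation).
#' @param d_tail how far the default grid extends beyond the latency
#'   (default 5 samples), where the curve's saturation and the
#'   too-many-components pathology are visible; 0 stops the grid at the
#'   latency, which is enough for the rate fit itself.
#' @param fit_range explicit `(d_min, d_max)` for the line fit, or `NULL`
#'   for [suggest_fit_range()]; if no linear region is found the fit falls
#'   back to the admissible range with a warning.
#' @param variance_threshold cumulative eigenvalue fraction target for
#'   `n_pcs = "auto"` (default 0.98).
#' @param max_lag CMIF scan limit in samples; default
#'   `max(100, 2 * delay)` when the delay is given, else 100.
#' @param cmif_points per-lag sample budget of the CMIF scan (evenly
#'   strided subsample of the overlap); `Inf` uses every sample.
#' @param standardize standardize both signals first (default `TRUE`).
#' @param jitter add seeded tie-breaking noise (default `TRUE`).
#' @param seed single seed governing all randomness (jitter).
#' @param basis PCA basis mode, see [pca_condition()].
#' @return An object of class `"inforate_fit"`; see
#'   [print.inforate_fit()], [summary.inforate_fit()], [coef.inforate_fit()],
#'   [plot.inforate_fit()].
#' @examples
#' \donttest{
#' sp <- channel_spec(noise_variance = 0.05, n = 20000, seed = 7)
#' sim <- simulate_gaussian_channel(sp)
#' fit <- information_rate(sim$x, sim$y, seed = 7)
#' fit
#' analytic_capacity(sp)   # oracle the estimate should track
#' }
#' @export
information_rate <- function(x, y, dt = NULL, k = 3L, delay = "auto",
                             n_pcs = "auto", L = "auto", d_values = NULL,
                             d_stride = 1L, d_tail = 5L, fit_range = NULL,
                             variance_threshold = 0.98,
                             max_lag = NULL, cmif_points = Inf,
                             standardize = TRUE,
                             jitter = TRUE, seed = 1L, basis = "y") {
  if (!inherits(x, "timeseries")) {
    if (is.null(dt)) stop("dt is required when x, y are plain vectors")
    x <- timeseries(as.numeric(x), dt)
    y <- timeseries(as.numeric(y), dt)
  }
  if (!inherits(y, "timeseries")) y <- timeseries(as.numeric(y), x$dt)
  if (length(x$values) != length(y$values)) stop("series lengths differ")
  if (abs(x$dt - y$dt) > 1e-12 * x$dt) stop("inconsistent dt between signals")
  if (any(x$missing) || any(y$missing))
    stop("interpolate missing samples first (see interpolate_missing)")
  n <- length(x$values)
  if (n < 10000L)
    warning("fewer than 10000 samples; estimates may be unreliable")
  notes <- character()

  if (standardize) { x <- standardize(x); y <- standardize(y) }
  if (jitter) {
    x <- add_jitter(x, seed = seed)
    y <- add_jitter(y, seed = seed + 1L)
  }

  # -- latency and memory order from the CMIF ------------------------------
  auto_delay <- identical(delay, "auto")
  auto_L <- identical(L, "auto")
  cmif <- NULL
  if (auto_delay || auto_L) {
    if (is.null(max_lag))
      max_lag <- if (!auto_delay) max(100L, 2L * abs(as.integer(delay))) else 100L
    max_lag <- min(max_lag, floor(n / 4) - 1L)
    cmif <- cross_mi_function(x, y, max_lag = max_lag, k = max(k, 8L),
                              max_points = cmif_points)
  }
  if (auto_delay) delay <- cmif$delay
  delay <- as.integer(delay)
  if (auto_L) {
    L <- tryCatch(cmif_halfwidth(cmif), error = function(e) NA_integer_)
    if (is.na(L)) {
      # weak-peak second stage: a genuine latency peak spans several lags,
      # so it survives smoothing while per-lag estimator noise does not
      smoothed <- smooth_cmif(cmif, window = 5L)
      L <- tryCatch(max(1L, cmif_halfwidth(smoothed) - 4L),
                    error = function(e) NA_integer_)
      if (!is.na(L)) {
        if (auto_delay) delay <- smoothed$delay
        notes <- c(notes, "CMIF peak detected only after lag smoothing (low-SNR channel)")
      } else {
        notes <- c(notes, "no significant CMIF peak: signals look independent; using delay = 0, L = 5")
        warning("no significant CMIF peak; using delay = 0 and L = 5")
        if (auto_delay) delay <- 0L
        L <- 5L
      }
    }
  }
  L <- as.integer(L)

  # -- number of principal components, chosen where the fit will live ------
  if (identical(n_pcs, "auto")) {
    d_ref <- max(4L, if (delay > L) (L + delay) %/% 2L else L)
    emb <- embed_aligned(x, y, d_ref, delay)
    frac <- pca_condition(emb$x, emb$y, 1L, basis = basis)$eigenvalue_fractions
    n_pcs <- min(suggest_N(frac, variance_threshold, above_floor = TRUE), d_ref)
  }
  N <- as.integer(n_pcs)

  # -- MI curve ------------------------------------------------------------
  if (is.null(d_values)) {
    d_top <- max(delay + as.integer(d_tail), max(L, N) + 6L)
    d_values <- unique(c(seq.int(max(2L, N), d_top, by = as.integer(d_stride)),
                         d_top))
  }
  curve <- mi_curve(x, y, d_values = d_values, delay = delay, N = N, k = k,
                    basis = basis)

  # -- fit range and line fit ----------------------------------------------
  second_region <- FALSE
  if (is.null(fit_range)) {
    fr <- tryCatch(suggest_fit_range(curve, delay = delay, L = L),
                   error = function(e) e)
    if (inherits(fr, "error")) {
      notes <- c(notes, paste0("fit-range search failed (", conditionMessage(fr),
                               "); fitting the admissible range"))
      warning("no clear linear region; fitting the admissible range instead")
      d_min <- max(L, N)
      d_cap <- if (delay >= d_min + 1L) delay else max(curve$d)
      if (sum(curve$d >= d_min & curve$d <= d_cap) < 2L) d_cap <- max(curve$d)
      fit_range <- c(d_min, d_cap)
    } else {
      fit_range <- as.integer(fr)
      second_region <- isTRUE(attr(fr, "second_region"))
      if (second_region) {
        notes <- c(notes, "second linear region beyond the latency: N may be too large")
        warning("second linear region beyond the latency; N may be too large")
      }
    }
  }
  est <- withCallingHandlers(
    fit_rate(curve, fit_range = fit_range, dt = x$dt),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  structure(list(
    rate_bits_per_s = est$rate_bits_per_s,
    slope_bits_per_sample = est$slope_bits_per_sample,
    intercept = est$intercept,
    r_squared = est$r_squared,
    slope_se = est$slope_se,
    fit_range = est$fit_range,
    negative_slope = est$negative_slope,
    second_region = second_region,
    curve = curve,
    cmif = cmif,
    delay = delay, L = L, N = N, k = as.integer(k),
    n = n, dt = x$dt, seed = as.integer(seed),
    variance_threshold = variance_threshold,
    notes = notes,
    call = match.call()
  ), class = "inforate_fit")
}

#' @describeIn information_rate compact display of a fitted rate.
#' @param ... unused.
#' @export
print.inforate_fit <- function(x, ...) {
  cat("Information transfer rate estimate\n")
  cat(sprintf("  rate      : %.4g bits/s  (%.4g bits/sample)\n",
              x$rate_bits_per_s, x$slope_bits_per_sample))
  cat(sprintf("  fit       : d = %d..%d, R^2 = %.4f, slope SE = %.3g bits/sample\n",
              x$fit_range[1L], x$fit_range[2L], x$r_squared, x$slope_se))
  cat(sprintf("  params    : n = %d, dt = %g s, k = %d, T = %d, L = %d, N = %d\n",
              x$n, x$dt, x$k, x$delay, x$L, x$N))
  for (msg in x$notes) cat("  note      : ", msg, "\n", sep = "")
  invisible(x)
}

#' @describeIn information_rate full summary: parameters, MI curve, CMIF peak.
#' @param object an `"inforate_fit"`.
#' @export
summary.inforate_fit <- function(object, ...) {
  print(object)
  cat("\nMI curve:\n")
  print.data.frame(object$curve, row.names = FALSE, digits = 4)
  if (!is.null(object$cmif))
    cat(sprintf("\nCMIF: peak %.4f bits at lag %d (grid %d..%d)\n",
                max(object$cmif$mi_bits), object$cmif$delay,
                min(object$cmif$lags), max(object$cmif$lags)))
  invisible(object)
}

#' @describeIn information_rate slope (bits/sample) and intercept of the fit.
#' @export
coef.inforate_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope_bits_per_sample)
}

#' @describeIn information_rate MI-curve points with fitted values and
#'   residuals (fit-range points only).
#' @export
residuals.inforate_fit <- function(object, ...) {
  sel <- object$curve$d >= object$fit_range[1L] &
    object$curve$d <= object$fit_range[2L]
  object$curve$mi_bits[sel] -
    (object$intercept + object$slope_bits_per_sample * object$curve$d[sel])
}

#' @describeIn information_rate predicted MI (bits) from the fitted line at
#'   block lengths `newdata` (default: the curve's).
#' @param newdata block lengths at which to evaluate the fitted line.
#' @export
predict.inforate_fit <- function(object, newdata = object$curve$d, ...) {
  object$intercept + object$slope_bits_per_sample * as.numeric(newdata)
}

#' @describeIn information_rate diagnostic plot: MI versus d with the fitted
#'   line over the fit range and the detected latency marked.
#' @export
plot.inforate_fit <- function(x, ...) {
  graphics::plot(x$curve$d, x$curve$mi_bits, pch = 16,
                 xlab = "embedding dimension d", ylab = "MI (bits)", ...)
  sel <- x$curve$d >= x$fit_range[1L] & x$curve$d <= x$fit_range[2L]
  graphics::abline(x$intercept, x$slope_bits_per_sample, col = "grey40")
  graphics::points(x$curve$d[sel], x$curve$mi_bits[sel], pch = 16, col = "red")
  if (x$delay > min(x$curve$d))
    graphics::abline(v = x$delay, lty = 3)
  graphics::legend("topleft", bty = "n", legend = sprintf(
    "%.3g bits/s (d = %d..%d)", x$rate_bits_per_s,
    x$fit_range[1L], x$fit_range[2L]))
  invisible(x)
}

#' Machine-readable report of a fitted rate
#'
#' Flattens an `"inforate_fit"` into a list of plain vectors suitable for
#' `jsonlite::toJSON`, embedding the resolved parameter set, the MI curve,
#' the CMIF summary, the seed and the package version so a run can be
#' audited and reproduced.
#'
#' @param fit an `"inforate_fit"`.
#' @return A named list.
#' @export
as_report <- function(fit) {
  stopifnot(inherits(fit, "inforate_fit"))
  list(
    rate_bits_per_s = fit$rate_bits_per_s,
    slope_bits_per_sample = fit$slope_bits_per_sample,
    intercept = fit$intercept,
    r_squared = fit$r_squared,
    slope_se = fit$slope_se,
    fit_range = fit$fit_range,
    delay = fit$delay, L = fit$L, N = fit$N, k = fit$k,
    n = fit$n, dt = fit$dt, seed = fit$seed,
    variance_threshold = fit$variance_threshold,
    mi_curve = list(d = fit$curve$d, mi_bits = fit$curve$mi_bits,
                    variance_explained = fit$curve$variance_explained),
    cmif = if (!is.null(fit$cmif))
      list(lags = fit$cmif$lags, mi_bits = fit$cmif$mi_bits,
           delay = fit$cmif$delay),
    notes = fit$notes,
    package_version = as.character(utils::packageVersion("inforate"))
  )
}
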