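#' k-nearest-neighbour mutual information (Kraskov variant 1)
#'
#' Nonparametric mutual information between two multidimensional sample sets,
#' in bits, from k-th-neighbour distances: for each joint sample the
#' Chebyshev (max-norm) distance to its k-th nearest neighbour in the joint
#' space sets a radius, the numbers of marginal neighbours strictly inside
#' that radius are counted, and digamma terms of `k`, the marginal counts and
#' `n` are combined.  The estimate is symmetric in its arguments, invariant
#' under monotone affine rescaling of either signal, and may come out
#' slightly negative for independent data; negative values are returned
#' as-is.
#'
#' Exactly coincident joint samples make the k-th-neighbour distance zero and
#' the estimator undefined; such ties are an error.  For discrete-valued
#' data (e.g. quantized sensor readings) break them first with
#' [add_jitter()].
#'
#' @param xs,ys numeric matrices (samples in rows) or vectors, with the same
#'   number of samples.
#' @param k number of neighbours, `1 <= k < n`; small values (2--6) trade
#'   variance against bias.
#' @param theiler dynamic-correlation exclusion window: samples whose row
#'   indices are within `theiler` of the query row are excluded from the
#'   neighbour search and the marginal counts.  Leave at 0 for independent
#'   samples; when the rows are overlapping delay blocks of a time series,
#'   temporal neighbours are near-duplicates in the embedded space and
#'   counting them as recurrences inflates the estimate badly.
#' @return An object of class `"mi_estimate"`: list with `value` (bits),
#'   `k`, `n`, `theiler`.
#' @examples
#' set.seed(1)
#' x <- rnorm(1000); y <- 0.8 * x + sqrt(1 - 0.64) * rnorm(1000)
#' knn_mutual_information(x, y, k = 3)      # close to -0.5 * log2(1 - 0.8^2)
#' @export
knn_mutual_information <- function(xs, ys, k = 3L, theiler = 0L) {
  xs <- as_sample_matrix(xs)
  ys <- as_sample_matrix(ys)
  n <- nrow(xs)
  if (nrow(ys) != n) stop("xs and ys must have the same number of samples")
  k <- as.integer(k)
  theiler <- as.integer(theiler)
  if (k < 1L || k >= n) stop("k must satisfy 1 <= k < n")
  if (theiler < 0L) stop("theiler must be >= 0")
  if (n - 2L * theiler <= k)
    stop("theiler window leaves fewer than k eligible neighbours")
  if (!all(is.finite(xs)) || !all(is.finite(ys)))
    stop("samples must be finite")
  value <- .ksg_mi_cpp(xs, ys, k, theiler)
  structure(list(value = value, k = k, n = n, theiler = theiler),
            class = "mi_estimate")
}

#' @export
print.mi_estimate <- function(x, ...) {
  cat(sprintf("MI = %.4f bits  (k = %d, n = %d)\n", x$value, x$k, x$n))
  invisible(x)
}

#' Brute-force kNN mutual information (test oracle)
#'
#' Same estimator as [knn_mutual_information()], computed from the full
#' pairwise max-norm distance matrices with no spatial index.  Quadratic in
#' `n`, intended as an independent cross-check of the tree-based path on
#' small inputs; the two must agree to machine precision.
#'
#' @inheritParams knn_mutual_information
#' @return An `"mi_estimate"`.
#' @export
knn_mi_bruteforce <- function(xs, ys, k = 3L, theiler = 0L) {
  xs <- as_sample_matrix(xs)
  ys <- as_sample_matrix(ys)
  n <- nrow(xs)
  if (nrow(ys) != n) stop("xs and ys must have the same number of samples")
  if (n > 5000L) stop("brute-force path is quadratic; use n <= 5000")
  k <- as.integer(k)
  theiler <- as.integer(theiler)
  if (k < 1L || k >= n) stop("k must satisfy 1 <= k < n")
  if (n - 2L * theiler <= k)
    stop("theiler window leaves fewer than k eligible neighbours")

  cheb <- function(m) {
    d <- matrix(0, n, n)
    for (j in seq_len(ncol(m)))
      d <- pmax(d, abs(outer(m[, j], m[, j], `-`)))
    d
  }
  dx <- cheb(xs); dy <- cheb(ys)
  dj <- pmax(dx, dy)
  acc <- accN <- 0
  for (i in seq_len(n)) {
    excl <- max(1L, i - theiler):min(n, i + theiler)
    dji <- dj[i, ]; dji[excl] <- Inf
    eps <- sort(dji, partial = k)[k]
    if (eps <= 0) stop("tied samples (zero k-th neighbour distance); add jitter")
    nx <- sum(dx[i, ] < eps) - sum(dx[i, excl] < eps)
    ny <- sum(dy[i, ] < eps) - sum(dy[i, excl] < eps)
    acc <- acc + digamma(nx + 1) + digamma(ny + 1)
    accN <- accN + digamma(n - length(excl) + 1)
  }
  value <- (digamma(k) + accN / n - acc / n) / log(2)
  structure(list(value = value, k = k, n = n, theiler = theiler),
            class = "mi_estimate")
}

#' Seeded tie-breaking jitter
#'
#' Adds a reproducible tiny uniform perturbation so that discrete-valued
#' samples (quantized sensor readings) have no exact coincidences, which the
#' k-nearest-neighbour estimator cannot handle.  The default amplitude,
#' `1e-10` times the sample standard deviation, is far below any physical
#' signal scale.  Applied once, before any MI computation in a pipeline, so
#' the lag scan and the MI curve see identical data.
#'
#' @param x numeric vector, matrix of samples, or [timeseries].
#' @param amplitude half-width of the uniform perturbation; `0` is the
#'   identity.  Default `1e-10 * sd(x)`.
#' @param seed integer seed making the jitter reproducible.
#' @return Object of the same shape as `x` with the perturbation added.
#' @export
add_jitter <- function(x, amplitude = NULL, seed = 1L) {
  if (inherits(x, "timeseries")) {
    out <- x
    out$values <- add_jitter(x$values, amplitude, seed)
    return(out)
  }
  v <- as.numeric(x)
  if (is.null(amplitude)) amplitude <- 1e-10 * stats::sd(v)
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (amplitude == 0) return(x)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  noise <- stats::runif(length(v), -amplitude, amplitude)
  if (is.matrix(x)) matrix(x + noise, nrow = nrow(x)) else x + noise
}

# coerce vectors / timeseries / matrices to a samples-in-rows matrix
as_sample_matrix <- function(x) {
  if (inherits(x, "timeseries")) x <- x$values
  if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1L)
}
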