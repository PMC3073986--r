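#' Delay-embed a series into consecutive-sample blocks
#'
#' Turns a scalar series into the matrix of all length-`d` blocks of
#' consecutive samples (stride 1, maximally overlapping): row `i` holds
#' samples `i + shift, ..., i + shift + d - 1` (1-based).  These blocks are
#' the multivariate observations whose mutual information is tracked as a
#' function of the block length `d`; a non-zero `shift` realises the
#' latency alignment of the second signal.
#'
#' @param ts a [timeseries] (or plain numeric vector).
#' @param d block length (embedding dimension), >= 1.
#' @param shift integer sample shift applied to the block start indices.
#' @return A matrix with `d` columns, one block per row, with attributes
#'   `d`, `shift` and `offset` (index of the first sample of the first
#'   block in the source series).
#' @export
embed_blocks <- function(ts, d, shift = 0L) {
  v <- if (inherits(ts, "timeseries")) ts$values else as.numeric(ts)
  d <- as.integer(d); shift <- as.integer(shift)
  if (d < 1L) stop("d must be >= 1")
  n <- length(v)
  # valid block starts i: 1 <= i + shift and i + shift + d - 1 <= n
  i_min <- max(1L, 1L - shift)
  i_max <- n - d + 1L - shift
  if (i_max < i_min) stop("d = ", d, " exceeds the usable series length")
  starts <- (i_min:i_max) + shift
  out <- matrix(v[outer(starts, 0:(d - 1L), `+`)], ncol = d)
  attr(out, "d") <- d
  attr(out, "shift") <- shift
  attr(out, "offset") <- starts[1L]
  out
}

#' Aligned block embeddings of two equal-length series
#'
#' Embeds `x` with shift 0 and `y` with shift `delay`, truncated to the
#' common index range so row `i` of the two matrices pairs the `x` block
#' starting at sample `i` with the `y` block starting at sample
#' `i + delay`.  Both matrices have the same number of rows.
#'
#' @param x,y [timeseries] or numeric vectors of equal length.
#' @param d block length.
#' @param delay sample shift applied to `y` (the detected latency `T`).
#' @return A list with matrices `x` and `y`.
#' @export
embed_aligned <- function(x, y, d, delay = 0L) {
  vx <- if (inherits(x, "timeseries")) x$values else as.numeric(x)
  vy <- if (inherits(y, "timeseries")) y$values else as.numeric(y)
  if (length(vx) != length(vy)) stop("series lengths differ")
  d <- as.integer(d); delay <- as.integer(delay)
  n <- length(vx)
  i_min <- max(1L, 1L - delay)
  i_max <- min(n - d + 1L, n - d + 1L - delay)
  if (i_max - i_min + 1L < 2L) stop("d + |delay| leaves too few blocks")
  i <- i_min:i_max
  list(
    x = matrix(vx[outer(i, 0:(d - 1L), `+`)], ncol = d),
    y = matrix(vy[outer(i + delay, 0:(d - 1L), `+`)], ncol = d)
  )
}
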