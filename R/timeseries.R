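#' Uniformly sampled scalar time series
#'
#' Lightweight container for a uniformly sampled scalar signal: the sample
#' values, the sampling interval `dt` in seconds, and an optional logical mask
#' marking samples that were absent in the source record (sensor dropouts,
#' file gaps).  All analysis functions in the package take and return this
#' class.
#'
#' @param values numeric vector of samples (length >= 2). `NA` entries are
#'   taken as missing and reflected in the mask.
#' @param dt sampling interval in seconds, strictly positive.
#' @param missing optional logical vector, same length as `values`, `TRUE`
#'   where the observation is absent. Defaults to `is.na(values)`.
#' @param label free-text label carried through processing steps.
#' @return An object of class `"timeseries"` with fields `values`, `dt`,
#'   `missing`, `label`.
#' @examples
#' ts <- timeseries(sin(seq(0, 1, by = 0.01)), dt = 0.01, label = "demo")
#' ts
#' @export
timeseries <- function(values, dt, missing = NULL, label = "") {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("time series must have at least 2 samples")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number")
  if (is.null(missing)) missing <- is.na(values)
  missing <- as.logical(missing)
  if (length(missing) != length(values))
    stop("missing mask length must match values")
  missing <- missing | is.na(values)
  if (any(!is.finite(values[!missing])))
    stop("non-missing values must be finite")
  structure(
    list(values = values, dt = dt, missing = missing, label = as.character(label)[1L]),
    class = "timeseries"
  )
}

#' @export
print.timeseries <- function(x, ...) {
  n <- length(x$values)
  nmiss <- sum(x$missing)
  cat(sprintf("<timeseries%s: %d samples @ %g s (%.6g s total)%s>\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              n, x$dt, n * x$dt,
              if (nmiss > 0) sprintf(", %d missing", nmiss) else ""))
  invisible(x)
}

#' @export
length.timeseries <- function(x) length(x$values)

#' @export
as.double.timeseries <- function(x, ...) x$values

#' Read a time series from a delimited text file
#'
#' Reads one numeric column from a plain-text, CSV or TSV file (one row per
#' sample).  Cells that fail to parse as numbers -- empty fields, `NaN`/`NA`
#' tokens, or any other non-numeric text -- are treated as missing
#' observations and flagged in the mask.  The sampling interval is never
#' inferred from the file; it must be supplied.
#'
#' @param path file to read.
#' @param dt sampling interval in seconds.
#' @param column column to use (index or name) when the file has several;
#'   default 1.
#' @param header does the file carry a header line? Default `FALSE`; a
#'   non-numeric first row is detected and skipped automatically.
#' @param sep field separator; by default inferred from the file extension
#'   (`","` for .csv, `"\t"` for .tsv, whitespace otherwise).
#' @return A [timeseries] with the missing mask set where parsing failed.
#' @export
read_timeseries <- function(path, dt, column = 1L, header = FALSE, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    ext <- tolower(tools::file_ext(path))
    sep <- switch(ext, csv = ",", tsv = "\t", "")
  }
  df <- utils::read.table(path, header = header, sep = sep,
                          colClasses = "character", na.strings = character(),
                          strip.white = TRUE, blank.lines.skip = FALSE,
                          fill = TRUE, comment.char = "")
  if (nrow(df) == 0L) stop("no rows in ", path)
  if (is.character(column)) {
    if (!column %in% names(df)) stop("no column named '", column, "'")
    raw <- df[[column]]
  } else {
    if (column < 1L || column > ncol(df)) stop("column index out of range")
    raw <- df[[column]]
  }
  vals <- suppressWarnings(as.numeric(raw))
  # un-headered file with a text first row: drop it rather than fail
  if (!header && length(vals) > 1L && is.na(vals[1L]) && !is.na(suppressWarnings(as.numeric(raw[2L]))) &&
      nzchar(raw[1L]) && is.na(suppressWarnings(as.numeric(raw[1L])))) {
    vals <- vals[-1L]
  }
  if (all(is.na(vals))) stop("no numeric values in ", path)
  timeseries(vals, dt = dt, label = basename(path))
}

#' Write a time series to a delimited text file
#'
#' Missing samples are written as empty fields so a round trip through
#' [read_timeseries()] preserves the mask.
#'
#' @param ts a [timeseries].
#' @param path output file; extension chooses the separator as in
#'   [read_timeseries()].
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "timeseries"))
  out <- ifelse(ts$missing, "", format(ts$values, digits = 15, trim = TRUE))
  writeLines(out, path)
  invisible(path)
}

#' Fill missing samples by shape-preserving cubic interpolation
#'
#' Gaps flagged in the missing mask are filled with the piecewise cubic
#' Hermite interpolating polynomial (PCHIP), which preserves monotonicity and
#' never overshoots the neighbouring observations -- the standard choice for
#' making gappy sensor records continuous before rate-per-time analyses.
#' Gaps touching either end of the record, where no bracketing observation
#' exists, are extended from the nearest observed value.
#'
#' @param ts a [timeseries], possibly with missing samples.
#' @return A [timeseries] with no missing samples; observed samples are
#'   unchanged.
#' @export
interpolate_missing <- function(ts) {
  stopifnot(inherits(ts, "timeseries"))
  m <- ts$missing
  if (!any(m)) return(ts)
  if (all(m)) stop("all samples are missing")
  v <- ts$values
  obs <- which(!m)
  if (length(obs) < 2L) {
    v[] <- v[obs]
    return(timeseries(v, ts$dt, missing = rep(FALSE, length(v)), label = ts$label))
  }
  # clamp edge gaps to the nearest observation so PCHIP has a bracket
  first <- obs[1L]; last <- obs[length(obs)]
  if (first > 1L) { v[seq_len(first - 1L)] <- v[first]; m[seq_len(first - 1L)] <- FALSE }
  if (last < length(v)) { v[(last + 1L):length(v)] <- v[last]; m[(last + 1L):length(v)] <- FALSE }
  if (any(m)) {
    obs <- which(!m)
    v[m] <- if (length(obs) >= 3L) {
      pracma::pchip(obs, v[obs], which(m))
    } else {
      stats::approx(obs, v[obs], xout = which(m))$y  # 2 points: linear
    }
  }
  timeseries(v, ts$dt, missing = rep(FALSE, length(v)), label = ts$label)
}

#' Anti-aliased downsampling
#'
#' Decimates a series by an integer factor after zero-phase low-pass
#' filtering with a Kaiser-window FIR filter (cutoff 0.8 of the new Nyquist
#' frequency, 60 dB stopband attenuation), so frequencies above the new
#' Nyquist cannot alias into the decimated record and no group delay is
#' introduced.
#'
#' @param ts a gap-free [timeseries].
#' @param factor integer decimation factor (>= 1). `factor = 1` returns the
#'   input untouched.
#' @return A [timeseries] with `dt` multiplied by `factor`.
#' @export
downsample <- function(ts, factor) {
  stopifnot(inherits(ts, "timeseries"))
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  if (any(ts$missing)) stop("interpolate missing samples before downsampling")
  if (factor == 1L) return(ts)
  nyq_frac <- 1 / factor              # new Nyquist as a fraction of the old
  # pass up to 0.8 of the new Nyquist, 60 dB down at the new Nyquist
  ko <- signal::kaiserord(c(0.8, 1) * nyq_frac, c(1, 0),
                          c(10^(-60 / 20), 10^(-60 / 20)))
  ntaps <- ko$n + (ko$n %% 2L)        # even order -> odd length, linear phase
  if (length(ts$values) <= 3L * ntaps)
    stop("series too short for the anti-aliasing filter (needs > ",
         3L * ntaps, " samples)")
  b <- signal::fir1(ntaps, ko$Wc, type = "low",
                    window = signal::kaiser(ntaps + 1L, ko$beta))
  filt <- signal::filtfilt(as.numeric(b), 1, ts$values)
  keep <- seq(1L, length(filt), by = factor)
  timeseries(filt[keep], dt = ts$dt * factor, label = ts$label)
}

#' Split a series into overlapping sliding windows
#'
#' @param ts a [timeseries].
#' @param window_len window length in samples (>= 2).
#' @param overlap_fraction fractional overlap between consecutive windows, in
#'   `[0, 1)`; 0.5 halves the stride. A trailing partial window is discarded.
#' @return A list of [timeseries] windows, each of exactly `window_len`
#'   samples; the start index (1-based) of each window is attached as
#'   attribute `"starts"`.
#' @export
sliding_windows <- function(ts, window_len, overlap_fraction = 0.5) {
  stopifnot(inherits(ts, "timeseries"))
  window_len <- as.integer(window_len)
  if (window_len < 2L) stop("window_len must be >= 2")
  n <- length(ts$values)
  if (window_len > n) stop("window longer than the series")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1)")
  stride <- max(1L, as.integer(round(window_len * (1 - overlap_fraction))))
  starts <- seq.int(1L, n - window_len + 1L, by = stride)
  out <- lapply(starts, function(s) {
    i <- s:(s + window_len - 1L)
    timeseries(ts$values[i], ts$dt, missing = ts$missing[i], label = ts$label)
  })
  attr(out, "starts") <- starts
  out
}

#' Standardize a series to zero mean and unit variance
#'
#' @param ts a gap-free [timeseries] with non-zero variance.
#' @return A [timeseries] with sample mean 0 and sample standard deviation 1.
#' @export
standardize <- function(ts) {
  stopifnot(inherits(ts, "timeseries"))
  if (any(ts$missing)) stop("interpolate missing samples before standardizing")
  s <- stats::sd(ts$values)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant series")
  timeseries((ts$values - mean(ts$values)) / s, ts$dt, label = ts$label)
}
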