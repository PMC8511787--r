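#' Uniformly sampled scalar time series
#'
#' Light-weight container for a uniformly sampled scalar signal. The sampling
#' period `dt` is supplied by the user and trusted over any timestamp column:
#' the methods in this package assume exactly uniform, gap-free sampling, so
#' missing values are an error rather than something to impute.
#'
#' @param values numeric vector of samples (length >= 2, no missing values).
#' @param dt sampling period, in time units (> 0).
#' @param t0 time of the first sample. Default 0.
#' @return An object of class `havok_ts`: a list with elements `values`, `dt`
#'   and `t0`.
#' @examples
#' ts <- time_series(sin(seq(0, 10, by = 0.01)), dt = 0.01)
#' ts
#' @export
time_series <- function(values, dt, t0 = 0) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("a time series needs at least 2 samples")
  if (anyNA(values) || any(!is.finite(values)))
    stop("time series values must be finite and non-missing")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("'dt' must be a single positive number")
  structure(list(values = values, dt = dt, t0 = t0), class = "havok_ts")
}

#' @export
print.havok_ts <- function(x, ...) {
  q <- length(x$values)
  cat(sprintf("Uniform time series: %d samples, dt = %g, t in [%g, %g]\n",
              q, x$dt, x$t0, x$t0 + (q - 1) * x$dt))
  invisible(x)
}

#' @export
length.havok_ts <- function(x) length(x$values)

#' Sampling times of a time series
#'
#' @param ts a [time_series()] object.
#' @return numeric vector `t0 + (0:(q-1)) * dt`.
#' @export
time_grid <- function(ts) {
  stopifnot(inherits(ts, "havok_ts"))
  ts$t0 + (seq_along(ts$values) - 1) * ts$dt
}

.detect_sep <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, csv = ",", tsv = "\t", tab = "\t", "")
}

#' Read a scalar time series from a delimited text file
#'
#' The delimiter is chosen from the file extension (`.csv` comma, `.tsv` tab,
#' anything else whitespace). A header line is detected automatically: if the
#' first row does not parse as numbers it is taken to be column names. One
#' value column is selected by name or by 1-based index. Empty or non-numeric
#' cells are an error; the loader never fills gaps.
#'
#' @param path file to read.
#' @param column column name (character) or 1-based column index (numeric).
#'   Default 1.
#' @param dt sampling period of the stored signal (the file's timestamp
#'   column, if any, is not trusted).
#' @param t0 time of the first sample. Default 0.
#' @return A [time_series()] object.
#' @export
load_series <- function(path, column = 1, dt, t0 = 0) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .detect_sep(path)
  raw <- utils::read.table(path, header = FALSE, sep = sep,
                           colClasses = "character", strip.white = TRUE,
                           na.strings = NULL, quote = "\"")
  if (nrow(raw) == 0L) stop("empty file: ", path)
  first_numeric <- !anyNA(suppressWarnings(as.numeric(unlist(raw[1L, ]))))
  header <- NULL
  if (!first_numeric) {
    header <- as.character(unlist(raw[1L, ]))
    raw <- raw[-1L, , drop = FALSE]
  }
  if (is.character(column)) {
    if (is.null(header)) stop("file has no header; select the column by index")
    j <- match(column, header)
    if (is.na(j)) stop("no column named '", column, "'")
  } else {
    j <- as.integer(column)
    if (j < 1L || j > ncol(raw)) stop("column index out of range: ", column)
  }
  cells <- raw[[j]]
  empty <- which(!nzchar(cells))
  if (length(empty))
    stop("missing value at row ", empty[1L])
  vals <- suppressWarnings(as.numeric(cells))
  bad <- which(is.na(vals))
  if (length(bad))
    stop("non-numeric value at row ", bad[1L], ": '", cells[bad[1L]], "'")
  if (length(vals) < 2L) stop("fewer than 2 data rows in ", path)
  time_series(vals, dt = dt, t0 = t0)
}

#' Write a time series as a two-column CSV
#'
#' Emits a `t,x` header and the samples at full double precision, so that a
#' [load_series()] round trip reproduces the values bit-for-bit.
#'
#' @param ts a [time_series()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_series <- function(ts, path) {
  stopifnot(inherits(ts, "havok_ts"))
  tt <- time_grid(ts)
  lines <- c("t,x", sprintf("%.17g,%.17g", tt, ts$values))
  writeLines(lines, path)
  invisible(path)
}

#' Resample a time series with a cubic spline
#'
#' Fits a cubic spline interpolant through the samples and evaluates it on the
#' uniform grid `t0, t0 + new_dt, ...`, never extrapolating past the original
#' final time. The spline uses the Forsythe-Malcolm-Moler end condition, which
#' reproduces a single cubic polynomial exactly and passes through every knot.
#'
#' @param ts a [time_series()] object with at least 4 samples.
#' @param new_dt target sampling period (> 0).
#' @return A [time_series()] with sampling period `new_dt`.
#' @export
resample_spline <- function(ts, new_dt) {
  stopifnot(inherits(ts, "havok_ts"))
  if (!is.numeric(new_dt) || length(new_dt) != 1L || new_dt <= 0)
    stop("'new_dt' must be a single positive number")
  if (length(ts$values) < 4L)
    stop("cubic spline resampling needs at least 4 samples")
  tt <- time_grid(ts)
  t_end <- tt[length(tt)]
  grid <- seq(ts$t0, t_end, by = new_dt)
  if (length(grid) < 2L)
    stop("resampling grid would contain fewer than 2 points")
  f <- stats::splinefun(tt, ts$values, method = "fmm")
  time_series(f(grid), dt = new_dt, t0 = ts$t0)
}

.fd1 <- function(v, dt) {
  n <- length(v)
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  d[1] <- (-3 * v[1] + 4 * v[2] - v[3]) / (2 * dt)
  d[n] <- (3 * v[n] - 4 * v[n - 1] + v[n - 2]) / (2 * dt)
  d
}

#' Finite-difference derivative estimates
#'
#' Estimates derivatives of a sampled signal by second-order central
#' differences in the interior and matching-order one-sided stencils at the
#' two boundary points. Higher orders are obtained by repeated application of
#' the first-derivative operator, so every returned vector has the same length
#' as the input.
#'
#' @param v numeric vector of samples.
#' @param dt sampling period.
#' @param max_order highest derivative order to return (>= 1). The vector must
#'   be longer than `2 * max_order`.
#' @return A list of `max_order` numeric vectors; element `k` approximates the
#'   k-th time derivative of the signal.
#' @examples
#' d <- fd_derivatives(sin(seq(0, 1, by = 0.001)), 0.001, 2)
#' @export
fd_derivatives <- function(v, dt, max_order = 1) {
  v <- as.numeric(v)
  max_order <- as.integer(max_order)
  if (max_order < 1L) stop("'max_order' must be at least 1")
  if (length(v) <= 2L * max_order)
    stop("vector too short for derivative order ", max_order,
         " (need length > ", 2L * max_order, ")")
  out <- vector("list", max_order)
  cur <- v
  for (k in seq_len(max_order)) {
    cur <- .fd1(cur, dt)
    out[[k]] <- cur
  }
  out
}
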