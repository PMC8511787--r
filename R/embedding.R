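#' Build a Hankel (time-delay) matrix from a time series
#'
#' Stacks `m` time-shifted copies of the signal as rows, giving the
#' `m x (q - m + 1)` Hankel matrix `H[i, j] = x[i + j - 1]`. Each column is a
#' short m-sample window of the trajectory; each anti-diagonal is constant.
#'
#' @param ts a [time_series()] object (length `q`).
#' @param m number of delays (rows), `2 <= m <= q - 1`. Odd `m` is required
#'   later for centring.
#' @return An object of class `delay_embedding`: list with the matrix `H`,
#'   dimensions `m`, `n`, the sampling period `dt`, start time `t0`, a
#'   `centred` flag and (after [centre_hankel()]) the centre row `h0`.
#' @seealso [centre_hankel()], [split_pair()], [check_sampling()]
#' @export
build_hankel <- function(ts, m) {
  stopifnot(inherits(ts, "havok_ts"))
  q <- length(ts$values)
  m <- as.integer(m)
  if (m < 2L || m > q - 1L)
    stop("'m' must satisfy 2 <= m <= q - 1 (q = ", q, ")")
  n <- q - m + 1L
  H <- matrix(0, m, n)
  for (i in seq_len(m)) H[i, ] <- ts$values[i:(i + n - 1L)]
  structure(list(H = H, m = m, n = n, dt = ts$dt, t0 = ts$t0,
                 centred = FALSE, h0 = NULL),
            class = "delay_embedding")
}

#' @export
print.delay_embedding <- function(x, ...) {
  cat(sprintf("Delay embedding: %d x %d Hankel matrix, dt = %g%s\n",
              x$m, x$n, x$dt, if (x$centred) ", centred" else ""))
  invisible(x)
}

#' Centre a delay embedding on its middle row
#'
#' Subtracts the middle delay row `h0` from every row of the Hankel matrix.
#' After centring, the columns of the matrix are deviations of each delay
#' window from its central sample, which is what aligns the SVD modes with
#' trajectory derivatives rather than with the signal itself. `m` must be odd
#' so that the middle row is unique; even `m` is rejected rather than
#' averaging two rows.
#'
#' @param emb an uncentred [build_hankel()] embedding with odd `m`.
#' @return The centred `delay_embedding`, with `h0` stored.
#' @export
centre_hankel <- function(emb) {
  stopifnot(inherits(emb, "delay_embedding"))
  if (emb$centred) stop("embedding is already centred")
  if (emb$m %% 2L == 0L)
    stop("centre row undefined: 'm' must be odd (got m = ", emb$m, ")")
  mid <- (emb$m + 1L) %/% 2L
  h0 <- emb$H[mid, ]
  emb$H <- emb$H - matrix(h0, emb$m, emb$n, byrow = TRUE)
  emb$h0 <- h0
  emb$centred <- TRUE
  emb
}

#' Split an embedding into two column-shifted Hankel matrices
#'
#' Returns the pair `H1` (columns `1..n-1`) and `H2` (columns `2..n`) used by
#' the structured (two-SVD) fit. Centring, when wanted, is applied once to the
#' full matrix before splitting.
#'
#' @param emb a [build_hankel()] embedding with `n >= 2` columns.
#' @return An object of class `hankel_pair`: list with `H1`, `H2`, `dt`,
#'   `centred`, `h0` and `m`.
#' @export
split_pair <- function(emb) {
  stopifnot(inherits(emb, "delay_embedding"))
  if (emb$n < 2L) stop("need at least 2 columns to split")
  structure(list(H1 = emb$H[, -emb$n, drop = FALSE],
                 H2 = emb$H[, -1L, drop = FALSE],
                 dt = emb$dt, centred = emb$centred, h0 = emb$h0, m = emb$m),
            class = "hankel_pair")
}

#' Sampling-adequacy check for a delay embedding
#'
#' The Taylor expansion of a delay window about its centre is dominated by the
#' first-derivative term only if the window length `m * dt` is much smaller
#' than the derivative-norm ratios `2 ||h0'|| / ||h0''||`,
#' `3 ||h0''|| / ||h0'''||`, and so on. Because the ratio sequence grows, the
#' first ratio is the binding one. "Much smaller" is operationalised as a
#' configurable factor-10 separation.
#'
#' @param emb a centred embedding (the check needs `h0`).
#' @param orders number of ratios to report (>= 1); derivatives up to order
#'   `orders + 1` are estimated with [fd_derivatives()].
#' @param margin pass if `m * dt < margin * ratio[1]`. Default 0.1.
#' @return An object of class `sampling_report`: list with `m_dt`, `ratios`,
#'   `margin` and logical `pass`. A vanishing denominator norm gives an
#'   infinite ratio, a pass, and a warning.
#' @export
check_sampling <- function(emb, orders = 3, margin = 0.1) {
  stopifnot(inherits(emb, "delay_embedding"))
  if (!emb$centred) stop("sampling check needs a centred embedding (h0)")
  orders <- as.integer(orders)
  if (orders < 1L) stop("'orders' must be at least 1")
  d <- fd_derivatives(emb$h0, emb$dt, orders + 1L)
  norms <- vapply(d, function(v) sqrt(sum(v^2)), numeric(1))
  k <- seq_len(orders) + 1L              # 2, 3, ...
  denom <- norms[k]
  ratios <- ifelse(denom < 1e-300, Inf, k * norms[k - 1L] / denom)
  if (any(!is.finite(ratios)))
    warning("a derivative norm is zero; ratio reported as +Inf")
  structure(list(m_dt = emb$m * emb$dt, ratios = ratios, margin = margin,
                 pass = emb$m * emb$dt < margin * ratios[1L]),
            class = "sampling_report")
}

#' @export
print.sampling_report <- function(x, ...) {
  cat(sprintf("Sampling check: m*dt = %g, first ratio = %g (margin %g) -> %s\n",
              x$m_dt, x$ratios[1L], x$margin,
              if (x$pass) "PASS" else "FAIL"))
  if (length(x$ratios) > 1L)
    cat("  ratio sequence:", paste(signif(x$ratios, 4), collapse = ", "), "\n")
  invisible(x)
}
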