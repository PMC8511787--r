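#' @keywords internal
.pinv <- function(A, tol = 1e-12) {
  sv <- svd(A)
  pos <- sv$d > tol * sv$d[1L]
  if (!any(pos)) stop("matrix is numerically zero; pseudo-inverse undefined")
  sv$v[, pos, drop = FALSE] %*% ((1 / sv$d[pos]) * t(sv$u[, pos, drop = FALSE]))
}

.check_state_rank <- function(V1, label) {
  d <- svd(V1, nu = 0, nv = 0)$d
  if (d[1L] == 0 || d[length(d)] / d[1L] < 1e-12)
    stop(label, ": temporal coordinates rank-deficient (condition number > 1e12),",
         " offending mode ", length(d))
}

.new_model <- function(A, B, r, dt, variant, emb, basis, basis2 = NULL,
                       closed, call = sys.call(-1)) {
  structure(list(A = A, B = B, d = nrow(A), r = r, dt = dt, variant = variant,
                 centred = emb$centred, closed = closed, basis = basis,
                 basis2 = basis2, h0 = emb$h0, m = emb$m, n = emb$n,
                 t0 = emb$t0, call = call),
            class = "havok_model")
}

#' Convert discrete one-step operators to continuous time
#'
#' First-order conversion: `A = (Ahat - I) / dt` and, for the forcing vector,
#' `B = Bhat / dt`. This is the default conversion used by the fitting
#' routines; the matrix-logarithm alternative is available for spectra via
#' [model_spectrum()] with `path = "discrete_log"`.
#'
#' @param Ahat square discrete dynamics matrix.
#' @param Bhat optional discrete forcing vector.
#' @param dt sampling period (> 0).
#' @return list with `A` and `B` (`NULL` when `Bhat` is absent).
#' @export
continuousize <- function(Ahat, Bhat = NULL, dt) {
  stopifnot(dt > 0, nrow(Ahat) == ncol(Ahat))
  list(A = (Ahat - diag(nrow(Ahat))) / dt,
       B = if (is.null(Bhat)) NULL else Bhat / dt)
}

#' Fit a HAVOK model to a delay embedding
#'
#' One truncated SVD of the embedding gives temporal coordinates `V`; the
#' one-step map between the time-shifted row blocks `V1` (rows `1..n-1`) and
#' `V2` (rows `2..n`) is fitted by least squares with a pseudo-inverse and
#' converted to continuous time. In the forced case the state is the first
#' `r - 1` coordinates and the r-th coordinate enters as a scalar forcing
#' channel, so `A` is `(r-1) x (r-1)` and `B` is a length `r - 1` vector.
#'
#' @param emb a `delay_embedding` (centred recommended) with `n >= r + 1`.
#' @param r truncation rank.
#' @param closed if `TRUE`, fit the full rank-r linear model with no forcing
#'   term; if `FALSE` (default), fit the forced model.
#' @return An object of class `havok_model`. Fields include the
#'   continuous-time dynamics `A`, forcing vector `B` (or `NULL`), the
#'   retained `spectral_basis` used for lifting, `h0` when centred, and the
#'   embedding dimensions.
#' @seealso [fit_shavok()], [havok()], [curvature_from_model()]
#' @export
fit_havok <- function(emb, r, closed = FALSE) {
  stopifnot(inherits(emb, "delay_embedding"))
  r <- as.integer(r)
  if (emb$n < r + 1L) stop("need n >= r + 1 columns")
  if (!closed && r < 2L) stop("forced model needs r >= 2")
  basis <- truncated_svd(emb$H, r)
  if (basis$S[1L] == 0 || basis$S[r] / basis$S[1L] < 1e-12)
    stop("embedding rank-deficient at mode ", r,
         "; lower 'r' or check the signal")
  n <- emb$n
  V1 <- basis$V[-n, , drop = FALSE]
  V2 <- basis$V[-1L, , drop = FALSE]
  .check_state_rank(V1, "fit_havok")
  P1 <- .pinv(t(V1))
  if (closed) {
    Ahat <- t(V2) %*% P1
    cont <- continuousize(Ahat, NULL, emb$dt)
  } else {
    AB <- t(V2[, seq_len(r - 1L), drop = FALSE]) %*% P1
    cont <- continuousize(AB[, seq_len(r - 1L), drop = FALSE],
                          AB[, r], emb$dt)
  }
  .new_model(cont$A, cont$B, r, emb$dt, "havok", emb, basis, closed = closed)
}

#' Fit a structured HAVOK (sHAVOK) model
#'
#' The structured variant splits the (centred) Hankel matrix into the two
#' column-shifted matrices `H1` and `H2`, takes an independent rank-r SVD of
#' each, sign-aligns the second basis to the first, and uses
#' `A = (V2' V1 - I) / dt`. Because both temporal factors are exactly
#' orthonormal, the fitted matrix is markedly closer to the antisymmetric
#' tridiagonal curvature form, especially for short records. In the forced
#' case the state is the first `r - 1` coordinates of the `H1` basis and
#' `[A, B]` is read off the first `r - 1` rows.
#'
#' @inheritParams fit_havok
#' @return An object of class `havok_model` with `variant = "shavok"`. The
#'   lifting basis (`$basis`) is the `H1` basis; the aligned `H2` basis is
#'   kept in `$basis2`.
#' @export
fit_shavok <- function(emb, r, closed = FALSE) {
  stopifnot(inherits(emb, "delay_embedding"))
  r <- as.integer(r)
  if (emb$n < r + 1L) stop("need n >= r + 1 columns")
  if (!closed && r < 2L) stop("forced model needs r >= 2")
  pair <- split_pair(emb)
  b1 <- truncated_svd(pair$H1, r)
  if (b1$S[1L] == 0 || b1$S[r] / b1$S[1L] < 1e-12)
    stop("embedding rank-deficient at mode ", r,
         "; lower 'r' or check the signal")
  b2 <- truncated_svd(pair$H2, r)
  b2 <- align_bases(b1, b2)
  M <- crossprod(b2$V, b1$V)                  # V2' V1, r x r
  if (closed) {
    cont <- continuousize(M, NULL, emb$dt)
  } else {
    AB <- (M[seq_len(r - 1L), , drop = FALSE] -
             diag(1, r - 1L, r)) / emb$dt     # ([Ahat, Bhat] - [I, 0]) / dt
    cont <- list(A = AB[, seq_len(r - 1L), drop = FALSE], B = AB[, r])
  }
  .new_model(cont$A, cont$B, r, emb$dt, "shavok", emb, b1, basis2 = b2,
             closed = closed)
}

#' Fit a structured time-delay model to a scalar time series
#'
#' User-facing front end running the whole pipeline: Hankel embedding,
#' optional centring, rank selection, and a HAVOK or sHAVOK fit.
#'
#' @param x a [time_series()] object or a numeric vector (then `dt` is
#'   required).
#' @param m number of delays; must be odd when `centre = TRUE`.
#' @param r truncation rank. If `NULL`, chosen as the number of singular
#'   values with `sigma_i / sigma_1 > 1e-8` (suits closed low-rank signals;
#'   set explicitly for chaotic data).
#' @param dt sampling period, needed when `x` is a bare vector.
#' @param variant `"shavok"` (default, two-SVD structured fit) or `"havok"`.
#' @param centre subtract the middle delay row before decomposing (default
#'   `TRUE`).
#' @param closed fit the closed rank-r linear model (`TRUE`) or the forced
#'   model with a scalar forcing channel (default `FALSE`).
#' @return A `havok_model`; see [fit_havok()].
#' @examples
#' sim <- sinusoid_example(dt = 0.001, t_end = 10)
#' mod <- havok(sim$ts, m = 41, r = 4, variant = "shavok", closed = TRUE)
#' mod
#' round(coef(mod) / delay_speed(mod), 5)   # curvature-normalized dynamics
#' @export
havok <- function(x, m, r = NULL, dt = NULL,
                  variant = c("shavok", "havok"),
                  centre = TRUE, closed = FALSE) {
  variant <- match.arg(variant)
  if (!inherits(x, "havok_ts")) {
    if (is.null(dt)) stop("'dt' is required when 'x' is a plain vector")
    x <- time_series(x, dt = dt)
  }
  emb <- build_hankel(x, m)
  if (centre) emb <- centre_hankel(emb)
  if (is.null(r)) r <- suggest_rank(emb)
  mod <- switch(variant,
                shavok = fit_shavok(emb, r, closed = closed),
                havok = fit_havok(emb, r, closed = closed))
  mod$call <- match.call()
  mod
}

#' Norm of the centre-row derivative (trajectory speed)
#'
#' The Euclidean norm of the finite-difference time derivative of the centre
#' delay row `h0`; the scale factor between the fitted dynamics matrix and
#' the curvature matrix `K = A / ||h0'||`.
#'
#' @param model a fitted `havok_model` from a centred embedding.
#' @return positive scalar.
#' @export
delay_speed <- function(model) {
  stopifnot(inherits(model, "havok_model"))
  if (!model$centred) stop("speed needs a centred model (h0 unavailable)")
  sqrt(sum(fd_derivatives(model$h0, model$dt, 1L)[[1L]]^2))
}

#' Eigenvalue spectrum of a fitted model
#'
#' Continuous-time eigenvalues of the dynamics, either directly from `A`
#' (`path = "continuous"`) or through the discrete operator,
#' `log(eig(I + dt A)) / dt` (`path = "discrete_log"`). The first-order
#' discrete-to-continuous conversion biases real parts by about
#' `-omega^2 dt / 2` for an oscillatory mode of frequency `omega`; the
#' discrete-log path removes that bias and is the right choice when judging
#' stability.
#'
#' @param model a fitted `havok_model`.
#' @param path `"continuous"` or `"discrete_log"`.
#' @return An object of class `model_spectrum`: list with complex `omegas`
#'   and `max_real`.
#' @export
model_spectrum <- function(model, path = c("continuous", "discrete_log")) {
  stopifnot(inherits(model, "havok_model"))
  path <- match.arg(path)
  om <- switch(path,
               continuous = eigen(model$A, only.values = TRUE)$values,
               discrete_log = log(eigen(diag(model$d) + model$dt * model$A,
                                        only.values = TRUE)$values +
                                    0i) / model$dt)
  om <- as.complex(om)
  structure(list(omegas = om, max_real = max(Re(om)), path = path),
            class = "model_spectrum")
}

#' @export
print.model_spectrum <- function(x, ...) {
  cat("Model spectrum (", x$path, "):\n", sep = "")
  print(signif(x$omegas, 4))
  cat("max real part:", signif(x$max_real, 4), "\n")
  invisible(x)
}

#' Integrate a fitted linear model forward
#'
#' Fixed-step fourth-order Runge-Kutta integration of `v' = A v (+ B u)` at
#' the model's sampling period, with the scalar forcing held constant over
#' each step (zero-order hold).
#'
#' @param model a fitted `havok_model`.
#' @param v0 initial state, length `model$d`.
#' @param forcing scalar forcing series (length >= `steps`); required for
#'   forced models, ignored for closed ones.
#' @param steps number of states to return (including the initial state).
#' @return `steps x d` matrix of states, first row `v0`.
#' @export
simulate_model <- function(model, v0, forcing = NULL, steps) {
  stopifnot(inherits(model, "havok_model"))
  v0 <- as.numeric(v0)
  if (length(v0) != model$d)
    stop("'v0' must have length ", model$d)
  steps <- as.integer(steps)
  if (steps < 1L) stop("'steps' must be positive")
  forced <- !model$closed
  if (forced) {
    if (is.null(forcing))
      stop("forced model requires a 'forcing' series")
    forcing <- as.numeric(forcing)
    if (length(forcing) < steps)
      stop("'forcing' must have length >= steps")
  }
  A <- model$A
  B <- if (forced) model$B else numeric(model$d)
  dt <- model$dt
  out <- matrix(0, steps, model$d)
  v <- v0
  for (k in seq_len(steps)) {
    out[k, ] <- v
    if (k == steps) break
    u <- if (forced) forcing[k] else 0
    f <- function(y) as.numeric(A %*% y) + B * u
    k1 <- f(v); k2 <- f(v + dt / 2 * k1)
    k3 <- f(v + dt / 2 * k2); k4 <- f(v + dt * k3)
    v <- v + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  out
}

#' Reconstruct the scalar signal from a state trajectory
#'
#' Lifts a trajectory of temporal coordinates back to the centre delay row
#' through the retained SVD factors, `x(t) = U[mid, ] diag(S) v(t)'`, adding
#' the stored centre row `h0` back when the model was fitted on a centred
#' embedding. With centring the add-back ties the reconstruction to the
#' training window, so the trajectory must have exactly one state per stored
#' training snapshot.
#'
#' @param model a fitted `havok_model` (its basis is retained by the fit).
#' @param traj `N x d` state matrix, e.g. from [simulate_model()] or the
#'   stored temporal coordinates `model$basis$V`.
#' @return A [time_series()] of the reconstructed centre-row signal.
#' @export
reconstruct_signal <- function(model, traj) {
  stopifnot(inherits(model, "havok_model"))
  traj <- as.matrix(traj)
  if (ncol(traj) != model$d)
    stop("trajectory must have ", model$d, " columns")
  mid <- (model$m + 1L) %/% 2L
  idx <- seq_len(model$d)
  xhat <- as.numeric(model$basis$U[mid, idx, drop = FALSE] %*%
                       (model$basis$S[idx] * t(traj)))
  if (model$centred) {
    n_train <- nrow(model$basis$V)
    if (nrow(traj) != n_train)
      stop("centred reconstruction needs one state per training snapshot (",
           n_train, ")")
    xhat <- xhat + model$h0[seq_len(n_train)]
  }
  t0_mid <- model$t0 + (mid - 1L) * model$dt
  time_series(xhat, dt = model$dt, t0 = t0_mid)
}

#' Estimate the forcing coordinate from a raw delay window
#'
#' Projects an m-sample window of the signal onto the r-th delay mode,
#' scaled by the inverse r-th singular value: `v_r = (u_r . w) / sigma_r`,
#' where `w` is the window after subtracting its central sample when the
#' model is centred. This is how the scalar forcing is estimated online for
#' forecasting.
#'
#' @param model a forced `havok_model`.
#' @param window numeric vector of length `model$m`.
#' @return scalar estimate of the forcing coordinate.
#' @export
estimate_forcing <- function(model, window) {
  stopifnot(inherits(model, "havok_model"))
  if (model$closed) stop("closed models have no forcing channel")
  window <- as.numeric(window)
  if (length(window) != model$m)
    stop("window must have length m = ", model$m)
  if (model$centred) window <- window - window[(model$m + 1L) %/% 2L]
  sum(model$basis$U[, model$r] * window) / model$basis$S[model$r]
}
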