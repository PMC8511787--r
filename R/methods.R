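#' @export
print.havok_model <- function(x, ...) {
  cat(sprintf("%s model (%s, %s): state dimension %d, rank %d, dt = %g\n",
              toupper(x$variant),
              if (x$centred) "centred" else "uncentred",
              if (x$closed) "closed" else "forced",
              x$d, x$r, x$dt))
  cat(sprintf("  fitted on a %d x %d delay embedding\n", x$m, x$n))
  if (!is.null(x$call)) {
    cat("  call: "); print(x$call)
  }
  invisible(x)
}

#' Model coefficients
#'
#' Returns the continuous-time dynamics matrix `A`, with the forcing vector
#' `B` appended as a final column named `B` for forced models.
#'
#' @param object a fitted `havok_model`.
#' @param ... unused.
#' @export
coef.havok_model <- function(object, ...) {
  if (object$closed) return(object$A)
  cbind(object$A, B = object$B)
}

#' Summary of a fitted time-delay model
#'
#' Collects the structure diagnostics (antisymmetry and tridiagonality
#' indices), the eigenvalue spectrum on both conversion paths, and -- for
#' centred fits -- the curvature estimates read off the super-diagonal of
#' `K = A / ||h0'||`.
#'
#' @param object a fitted `havok_model`.
#' @param ... unused.
#' @return An object of class `summary.havok_model`.
#' @export
summary.havok_model <- function(object, ...) {
  out <- list(model = object,
              structure = structure_report(object$A),
              spectrum = model_spectrum(object, "discrete_log"))
  if (object$centred)
    out$curvatures <- curvature_from_model(object)
  class(out) <- "summary.havok_model"
  out
}

#' @export
print.summary.havok_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  antisymmetry index: %.4g   off-tridiagonal mass: %.4g\n",
              x$structure$antisym_index, x$structure$tridiag_index))
  cat(sprintf("  max Re(omega) [discrete-log path]: %.4g\n",
              x$spectrum$max_real))
  if (!is.null(x$curvatures))
    cat("  curvature estimates:",
        paste(signif(x$curvatures$kappas, 4), collapse = ", "), "\n")
  invisible(x)
}

#' One-step prediction residuals on the temporal coordinates
#'
#' For each consecutive pair of stored temporal states, the difference
#' between the observed next state and the one-step prediction of the fitted
#' discrete operator `I + dt A (+ dt B v_r)`.
#'
#' @param object a fitted `havok_model`.
#' @param ... unused.
#' @return `(N - 1) x d` matrix of residuals.
#' @export
residuals.havok_model <- function(object, ...) {
  V <- object$basis$V
  n <- nrow(V)
  Vnext <- if (object$variant == "shavok") object$basis2$V else V[-1L, , drop = FALSE]
  Vcur <- if (object$variant == "shavok") V else V[-n, , drop = FALSE]
  d <- object$d
  Ahat <- diag(d) + object$dt * object$A
  pred <- Vcur[, seq_len(d), drop = FALSE] %*% t(Ahat)
  if (!object$closed)
    pred <- pred + object$dt * outer(Vcur[, object$r], object$B)
  Vnext[, seq_len(d), drop = FALSE] - pred
}

#' Fitted (reconstructed) training signal
#'
#' Reconstruction of the centre delay row over the training window from the
#' stored temporal coordinates; see [reconstruct_signal()].
#'
#' @param object a fitted `havok_model`.
#' @param ... unused.
#' @export
fitted.havok_model <- function(object, ...) {
  reconstruct_signal(object, object$basis$V[, seq_len(object$d), drop = FALSE])
}

#' Simulate a fitted model forward
#'
#' Convenience wrapper around [simulate_model()] following the base
#' [stats::simulate()] generic. By default the simulation starts from the
#' first stored temporal state and, for forced models, replays the stored
#' forcing coordinate.
#'
#' @param object a fitted `havok_model`.
#' @param nsim number of steps to simulate (default: the training length).
#' @param seed unused (the integration is deterministic); kept for generic
#'   compatibility.
#' @param v0 initial state (default: first stored temporal state).
#' @param forcing forcing series for forced models (default: the stored r-th
#'   temporal coordinate).
#' @param ... unused.
#' @return `nsim x d` state matrix.
#' @export
simulate.havok_model <- function(object, nsim = NULL, seed = NULL,
                                 v0 = NULL, forcing = NULL, ...) {
  V <- object$basis$V
  if (is.null(nsim)) nsim <- nrow(V)
  if (is.null(v0)) v0 <- V[1L, seq_len(object$d)]
  if (!object$closed && is.null(forcing)) {
    forcing <- V[, object$r]
    if (length(forcing) < nsim)
      forcing <- c(forcing, rep(0, nsim - length(forcing)))
  }
  simulate_model(object, v0 = v0, forcing = forcing, steps = nsim)
}

#' Forecast the temporal state beyond the training window
#'
#' Integrates the fitted model forward from the last stored temporal state.
#' Forced models need a forcing series for the forecast horizon (default
#' zero, i.e. the unforced linear flow).
#'
#' @param object a fitted `havok_model`.
#' @param n_ahead number of steps to forecast.
#' @param forcing optional forcing series of length >= `n_ahead`.
#' @param ... unused.
#' @return `n_ahead x d` matrix of forecast states.
#' @export
predict.havok_model <- function(object, n_ahead = 10, forcing = NULL, ...) {
  v0 <- object$basis$V[nrow(object$basis$V), seq_len(object$d)]
  if (!object$closed && is.null(forcing)) forcing <- rep(0, n_ahead)
  simulate_model(object, v0 = v0, forcing = forcing, steps = n_ahead)
}

#' Plot a fitted model: dynamics matrix and spectrum
#'
#' Left panel: image of the curvature-normalized dynamics matrix
#' (`A / ||h0'||` for centred fits, `A` otherwise), on a symmetric colour
#' scale so antisymmetric tridiagonal structure is visible at a glance.
#' Right panel: eigenvalues in the complex plane (discrete-log path).
#'
#' @param x a fitted `havok_model`.
#' @param ... unused.
#' @export
plot.havok_model <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  K <- if (x$centred) x$A / delay_speed(x) else x$A
  lim <- max(abs(K))
  d <- nrow(K)
  pal <- grDevices::hcl.colors(65, "Blue-Red 2")
  graphics::image(seq_len(d), seq_len(d), t(K[d:1, , drop = FALSE]),
                  zlim = c(-lim, lim), col = pal, axes = FALSE,
                  xlab = "column", ylab = "row",
                  main = if (x$centred) "K = A / ||h0'||" else "A")
  graphics::axis(1, at = seq_len(d)); graphics::axis(2, at = seq_len(d), labels = d:1)
  graphics::box()
  om <- model_spectrum(x, "discrete_log")$omegas
  graphics::plot(Re(om), Im(om), pch = 4, col = "maroon",
                 xlab = "Re(omega)", ylab = "Im(omega)",
                 main = "spectrum (discrete-log)")
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}
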