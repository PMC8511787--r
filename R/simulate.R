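#' @keywords internal
.rk4 <- function(f, y0, dt, steps) {
  steps <- as.integer(steps)
  if (steps < 2L) stop("'steps' must be at least 2")
  Y <- matrix(0, steps, length(y0))
  y <- as.numeric(y0)
  Y[1L, ] <- y
  for (k in seq_len(steps - 1L)) {
    k1 <- f(y)
    k2 <- f(y + dt / 2 * k1)
    k3 <- f(y + dt / 2 * k2)
    k4 <- f(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(y)))
      stop("integration diverged (non-finite state at step ", k + 1L, ")")
    Y[k + 1L, ] <- y
  }
  Y
}

.new_multi <- function(states, dt, system, params, t0 = 0) {
  structure(list(states = states, dt = dt, t0 = t0, system = system,
                 params = params),
            class = "multi_series")
}

#' @export
print.multi_series <- function(x, ...) {
  cat(sprintf("%s trajectory: %d samples x %d states, dt = %g\n",
              x$system, nrow(x$states), ncol(x$states), x$dt))
  invisible(x)
}

#' Extract a scalar observable from a simulated trajectory
#'
#' @param ms a `multi_series` from one of the simulators.
#' @param coord which state coordinate to read (default 1).
#' @param transform optional function applied to the coordinate (e.g. `sin`
#'   for pendulum angles).
#' @return A [time_series()] of the observable.
#' @export
as_time_series <- function(ms, coord = 1L, transform = NULL) {
  stopifnot(inherits(ms, "multi_series"))
  v <- ms$states[, coord]
  if (!is.null(transform)) v <- transform(v)
  time_series(v, dt = ms$dt, t0 = ms$t0)
}

#' The worked sinusoid example, with analytic derivative closures
#'
#' Samples `x(t) = sin(t) + sin(2t)` on `[0, t_end]` and exposes the exact
#' derivatives of the centre delay row for any odd delay count `m`: on the
#' grid `t = t0 + (m-1)/2 dt, ..., t_end - (m-1)/2 dt` the k-th derivative is
#' the analytically differentiated signal. The fifth derivative satisfies
#' the linear dependence `x^(5) = -5 x''' - 4 x'` (the signal solves
#' `x^(4) + 5 x'' + 4 x = 0`), so at most four derivative vectors are
#' independent and exactly three curvatures are non-zero.
#'
#' @param dt sampling period (default 0.001).
#' @param t_end end of the sampling window (default 10).
#' @return list with `ts` (the sampled [time_series()]), and `derivatives`, a
#'   function `(m, max_order = 4)` returning the list of analytic derivative
#'   vectors of the centre row for a delay count `m` (orders up to 5).
#' @export
sinusoid_example <- function(dt = 0.001, t_end = 10) {
  stopifnot(dt > 0, t_end > dt)
  tt <- seq(0, t_end, by = dt)
  ts <- time_series(sin(tt) + sin(2 * tt), dt = dt, t0 = 0)
  derivatives <- function(m, max_order = 4) {
    m <- as.integer(m)
    if (m %% 2L == 0L) stop("'m' must be odd")
    if (max_order > 5L) stop("analytic derivatives available up to order 5")
    half <- (m - 1L) / 2L
    tc <- tt[(half + 1L):(length(tt) - half)]
    all5 <- list(
      cos(tc) + 2 * cos(2 * tc),
      -sin(tc) - 4 * sin(2 * tc),
      -cos(tc) - 8 * cos(2 * tc),
      sin(tc) + 16 * sin(2 * tc),
      cos(tc) + 32 * cos(2 * tc))
    all5[seq_len(max_order)]
  }
  list(ts = ts, derivatives = derivatives)
}

#' Simulate the Lorenz system
#'
#' Fixed-step fourth-order Runge-Kutta integration of the Lorenz equations
#' `x' = sigma (y - x)`, `y' = x (rho - z) - y`, `z' = x y - beta z`. The
#' defaults are the standard chaotic parameters and the short-record
#' configuration used throughout this package's examples: 3000 samples from
#' `[-8, 8, 27]` at `dt = 0.001`.
#'
#' @param steps number of samples (>= 2).
#' @param dt integration step / sampling period.
#' @param init initial state, length 3.
#' @param sigma,rho,beta system parameters.
#' @return A `multi_series` with columns (x, y, z).
#' @export
simulate_lorenz <- function(steps = 3000, dt = 0.001, init = c(-8, 8, 27),
                            sigma = 10, rho = 28, beta = 8 / 3) {
  stopifnot(length(init) == 3L, dt > 0)
  f <- function(y) c(sigma * (y[2L] - y[1L]),
                     y[1L] * (rho - y[3L]) - y[2L],
                     y[1L] * y[2L] - beta * y[3L])
  .new_multi(.rk4(f, init, dt, steps), dt, "lorenz",
             list(sigma = sigma, rho = rho, beta = beta))
}

#' Simulate the Roessler system
#'
#' Fixed-step RK4 integration of `x' = -y - z`, `y' = x + a y`,
#' `z' = b + z (x - c)`. Defaults: `a = b = 0.1`, `c = 14`, 70000 samples
#' from `(1, 1, 1)` at `dt = 0.001`.
#'
#' @param steps number of samples (>= 2).
#' @param dt integration step / sampling period.
#' @param init initial state, length 3.
#' @param a,b,c system parameters.
#' @return A `multi_series` with columns (x, y, z).
#' @export
simulate_rossler <- function(steps = 70000, dt = 0.001, init = c(1, 1, 1),
                             a = 0.1, b = 0.1, c = 14) {
  stopifnot(length(init) == 3L, dt > 0)
  f <- function(y) c(-y[2L] - y[3L],
                     y[1L] + a * y[2L],
                     b + y[3L] * (y[1L] - c))
  .new_multi(.rk4(f, init, dt, steps), dt, "rossler",
             list(a = a, b = b, c = c))
}

.dp_accel <- function(y, gl) {
  # equations of motion from the point-mass double-pendulum Lagrangian
  # L = (1/6) m l^2 (th2d^2 + 4 th1d^2 + 3 th1d th2d cos(th1 - th2))
  #     + (1/2) m g l (3 cos th1 + cos th2)
  # reduced by m l^2 / 6; gl = g / l
  D <- y[1L] - y[2L]
  cD <- cos(D); sD <- sin(D)
  M <- matrix(c(8, 3 * cD, 3 * cD, 2), 2L, 2L)
  rhs <- c(-3 * y[4L]^2 * sD - 9 * gl * sin(y[1L]),
           3 * y[3L]^2 * sD - 3 * gl * sin(y[2L]))
  solve(M, rhs)
}

#' Simulate a frictionless double pendulum
#'
#' Integrates the equations of motion of the point-mass double pendulum
#' (equal masses `m` at the end of each arm, equal lengths `l`), derived
#' from its Lagrangian via the Euler-Lagrange equations, with fixed-step
#' RK4. The conventional scalar observable for this system is
#' `sin(theta_1)`; use `as_time_series(ms, 1, sin)`.
#'
#' @param steps number of samples (>= 2). Default 1200.
#' @param dt integration step. Default 0.001.
#' @param init initial state `(theta1, theta2, theta1_dot, theta2_dot)`.
#'   Default `(pi/2, pi/2, -0.01, -0.005)`.
#' @param m,l,g mass, arm length and gravitational acceleration.
#' @return A `multi_series` with columns
#'   `(theta1, theta2, theta1_dot, theta2_dot)`.
#' @export
simulate_double_pendulum <- function(steps = 1200, dt = 0.001,
                                     init = c(pi / 2, pi / 2, -0.01, -0.005),
                                     m = 1, l = 1, g = 10) {
  stopifnot(length(init) == 4L, dt > 0, m > 0, l > 0)
  gl <- g / l
  f <- function(y) c(y[3L], y[4L], .dp_accel(y, gl))
  .new_multi(.rk4(f, init, dt, steps), dt, "double_pendulum",
             list(m = m, l = l, g = g))
}

#' Total energy along a double-pendulum trajectory
#'
#' Kinetic plus potential energy of the point-mass double pendulum, used to
#' monitor integration accuracy (the exact flow conserves it).
#'
#' @param ms a `multi_series` from [simulate_double_pendulum()], or a
#'   4-column state matrix.
#' @param m,l,g parameters; taken from the `multi_series` when available.
#' @return numeric vector of energies, one per sample.
#' @export
double_pendulum_energy <- function(ms, m = 1, l = 1, g = 10) {
  if (inherits(ms, "multi_series")) {
    m <- ms$params$m; l <- ms$params$l; g <- ms$params$g
    Y <- ms$states
  } else Y <- as.matrix(ms)
  kin <- (1 / 6) * m * l^2 *
    (Y[, 4L]^2 + 4 * Y[, 3L]^2 + 3 * Y[, 3L] * Y[, 4L] * cos(Y[, 1L] - Y[, 2L]))
  pot <- -(1 / 2) * m * g * l * (3 * cos(Y[, 1L]) + cos(Y[, 2L]))
  kin + pot
}
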