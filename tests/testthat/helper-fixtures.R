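# Shared fixtures, computed once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# The worked sinusoid example: x = sin t + sin 2t on [0, 10] at dt = 0.001,
# 41-delay centred embedding, closed rank-4 fits of both variants.
sinusoid_fixture <- function() {
  if (is.null(.fixture_cache$sinusoid)) {
    sim <- sinusoid_example(dt = 0.001, t_end = 10)
    emb <- centre_hankel(build_hankel(sim$ts, 41))
    .fixture_cache$sinusoid <- list(
      sim = sim,
      emb = emb,
      havok = fit_havok(emb, 4, closed = TRUE),
      shavok = fit_shavok(emb, 4, closed = TRUE))
  }
  .fixture_cache$sinusoid
}

# One long Lorenz trajectory (x coordinate) from which short windows are
# drawn, emulating repeated experiments with different initial conditions.
lorenz_x_long <- function(steps = 60000) {
  key <- paste0("lorenz", steps)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- simulate_lorenz(steps = steps)$states[, 1]
  .fixture_cache[[key]]
}

# Coarsely sampled Lorenz x(t): simulated at dt = 0.001, subsampled 100x.
lorenz_x_coarse <- function(n_coarse = 400) {
  x <- lorenz_x_long((n_coarse - 1) * 100 + 1)
  time_series(x[seq(1, length(x), by = 100)], dt = 0.1)
}

# Matrix logarithm via complex eigendecomposition (diagonalizable input);
# independent of the package's first-order continuous-time conversion.
eigen_logm <- function(M) {
  e <- eigen(M)
  Re(e$vectors %*% diag(log(e$values + 0i), nrow(M)) %*% solve(e$vectors))
}

# R^2 of y against a reference signal.
r_squared <- function(y, ref) 1 - sum((y - ref)^2) / sum((ref - mean(ref))^2)
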