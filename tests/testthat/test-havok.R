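test_that("discrete-to-continuous conversion is exact first-order arithmetic", {
  G <- matrix(c(0, -2, 2, 0), 2)
  out <- continuousize(diag(2), NULL, 0.01)
  expect_equal(out$A, matrix(0, 2, 2))
  expect_null(out$B)
  expect_equal(continuousize(diag(2) + 0.01 * G, NULL, 0.01)$A, G,
               tolerance = 1e-12)
  expect_equal(continuousize(diag(2), c(0, 0), 0.01)$B, c(0, 0))
})

test_that("single-SVD fit recovers the curvature-scale matrix of the worked example", {
  fx <- sinusoid_fixture()
  K <- curvature_from_model(fx$havok)$K
  # super-diagonal magnitudes track the analytic curvatures
  expect_equal(abs(K[1, 2]), 1.205e-2, tolerance = 1e-3)
  expect_equal(abs(K[2, 3]), 4.458e-3, tolerance = 1e-3)
  expect_equal(abs(K[3, 4]), 6.617e-3, tolerance = 1e-3)
})

test_that("a pure sinusoid yields a single near-imaginary conjugate pair", {
  tt <- seq(0, 10, by = 0.001)
  mod <- havok(sin(tt), m = 41, r = 2, dt = 0.001,
               variant = "havok", closed = TRUE)
  om <- model_spectrum(mod, "continuous")$omegas
  expect_equal(sort(Im(om)), c(-1, 1), tolerance = 1e-3)
  expect_lt(max(abs(Re(om))), 1e-3)
})

test_that("degenerate embeddings are rejected with a rank error", {
  const <- centre_hankel(build_hankel(time_series(rep(3, 101), dt = 0.01), 41))
  expect_error(fit_havok(const, 4, closed = TRUE), "rank-deficient")
  expect_error(fit_shavok(const, 4, closed = TRUE), "rank-deficient")
})

test_that("structured fit is antisymmetric with matching sub/super diagonals", {
  fx <- sinusoid_fixture()
  K <- curvature_from_model(fx$shavok)$K
  for (i in 1:3)
    expect_lt(abs(K[i, i + 1] + K[i + 1, i]), 1e-6)
  oracle <- gram_curvatures(fx$sim$derivatives(41, 4))
  expect_equal(curvature_from_model(fx$shavok)$kappas, oracle$kappas,
               tolerance = 1e-3)
  # and the off-tridiagonal leakage is far below the single-SVD fit's
  Kh <- curvature_from_model(fx$havok)$K
  expect_lt(5 * structure_report(K)$tridiag_index,
            structure_report(Kh)$tridiag_index)
})

test_that("the two variants converge on long records", {
  sim <- sinusoid_example(dt = 0.001, t_end = 100)
  emb <- centre_hankel(build_hankel(sim$ts, 41))
  Ah <- fit_havok(emb, 4, closed = TRUE)$A
  As <- fit_shavok(emb, 4, closed = TRUE)$A
  expect_lt(norm(As - Ah, "F") / norm(Ah, "F"), 1e-2)
})

test_that("forced fits have a reduced state and a forcing vector", {
  fx <- sinusoid_fixture()
  for (mod in list(fit_havok(fx$emb, 4), fit_shavok(fx$emb, 4))) {
    expect_false(mod$closed)
    expect_equal(mod$d, 3L)
    expect_equal(dim(mod$A), c(3L, 3L))
    expect_length(mod$B, 3L)
    expect_gt(sum(mod$B^2), 0)
  }
  expect_null(fx$havok$B)
  expect_equal(fx$havok$d, 4L)
})

test_that("model spectra follow both conversion paths", {
  fx <- sinusoid_fixture()
  zero <- fx$havok; zero$A <- matrix(0, 4, 4)
  expect_equal(model_spectrum(zero)$omegas, rep(0 + 0i, 4))

  om <- model_spectrum(fx$havok, "discrete_log")$omegas
  mags <- sort(unique(round(Mod(om), 6)))
  expect_equal(mags[2] / mags[1], 2, tolerance = 0.01)
  # spectra of real matrices close under conjugation
  expect_equal(sort(Im(om)), -rev(sort(Im(om))), tolerance = 1e-10)

  skew <- fx$havok; skew$A <- curvature_matrix(c(1, 0.5, 0.2))
  expect_lt(model_spectrum(skew, "continuous")$max_real, 1e-10)
})

test_that("fixed-step integration conserves norm under skew dynamics", {
  fx <- sinusoid_fixture()
  mod <- fx$havok
  mod$A <- matrix(0, 4, 4)
  traj <- simulate_model(mod, c(1, 2, 3, 4), steps = 10)
  expect_equal(traj, matrix(rep(c(1, 2, 3, 4), each = 10), 10))

  mod$A <- curvature_matrix(c(0.7, 0.5, 0.3))
  mod$dt <- 0.01
  traj <- simulate_model(mod, c(1, 0, 0, 0), steps = 1e4)
  norms <- sqrt(rowSums(traj^2))
  expect_lt(max(abs(norms - 1)), 1e-8)
})

test_that("the closed fit resimulates its own training coordinates", {
  fx <- sinusoid_fixture()
  mod <- fx$havok
  V <- mod$basis$V
  traj <- simulate_model(mod, V[1, ], steps = nrow(V))
  expect_gt(r_squared(traj[, 1], V[, 1]), 0.99)
})

test_that("lifting reconstructs the training signal and flags divergence", {
  fx <- sinusoid_fixture()
  mod <- fx$havok
  rec <- reconstruct_signal(mod, mod$basis$V)
  centre <- fx$sim$ts$values[21:(21 + mod$n - 1)]
  expect_lt(sqrt(sum((rec$values - centre)^2) / sum(centre^2)), 1e-10)

  zero_rec <- reconstruct_signal(mod, matrix(0, nrow(mod$basis$V), 4))
  expect_equal(zero_rec$values, mod$h0)

  # an unstable spectrum makes the reconstruction grow exponentially
  unstable <- mod
  unstable$A <- mod$A + 0.5 * diag(4)
  traj <- simulate_model(unstable, mod$basis$V[1, ], steps = nrow(mod$basis$V))
  expect_gt(sqrt(sum(traj[nrow(traj), ]^2)) / sqrt(sum(traj[1, ]^2)), 50)

  stripped <- mod; stripped$basis <- NULL
  expect_error(reconstruct_signal(stripped, mod$basis$V), "")
})

test_that("forcing estimation inverts the SVD coordinates", {
  fx <- sinusoid_fixture()
  forced <- fit_havok(fx$emb, 4)
  j <- 123L
  window <- fx$emb$H[, j] + fx$emb$h0[j]    # reconstruct the raw delay window
  expect_equal(estimate_forcing(forced, window), forced$basis$V[j, 4],
               tolerance = 1e-8)
  expect_equal(estimate_forcing(forced, rep(0, 41)), 0)
  expect_error(estimate_forcing(forced, rep(0, 40)), "length m")
  expect_error(estimate_forcing(fx$havok, rep(0, 41)), "closed")
})

test_that("models survive a serialization round trip with validation", {
  fx <- sinusoid_fixture()
  dir <- withr::local_tempdir()
  path <- file.path(dir, "model.json")
  forced <- fit_shavok(fx$emb, 4)
  write_havok_model(forced, path)
  back <- read_havok_model(path)
  expect_equal(back$A, forced$A, tolerance = 1e-12)
  expect_equal(back$B, forced$B, tolerance = 1e-12)
  expect_equal(back$h0, forced$h0, tolerance = 1e-12)
  expect_equal(back$basis$U, forced$basis$U, tolerance = 1e-12,
               ignore_attr = TRUE)

  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc$B <- NULL
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  expect_error(read_havok_model(path), "forced model")
})

test_that("model methods expose coefficients, residuals and summaries", {
  fx <- sinusoid_fixture()
  expect_equal(coef(fx$havok), fx$havok$A)
  forced <- fit_shavok(fx$emb, 4)
  cf <- coef(forced)
  expect_equal(dim(cf), c(3L, 4L))
  expect_equal(unname(cf[, 4]), forced$B)

  res <- residuals(fx$shavok)
  expect_equal(dim(res), c(9960L, 4L))
  expect_lt(max(abs(res)), 1e-2)

  s <- summary(fx$shavok)
  expect_s3_class(s, "summary.havok_model")
  expect_lt(s$structure$antisym_index, 0.01)

  fc <- predict(fx$havok, n_ahead = 5)
  expect_equal(dim(fc), c(5L, 4L))
})
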