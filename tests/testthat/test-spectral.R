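test_that("truncated SVD returns orthonormal factors with canonical signs", {
  b <- truncated_svd(diag(3), 2)
  expect_equal(b$S, c(1, 1))
  expect_equal(crossprod(b$U), diag(2), tolerance = 1e-10)
  expect_equal(crossprod(b$V), diag(2), tolerance = 1e-10)
  for (j in 1:2) expect_gt(b$U[which.max(abs(b$U[, j])), j], 0)

  set.seed(4)
  a <- rnorm(6); c2 <- rnorm(9)
  rank1 <- truncated_svd(outer(a, c2), 2)
  expect_lt(rank1$singular_values[2] / rank1$singular_values[1], 1e-12)

  expect_error(truncated_svd(matrix(1:6, 2), 3), "between 1 and")
  expect_error(truncated_svd(matrix(c(1, NA, 2, 3), 2), 1), "non-finite")
})

test_that("rank-4 truncation captures the centred sinusoid embedding", {
  fx <- sinusoid_fixture()
  b <- fx$havok$basis
  mass <- sum(b$S^2) / sum(b$singular_values^2)
  expect_gt(mass, 1 - 1e-10)
})

test_that("reconstruction error equals the first dropped singular-value ratio", {
  set.seed(5)
  M <- tcrossprod(matrix(rnorm(40), 8, 5) %*% diag(c(10, 5, 2, 1, 0.5)),
                  matrix(rnorm(60), 12, 5)) + matrix(rnorm(96, sd = 0.01), 8)
  r <- 3
  b <- truncated_svd(M, r)
  approx <- t(b$V %*% (b$S * t(b$U)))
  full <- svd(M)                                   # independent full-SVD oracle
  expect_equal(norm(M - approx, "2") / full$d[1], full$d[r + 1] / full$d[1],
               tolerance = 1e-10)
})

test_that("sign alignment fixes flips and rejects degenerate pairings", {
  set.seed(6)
  b <- truncated_svd(matrix(rnorm(80), 8, 10), 4)
  other <- b
  other$U[, c(2, 4)] <- -other$U[, c(2, 4)]
  other$V[, c(2, 4)] <- -other$V[, c(2, 4)]
  fixed <- align_bases(b, other)
  expect_equal(fixed$V, b$V)
  expect_equal(fixed$U, b$U)
  expect_equal(align_bases(b, b), b)

  overlaps_before <- abs(crossprod(other$V, b$V))
  overlaps_after <- abs(crossprod(fixed$V, b$V))
  expect_equal(overlaps_after, overlaps_before, tolerance = 1e-12)

  zeroed <- b
  zeroed$V[, 3] <- 0
  expect_error(align_bases(b, zeroed), "not in correspondence")
})

test_that("discrete polynomial bases are orthonormal with the stated degrees", {
  p1 <- discrete_polynomials(3, 1, "centred")
  expect_equal(p1$P[, 1], c(-1, 0, 1) / sqrt(2))

  leg <- discrete_polynomials(11, 3, "legendre")
  expect_equal(leg$P[, 1], rep(1 / sqrt(11), 11))

  full <- discrete_polynomials(5, 4, "centred")
  expect_equal(crossprod(full$P), diag(4), tolerance = 1e-12)
  # polynomials vanishing at the centre span only m - 1 dimensions on an
  # m-point grid (x^5 - 5x^3 + 4x vanishes identically on -2..2), so the
  # centred basis degenerates at r = m
  expect_error(discrete_polynomials(5, 5, "centred"), "degenerate")

  expect_error(discrete_polynomials(4, 2, "centred"), "odd")
  expect_error(discrete_polynomials(5, 6, "centred"), "between 1 and m")
})

test_that("centred polynomials converge to their continuous counterparts", {
  # closed form: the squared norm of x^3 - (3/5) p^2 x on [-p, p] is 8 p^7 / 175
  p <- 1.7
  num <- stats::integrate(function(x) (x^3 - 0.6 * p^2 * x)^2, -p, p,
                          rel.tol = 1e-12)$value
  expect_equal(num, 8 * p^7 / 175, tolerance = 1e-10)

  # the discrete degree-3 column tracks the normalized continuous polynomial
  m <- 201
  pb <- discrete_polynomials(m, 3, "centred")
  half <- (m - 1) / 2
  x <- pb$p / half                                  # rescale indices to [-1, 1]
  cont <- (x^3 - 0.6 * x) / sqrt(8 / 175)
  cosine <- abs(sum(pb$P[, 3] * cont)) /
    sqrt(sum(pb$P[, 3]^2) * sum(cont^2))
  expect_gt(cosine, 0.999)
})

test_that("mode-polynomial similarity scores behave as cosines", {
  P <- discrete_polynomials(21, 3, "centred")
  expect_equal(polynomial_similarity(P$P, P), rep(1, 3), tolerance = 1e-12)

  # exact orthogonal complement scores zero
  set.seed(7)
  Q <- qr.Q(qr(cbind(P$P, matrix(rnorm(21 * 3), 21))))
  expect_lt(max(polynomial_similarity(Q[, 4:6], P)), 1e-8)

  fx <- sinusoid_fixture()
  scores <- polynomial_similarity(fx$havok$basis,
                                  discrete_polynomials(41, 4, "centred"))
  expect_true(all(scores > 0.99))

  expect_error(polynomial_similarity(P$P[, 1:2], P), "shape mismatch")
})
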