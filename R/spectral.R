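#' Truncated SVD of a delay matrix, in temporal orientation
#'
#' Decomposes the transpose of `M`, so that for an `m x n` Hankel matrix the
#' factor `V` (n x r) holds the temporal singular vectors (the eigen-time-delay
#' coordinates) and `U` (m x r) holds the delay-direction modes, which for a
#' centred embedding resemble discrete orthogonal polynomials. A deterministic
#' sign convention is applied jointly to each (U, V) column pair -- the entry
#' of largest magnitude in the `U` column is made positive -- so repeated runs
#' are reproducible; the product `U diag(S) V'` is unchanged.
#'
#' @param M numeric matrix (finite entries), or a `delay_embedding` whose `H`
#'   is decomposed.
#' @param r truncation rank, `1 <= r <= min(dim(M))`.
#' @return An object of class `spectral_basis`: list with `U` (m x r),
#'   `S` (length r, descending, non-negative), `V` (n x r), `r`, and
#'   `singular_values` (the full spectrum, for rank diagnostics).
#' @export
truncated_svd <- function(M, r) {
  if (inherits(M, "delay_embedding")) M <- M$H
  if (!is.matrix(M)) M <- as.matrix(M)
  if (any(!is.finite(M))) stop("matrix contains non-finite entries")
  r <- as.integer(r)
  if (r < 1L || r > min(dim(M)))
    stop("'r' must be between 1 and min(dim(M)) = ", min(dim(M)))
  sv <- svd(t(M))
  V <- sv$u[, seq_len(r), drop = FALSE]
  U <- sv$v[, seq_len(r), drop = FALSE]
  for (j in seq_len(r)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) {
      U[, j] <- -U[, j]
      V[, j] <- -V[, j]
    }
  }
  structure(list(U = U, S = sv$d[seq_len(r)], V = V, r = r,
                 singular_values = sv$d),
            class = "spectral_basis")
}

#' @export
print.spectral_basis <- function(x, ...) {
  cat(sprintf("Spectral basis: rank %d, U %d x %d, V %d x %d\n",
              x$r, nrow(x$U), x$r, nrow(x$V), x$r))
  cat("  singular values:", paste(signif(x$S, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Suggested truncation rank from singular-value decay
#'
#' Counts the singular values with `sigma_i / sigma_1 > tol`. Suits closed
#' low-rank signals; chaotic data usually need a user-chosen rank.
#'
#' @param emb a `delay_embedding` or numeric matrix.
#' @param tol relative cutoff, default 1e-8.
#' @return integer rank suggestion (at least 1).
#' @export
suggest_rank <- function(emb, tol = 1e-8) {
  if (inherits(emb, "delay_embedding")) emb <- emb$H
  d <- svd(emb, nu = 0, nv = 0)$d
  max(1L, sum(d / d[1L] > tol))
}

#' Align the signs of one spectral basis to another
#'
#' Two independently computed SVDs carry independent sign ambiguities, which
#' would make products such as `V2' V1` ill-defined. This flips the sign of
#' each (U, V) column pair of `other` so that every diagonal entry of
#' `t(other$V) %*% ref$V` is non-negative. Magnitudes of the overlaps are
#' never changed, only signs.
#'
#' @param ref reference `spectral_basis`.
#' @param other basis to align; must have the same rank and the same number of
#'   `V` rows as `ref`.
#' @return `other`, sign-aligned.
#' @export
align_bases <- function(ref, other) {
  stopifnot(inherits(ref, "spectral_basis"), inherits(other, "spectral_basis"))
  if (ref$r != other$r) stop("ranks differ")
  if (nrow(ref$V) != nrow(other$V)) stop("V row counts differ")
  ov <- colSums(other$V * ref$V)
  if (any(abs(ov) < 1e-6))
    stop("modes not in correspondence: |diagonal overlap| < 1e-6 for mode ",
         which(abs(ov) < 1e-6)[1L])
  flip <- which(ov < 0)
  other$U[, flip] <- -other$U[, flip, drop = FALSE]
  other$V[, flip] <- -other$V[, flip, drop = FALSE]
  other
}

#' Discrete orthonormal polynomial bases on the centred index grid
#'
#' Builds the orthonormal polynomial columns that the delay-direction modes of
#' a (centred) Hankel SVD converge to. With the centred index vector
#' `p = (-(m-1)/2, ..., 0, ..., (m-1)/2)`, the `centred` variant applies
#' Gram-Schmidt to the element-wise powers `p, p^2, ..., p^r` (degrees 1..r,
#' all vanishing at the centre index), while the `legendre` variant starts
#' from the constant vector, `1, p, ..., p^(r-1)` (degrees 0..r-1), matching
#' the modes of an uncentred embedding.
#'
#' @param m number of grid points; must be odd for the `centred` variant.
#' @param r number of columns (`r <= m`).
#' @param variant `"centred"` or `"legendre"`.
#' @return An object of class `polynomial_basis`: list with the `m x r` matrix
#'   `P` (orthonormal columns), `variant` and the index vector `p`.
#' @export
discrete_polynomials <- function(m, r, variant = c("centred", "legendre")) {
  variant <- match.arg(variant)
  m <- as.integer(m); r <- as.integer(r)
  if (r < 1L || r > m) stop("'r' must be between 1 and m")
  if (variant == "centred" && m %% 2L == 0L)
    stop("'m' must be odd for the centred variant")
  p <- seq.int(-(m - 1L) / 2L, (m - 1L) / 2L)
  degs <- if (variant == "centred") seq_len(r) else seq_len(r) - 1L
  P <- vapply(degs, function(k) {
    col <- p^k
    col / sqrt(sum(col^2))
  }, numeric(m))
  P <- matrix(P, nrow = m)
  for (j in seq_len(r)) {        # modified Gram-Schmidt
    for (k in seq_len(j - 1L))
      P[, j] <- P[, j] - sum(P[, j] * P[, k]) * P[, k]
    nrm <- sqrt(sum(P[, j]^2))
    if (nrm < 1e-12) stop("polynomial basis degenerate at column ", j)
    P[, j] <- P[, j] / nrm
  }
  structure(list(P = P, variant = variant, p = p), class = "polynomial_basis")
}

#' Cosine similarity between SVD modes and polynomial columns
#'
#' Scores, mode by mode, how closely the delay-direction singular vectors
#' match the discrete orthogonal polynomials of matching degree. Values near 1
#' indicate the embedding is in the well-sampled regime where the polynomial
#' correspondence holds.
#'
#' @param basis a `spectral_basis` (its `U` is used) or an `m x r` matrix.
#' @param poly a [discrete_polynomials()] basis (or `m x r` matrix) with the
#'   same dimensions.
#' @return numeric vector of `|cosine|` scores in `[0, 1]`, one per mode.
#' @export
polynomial_similarity <- function(basis, poly) {
  U <- if (inherits(basis, "spectral_basis")) basis$U else as.matrix(basis)
  P <- if (inherits(poly, "polynomial_basis")) poly$P else as.matrix(poly)
  if (!all(dim(U) == dim(P)))
    stop("shape mismatch: modes are ", nrow(U), " x ", ncol(U),
         ", polynomials ", nrow(P), " x ", ncol(P))
  un <- sqrt(colSums(U^2)); pn <- sqrt(colSums(P^2))
  abs(colSums(U * P)) / (un * pn)
}
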