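#' Frenet-Serret frame by Gram-Schmidt on trajectory derivatives
#'
#' Orthonormalizes the successive derivative vectors of a trajectory in
#' order (modified Gram-Schmidt), so the first frame vector is parallel to
#' the first derivative, the second spans the plane of the first two, and so
#' on. The frame vectors are the rows of the returned matrix.
#'
#' @param derivs list of numeric vectors of equal length `N` (derivative
#'   orders 1, 2, ...); they must be numerically independent (each residual
#'   after projection must retain more than 1e-10 of the input norm).
#' @return An object of class `frenet_frame`: list with the `r x N` matrix
#'   `E` whose rows are the orthonormal frame vectors.
#' @export
frenet_frame <- function(derivs) {
  stopifnot(is.list(derivs), length(derivs) >= 1L)
  N <- length(derivs[[1L]])
  if (!all(vapply(derivs, length, integer(1)) == N))
    stop("derivative vectors must all have the same length")
  r <- length(derivs)
  E <- matrix(0, r, N)
  for (i in seq_len(r)) {
    e <- as.numeric(derivs[[i]])
    nrm0 <- sqrt(sum(e^2))
    for (k in seq_len(i - 1L))
      e <- e - sum(e * E[k, ]) * E[k, ]
    nrm <- sqrt(sum(e^2))
    if (nrm0 == 0 || nrm <= 1e-10 * nrm0)
      stop("derivative vectors numerically dependent at order ", i)
    E[i, ] <- e / nrm
  }
  structure(list(E = E), class = "frenet_frame")
}

#' @export
print.frenet_frame <- function(x, ...) {
  cat(sprintf("Frenet-Serret frame: %d orthonormal vectors in R^%d\n",
              nrow(x$E), ncol(x$E)))
  invisible(x)
}

#' Build the antisymmetric tridiagonal curvature matrix
#'
#' @param kappas curvature values `kappa_1 .. kappa_{r-1}` (non-negative).
#' @return `r x r` matrix with `kappas` on the super-diagonal, `-kappas` on
#'   the sub-diagonal and zeros elsewhere.
#' @export
curvature_matrix <- function(kappas) {
  r <- length(kappas) + 1L
  K <- matrix(0, r, r)
  for (i in seq_along(kappas)) {
    K[i, i + 1L] <- kappas[i]
    K[i + 1L, i] <- -kappas[i]
  }
  K
}

#' Curvatures from Gram determinants of derivative vectors
#'
#' The exact (oracle) route to the generalized Frenet-Serret curvatures:
#' with `D_i` the square root of the determinant of the Gram matrix of the
#' first `i` derivative vectors (`D_0 = 1`), the i-th curvature is
#' `kappa_i = D_{i+1} D_{i-1} / (D_i^2 ||gamma'||)`. For two vectors this
#' reduces to the classical `||gamma' ^ gamma''|| / ||gamma'||^3`.
#'
#' @param derivs list of `k >= 2` derivative vectors (orders 1..k) of equal
#'   length.
#' @return An object of class `curvature_estimate`: list with `kappas`
#'   (length `k - 1`), `speed` (`||gamma'||`), the template matrix `K` built
#'   from the curvatures, and `source = "gram"`.
#' @export
gram_curvatures <- function(derivs) {
  stopifnot(is.list(derivs), length(derivs) >= 2L)
  k <- length(derivs)
  M <- do.call(cbind, lapply(derivs, as.numeric))
  norms <- sqrt(colSums(M^2))
  if (any(norms == 0)) stop("zero derivative vector supplied")
  D <- numeric(k + 1L)
  D[1L] <- 1
  for (i in seq_len(k)) {
    G <- crossprod(M[, seq_len(i), drop = FALSE])
    detG <- det(G)
    # relative test: det of the Gram of the normalized vectors
    if (detG / prod(norms[seq_len(i)]^2) < 1e-20)
      stop("derivative vectors numerically dependent at order ", i,
         " (singular Gram matrix)")
    D[i + 1L] <- sqrt(detG)
  }
  speed <- norms[1L]
  kappas <- vapply(seq_len(k - 1L), function(i)
    D[i + 2L] * D[i] / (D[i + 1L]^2 * speed), numeric(1))
  structure(list(kappas = kappas, speed = speed,
                 K = curvature_matrix(kappas), source = "gram"),
            class = "curvature_estimate")
}

#' Curvature estimates from a fitted model
#'
#' Scales the fitted dynamics by the centre-row speed, `K = A / ||h0'||`,
#' where `||h0'||` is the Euclidean norm of the finite-difference derivative
#' of the stored centre row, and reads the curvature magnitudes off the
#' super-diagonal of `K`. (Empirically the super-diagonal tracks the true
#' curvatures more closely than the sub-diagonal for single-SVD fits, and
#' the two agree for structured fits.)
#'
#' @param model a `havok_model` fitted on a centred embedding.
#' @param emb optional: the embedding the model was fitted on (only its `h0`
#'   is used; the model already stores it, so this is rarely needed).
#' @return A `curvature_estimate` with `kappas` (super-diagonal magnitudes),
#'   `speed`, the full normalized matrix `K`, and `source = "model"`.
#' @export
curvature_from_model <- function(model, emb = NULL) {
  stopifnot(inherits(model, "havok_model"))
  if (!is.null(emb)) {
    stopifnot(inherits(emb, "delay_embedding"))
    if (!emb$centred) stop("embedding must be centred")
    model$h0 <- emb$h0
    model$centred <- TRUE
  }
  if (!model$centred || is.null(model$h0))
    stop("curvature extraction needs a centred model (h0 unavailable)")
  speed <- delay_speed(model)
  K <- model$A / speed
  d <- nrow(K)
  kappas <- if (d >= 2L) abs(K[cbind(seq_len(d - 1L), seq_len(d - 1L) + 1L)])
            else numeric(0)
  structure(list(kappas = kappas, speed = speed, K = K, source = "model"),
            class = "curvature_estimate")
}

#' @export
print.curvature_estimate <- function(x, ...) {
  cat("Curvature estimate (", x$source, "):\n", sep = "")
  cat("  kappas:", paste(signif(x$kappas, 4), collapse = ", "), "\n")
  cat("  speed ||gamma'||:", signif(x$speed, 6), "\n")
  invisible(x)
}

#' Antisymmetry and tridiagonality diagnostics of a dynamics matrix
#'
#' Quantifies how far a fitted dynamics matrix is from the ideal
#' antisymmetric tridiagonal curvature form:
#' `antisym_index = ||A + A'||_F / (2 ||A||_F)` (0 for an exactly
#' antisymmetric matrix, 1 for a symmetric one) and `tridiag_index`, the
#' fraction of squared Frobenius mass outside the tridiagonal band. The
#' largest eigenvalue real part is reported as a stability indicator.
#'
#' @param A square numeric matrix with finite entries.
#' @return An object of class `havok_structure`: list with `antisym_index`,
#'   `tridiag_index` and `max_real`.
#' @export
structure_report <- function(A) {
  if (inherits(A, "havok_model")) A <- A$A
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("matrix must be square")
  if (any(!is.finite(A))) stop("matrix contains non-finite entries")
  nF <- norm(A, "F")
  anti <- if (nF == 0) 0 else norm(A + t(A), "F") / (2 * nF)
  d <- nrow(A)
  band <- abs(row(A) - col(A)) <= 1L
  tri <- if (nF == 0) 0 else sum(A[!band]^2) / nF^2
  structure(list(antisym_index = anti, tridiag_index = tri,
                 max_real = max(Re(eigen(A, only.values = TRUE)$values))),
            class = "havok_structure")
}

#' @export
print.havok_structure <- function(x, ...) {
  cat(sprintf(
    "Structure report: antisym_index = %.4g, tridiag_index = %.4g, max Re(omega) = %.4g\n",
    x$antisym_index, x$tridiag_index, x$max_real))
  invisible(x)
}
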