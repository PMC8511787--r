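#' Write a fitted model to disk
#'
#' Serializes a `havok_model` as a JSON document (dynamics `A`, forcing `B`,
#' singular values, sampling period, rank, variant and flags) plus companion
#' dense CSV files, in the same directory, for the delay modes `U` and -- for
#' centred models -- the centre row `h0`. The temporal coordinates `V` are
#' not serialized (they scale with the training data; refit to recover them).
#'
#' @param model a fitted `havok_model`.
#' @param path output path for the JSON document (e.g. `model.json`); the
#'   companions are written next to it as `<stem>_basis.csv` and
#'   `<stem>_h0.csv`.
#' @return `path`, invisibly.
#' @export
write_havok_model <- function(model, path) {
  stopifnot(inherits(model, "havok_model"))
  stem <- sub("\\.json$", "", path)
  basis_file <- paste0(basename(stem), "_basis.csv")
  h0_file <- if (model$centred) paste0(basename(stem), "_h0.csv") else NULL
  doc <- list(
    format = "havok_model",
    variant = model$variant, closed = model$closed, centred = model$centred,
    r = model$r, d = model$d, m = model$m, n = model$n,
    dt = model$dt, t0 = model$t0,
    A = model$A, B = model$B, S = model$basis$S,
    basis_file = basis_file, h0_file = h0_file)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null")
  utils::write.table(model$basis$U, file.path(dirname(path), basis_file),
                     sep = ",", row.names = FALSE,
                     col.names = paste0("u", seq_len(model$r)))
  if (model$centred)
    utils::write.table(data.frame(h0 = model$h0),
                       file.path(dirname(path), h0_file),
                       sep = ",", row.names = FALSE)
  invisible(path)
}

#' Read a fitted model back from disk
#'
#' Loads a model written by [write_havok_model()] and validates its
#' invariants: shapes, descending non-negative singular values, orthonormal
#' delay modes, and the forced/closed dimension rule (`d = r - 1` with `B`
#' present when forced, `d = r` with no `B` when closed).
#'
#' @param path path to the JSON document.
#' @return A `havok_model` (without temporal coordinates `V`).
#' @export
read_havok_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "havok_model"))
    stop("not a havok model document: ", path)
  A <- as.matrix(doc$A)            # read back row-major, already d x d
  A <- matrix(as.numeric(A), doc$d, doc$d)
  B <- if (is.null(doc$B) || !length(doc$B)) NULL else as.numeric(doc$B)
  S <- as.numeric(doc$S)
  if (doc$closed && (!is.null(B) || doc$d != doc$r))
    stop("invalid model document: closed model must have d = r and no B")
  if (!doc$closed && (is.null(B) || doc$d != doc$r - 1L))
    stop("invalid model document: forced model must have d = r - 1 and B")
  if (is.unsorted(rev(S)) || any(S < 0))
    stop("invalid model document: singular values not descending/non-negative")
  U <- as.matrix(utils::read.csv(file.path(dirname(path), doc$basis_file)))
  if (!all(dim(U) == c(doc$m, doc$r)))
    stop("invalid model document: basis shape mismatch")
  orth <- max(abs(crossprod(U) - diag(doc$r)))
  if (orth > 1e-8)
    stop("invalid model document: delay modes not orthonormal (max dev ",
         signif(orth, 3), ")")
  h0 <- NULL
  if (doc$centred) {
    h0 <- utils::read.csv(file.path(dirname(path), doc$h0_file))$h0
    if (length(h0) != doc$n) stop("invalid model document: h0 length mismatch")
  }
  structure(list(A = A, B = B, d = doc$d, r = doc$r, dt = doc$dt,
                 variant = doc$variant, centred = doc$centred,
                 closed = doc$closed,
                 basis = list(U = U, S = S, V = NULL),
                 basis2 = NULL, h0 = h0, m = doc$m, n = doc$n, t0 = doc$t0,
                 call = NULL),
            class = "havok_model")
}
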