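# Orthogonal correction projector Psi = I - sum_i v_i v_i'.
#
# The accumulated vectors span the center-specific subspace V; Psi projects
# onto its orthogonal complement U, where models are trained and features
# are comparable between centers.

#' Build a correction projector from accumulated vectors
#'
#' Sequentially re-orthonormalizes the supplied vectors and realizes the
#' projector `Psi = I - sum_i v_i v_i'` onto their orthogonal complement.
#' With no vectors the projector is the identity (no correction).
#'
#' @param vectors Accumulated directions: a list of numeric vectors, an
#'   N x J matrix of columns, or `NULL`/empty for the identity.
#' @param n Feature dimension, required only when `vectors` is empty.
#' @param tol Dependence tolerance for the orthogonalization (default 1e-10).
#' @return An object of class `"irma_projector"` with elements `vectors`
#'   (N x J orthonormal columns), `matrix` (N x N), `n`, `rank` (= N - J).
#' @export
#' @examples
#' p <- build_projector(list(c(1, 0, 0)))
#' p$matrix # diag(0, 1, 1)
build_projector <- function(vectors = NULL, n = NULL, tol = 1e-10) {
  if (is.matrix(vectors)) {
    if (is.null(n)) n <- nrow(vectors)
    vectors <- if (ncol(vectors)) asplit(vectors, 2) else list()
  }
  if (is.null(vectors)) vectors <- list()
  if (length(vectors) == 0L) {
    if (is.null(n)) stop("n is required for an empty projector", call. = FALSE)
    return(structure(list(vectors = matrix(0, n, 0), matrix = diag(n),
                          n = n, rank = n), class = "irma_projector"))
  }
  n <- length(vectors[[1]])
  V <- NULL
  for (v in vectors) {
    if (length(v) != n) stop("vectors of unequal length", call. = FALSE)
    u <- orthogonalize(as.numeric(v), V, tol = tol)
    if (is.null(u)) {
      stop("degenerate input: vector linearly dependent on earlier ones",
           call. = FALSE)
    }
    V <- cbind(V, u)
  }
  psi <- diag(n) - tcrossprod(V)
  psi <- (psi + t(psi)) / 2
  structure(list(vectors = V, matrix = psi, n = n, rank = n - ncol(V)),
            class = "irma_projector")
}

#' @export
print.irma_projector <- function(x, ...) {
  cat("Correction projector: removes", ncol(x$vectors), "of", x$n,
      "dimensions (rank", x$rank, ")\n")
  invisible(x)
}

#' Harmonize feature vectors with a correction projector
#'
#' Right-multiplies the feature matrix by `Psi`, removing every component
#' inside the accumulated subspace V. The map is idempotent and leaves rows
#' already orthogonal to V untouched.
#'
#' @param data Feature table or numeric matrix (samples x features).
#' @param projector An `"irma_projector"`.
#' @return Object of the same kind as `data` with corrected features.
#' @export
harmonize_features <- function(data, projector) {
  stopifnot(inherits(projector, "irma_projector"))
  if (is.data.frame(data)) {
    X <- feature_matrix(data)
    if (ncol(X) != projector$n) stop("feature dimension mismatch", call. = FALSE)
    return(set_feature_matrix(data, X %*% projector$matrix))
  }
  X <- as.matrix(data)
  if (ncol(X) != projector$n) stop("feature dimension mismatch", call. = FALSE)
  X %*% projector$matrix
}

#' Certificate that harmonized rows lie in the complement subspace U
#'
#' Returns the maximum absolute inner product between the rows of `X` and
#' the projector's accumulated vectors. After [harmonize_features()] this
#' residual is at numerical zero, certifying membership of U.
#'
#' @param projector An `"irma_projector"`.
#' @param X Feature table or numeric matrix.
#' @return Scalar maximum absolute residual (0 when no vectors accumulated).
#' @export
subspace_complement_check <- function(projector, X) {
  if (is.data.frame(X)) X <- feature_matrix(X)
  if (ncol(projector$vectors) == 0L) return(0)
  max(abs(as.matrix(X) %*% projector$vectors))
}
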