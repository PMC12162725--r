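# PCA-based coordinate system fitted on a space-defining reference cohort.
#
# Preprocessed (masked, global-mean-normalized) image vectors are projected
# onto the principal components of a fixed reference group; features are then
# z-scored with parameters estimated on the reference healthy controls so
# every data set lives in one shared, comparably scaled coordinate system.

#' Global mean normalization of a masked image vector
#'
#' Divides every entry by the mean over the masked entries so the masked
#' mean uptake becomes exactly one, the usual semi-quantification for brain
#' FDG-PET.
#'
#' @param x Numeric vector (one flattened masked scan) or matrix with one
#'   scan per row.
#' @param mask Optional logical/0-1 vector selecting the entries over which
#'   the mean is taken (default: all entries).
#' @return Normalized vector or matrix.
#' @export
#' @examples
#' global_mean_normalize(c(2, 4)) # c(2/3, 4/3)
global_mean_normalize <- function(x, mask = NULL) {
  if (is.matrix(x)) {
    return(t(apply(x, 1, global_mean_normalize, mask = mask)))
  }
  x <- as.numeric(x)
  idx <- if (is.null(mask)) seq_along(x) else which(as.logical(mask))
  m <- mean(x[idx])
  if (!is.finite(m) || m <= 0) {
    stop("invalid image: nonpositive masked mean", call. = FALSE)
  }
  x / m
}

#' Fit the PCA reference coordinate system
#'
#' Computes the principal axes of the mean-centered reference matrix via
#' singular value decomposition and retains the smallest number of
#' components whose cumulative variance fraction reaches `variance_target`.
#' Per-feature z-scoring parameters are estimated from the reference rows
#' flagged as healthy controls (all rows by default).
#'
#' @param reference R x D numeric matrix of preprocessed reference vectors
#'   (R >= 2 subjects).
#' @param variance_target Fraction of reference variance the retained
#'   components must cover, in (0, 1]; default 0.8.
#' @param hc Optional logical vector (length R) flagging the healthy-control
#'   rows used for the feature z-scoring parameters.
#' @return An object of class `"pca_basis"`: `G` (D x K orthonormal
#'   component columns, each column's largest-magnitude loading positive),
#'   `reference_mean` (D), `variance_fractions` (all positive-variance axes,
#'   descending), `k`, `zscore_mean`/`zscore_sd` (K), `mask_index` (optional,
#'   see [read_masked_volumes()]).
#' @export
fit_reference_space <- function(reference, variance_target = 0.8, hc = NULL) {
  reference <- as.matrix(reference)
  R <- nrow(reference)
  if (R < 2) stop("need at least two reference subjects", call. = FALSE)
  stopifnot(variance_target > 0, variance_target <= 1)
  mu <- colMeans(reference)
  Xc <- sweep(reference, 2L, mu)
  sv <- svd(Xc)
  pos <- sv$d > max(sv$d) * 1e-12
  if (!any(pos)) stop("degenerate input: reference has zero variance", call. = FALSE)
  d2 <- sv$d[pos]^2
  frac <- d2 / sum(d2)
  k <- which(cumsum(frac) >= variance_target - 1e-12)[1]
  G <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(G[, j]))
    if (G[i, j] < 0) G[, j] <- -G[, j]
  }
  basis <- structure(list(
    G = G,
    reference_mean = mu,
    variance_fractions = frac,
    k = k,
    variance_target = variance_target,
    zscore_mean = NULL,
    zscore_sd = NULL,
    mask_index = NULL
  ), class = "pca_basis")

  hc <- hc %||% rep(TRUE, R)
  stopifnot(length(hc) == R)
  feats <- extract_features(reference[hc, , drop = FALSE], basis)
  zm <- colMeans(feats)
  zs <- apply(feats, 2, stats::sd)
  if (any(zs <= 0)) {
    stop("degenerate feature: zero standard deviation in reference HCs",
         call. = FALSE)
  }
  basis$zscore_mean <- zm
  basis$zscore_sd <- zs
  basis
}

#' @export
print.pca_basis <- function(x, ...) {
  cat("PCA basis:", x$k, "components of", length(x$reference_mean),
      "input dimensions\n")
  cat(sprintf("  cumulative variance at K: %.3f (target %.2f)\n",
              sum(x$variance_fractions[seq_len(x$k)]), x$variance_target))
  invisible(x)
}

#' Project preprocessed vectors into the reference feature space
#'
#' Computes `(X - reference_mean) %*% G`, the coordinates of each row on the
#' retained principal components.
#'
#' @param X M x D matrix (or single D-vector) of preprocessed image vectors.
#' @param basis A `"pca_basis"`.
#' @return M x K feature matrix.
#' @export
extract_features <- function(X, basis) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != length(basis$reference_mean)) {
    stop("input dimension ", ncol(X), " does not match basis dimension ",
         length(basis$reference_mean), call. = FALSE)
  }
  sweep(X, 2L, basis$reference_mean) %*% basis$G
}

#' Z-score features with the reference-HC parameters
#'
#' @param x M x K feature matrix (or feature table, whose feature columns
#'   are transformed in place).
#' @param basis A `"pca_basis"` carrying `zscore_mean`/`zscore_sd`.
#' @return Object of the same kind with standardized features.
#' @export
zscore_features <- function(x, basis) {
  .apply_z(x, basis, forward = TRUE)
}

#' Undo the reference-HC z-scoring
#'
#' Inverse of [zscore_features()]; composing the two is the identity.
#'
#' @inheritParams zscore_features
#' @return Object of the same kind on the original feature scale.
#' @export
inverse_zscore <- function(x, basis) {
  .apply_z(x, basis, forward = FALSE)
}

.apply_z <- function(x, basis, forward) {
  if (is.null(basis$zscore_mean)) {
    stop("basis has no z-scoring parameters", call. = FALSE)
  }
  if (is.data.frame(x)) {
    return(set_feature_matrix(x, .apply_z(feature_matrix(x), basis, forward)))
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  stopifnot(ncol(x) == length(basis$zscore_mean))
  if (forward) {
    sweep(sweep(x, 2L, basis$zscore_mean), 2L, basis$zscore_sd, "/")
  } else {
    sweep(sweep(x, 2L, basis$zscore_sd, "*"), 2L, basis$zscore_mean, "+")
  }
}

#' Scree plot of a PCA basis
#'
#' @param object A `"pca_basis"`.
#' @param ... Unused.
#' @return A ggplot object showing per-component and cumulative variance
#'   fractions with the retention cut.
#' @export
autoplot.pca_basis <- function(object, ...) {
  df <- tibble::tibble(
    component = seq_along(object$variance_fractions),
    fraction = object$variance_fractions,
    cumulative = cumsum(object$variance_fractions)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$fraction), fill = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative), colour = "firebrick") +
    ggplot2::geom_hline(yintercept = object$variance_target,
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$k + 0.5, linetype = "dotted") +
    ggplot2::labs(x = "principal component", y = "variance fraction") +
    ggplot2::theme_minimal()
}
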