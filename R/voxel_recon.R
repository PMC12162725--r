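# Analytic voxel-space reconstruction of original, removed and corrected
# profiles.
#
# With features x = (X - mean) G, a feature-space correction projector Psi
# and the component matrix G, the corrected scan decomposes exactly as
#   X_hat = X_corr + X_rem,
#   X_rem  = x (I - Psi) G',
#   X_corr = mean + x Psi G',
# so the removed map is pure center-subspace content and the reference mean
# is carried entirely by the corrected profile.

#' Reconstruct a feature vector in voxel space
#'
#' Back-projects feature coordinates through the PCA basis:
#' `reference_mean + x %*% t(G)`. Feature vectors must be on the raw
#' (un-z-scored) scale; undo any scaling with [inverse_zscore()] first.
#'
#' @param x K-vector of feature coordinates (or M x K matrix).
#' @param basis A `"pca_basis"`.
#' @return D-vector (or M x D matrix) in voxel space. Lossy for inputs
#'   outside the span of the retained components; exact within it.
#' @export
reconstruct <- function(x, basis) {
  single <- is.null(dim(x))
  if (single) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != basis$k) {
    stop("feature dimension ", ncol(x), " does not match basis K = ",
         basis$k, call. = FALSE)
  }
  out <- sweep(x %*% t(basis$G), 2L, basis$reference_mean, "+")
  if (single) as.numeric(out) else out
}

#' Voxel-space profile removed by the correction
#'
#' The component of a scan residing in the center subspace V:
#' `x (I - Psi) G'`. Zero for feature vectors orthogonal to V; together with
#' [corrected_image()] it reassembles [reconstruct()] exactly.
#'
#' @param x K-vector (or M x K matrix) of raw-scale feature coordinates.
#' @param projector Feature-space `"irma_projector"` (K-dimensional).
#' @param basis A `"pca_basis"`.
#' @return D-vector (or M x D matrix), without the reference-mean offset.
#' @export
removed_profile <- function(x, projector, basis) {
  single <- is.null(dim(x))
  if (single) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  stopifnot(ncol(x) == projector$n, ncol(x) == basis$k)
  rem <- (x - x %*% projector$matrix) %*% t(basis$G)
  if (single) as.numeric(rem) else rem
}

#' Center-corrected scan in voxel space
#'
#' `reference_mean + x Psi G'`, i.e. the reconstruction of the harmonized
#' feature vector. Identically `reconstruct(x) - removed_profile(x)`.
#'
#' @inheritParams removed_profile
#' @return D-vector (or M x D matrix).
#' @export
corrected_image <- function(x, projector, basis) {
  single <- is.null(dim(x))
  if (single) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  stopifnot(ncol(x) == projector$n, ncol(x) == basis$k)
  out <- reconstruct(x %*% projector$matrix, basis)
  if (single && !is.null(dim(out))) as.numeric(out) else out
}

#' Voxel-wise z-map against reference volumes
#'
#' Standardizes each voxel by the mean and standard deviation of the
#' reference (healthy-control) volumes. Voxels with zero reference variance
#' are set to 0 with a warning.
#'
#' @param X D-vector (or M x D matrix) of voxel values.
#' @param reference R x D matrix of reference volumes.
#' @return Z-scored object of the same shape.
#' @export
voxel_zscore <- function(X, reference) {
  reference <- as.matrix(reference)
  mu <- colMeans(reference)
  sdv <- apply(reference, 2, stats::sd)
  zero <- sdv <= 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance voxel(s) set to 0 in z-map")
    sdv[zero] <- 1
  }
  z <- function(v) {
    out <- (v - mu) / sdv
    out[zero] <- 0
    out
  }
  if (is.null(dim(X))) z(as.numeric(X)) else t(apply(X, 1, z))
}

#' Full voxel-space decomposition of a feature vector
#'
#' Convenience wrapper returning the original reconstruction, removed
#' profile and corrected image (and, when reference volumes are supplied,
#' their voxel-wise z-maps) in one object. The identity
#' `original = corrected + removed` holds to numerical precision.
#'
#' @inheritParams removed_profile
#' @param reference Optional R x D reference volumes for z-maps.
#' @return A list of class `"voxel_profile"` with `original`, `removed`,
#'   `corrected`, and optionally `zmap_original`, `zmap_removed`,
#'   `zmap_corrected`.
#' @export
voxel_profile <- function(x, projector, basis, reference = NULL) {
  orig <- reconstruct(x, basis)
  rem <- removed_profile(x, projector, basis)
  corr <- corrected_image(x, projector, basis)
  out <- list(original = orig, removed = rem, corrected = corr)
  if (!is.null(reference)) {
    out$zmap_original <- voxel_zscore(orig, reference)
    # the removed profile is a difference map: z-scale without re-centering
    sdv <- apply(as.matrix(reference), 2, stats::sd)
    sdv[sdv <= 0] <- 1
    out$zmap_removed <- if (is.null(dim(rem))) rem / sdv else sweep(rem, 2, sdv, "/")
    out$zmap_corrected <- voxel_zscore(corr, reference)
  }
  structure(out, class = "voxel_profile")
}

#' @export
print.voxel_profile <- function(x, ...) {
  d <- if (is.null(dim(x$original))) length(x$original) else ncol(x$original)
  cat("Voxel profile decomposition over", d, "voxels",
      if (!is.null(x$zmap_original)) "(with z-maps)" else "", "\n")
  cat(sprintf("  max |original - corrected - removed| = %.2e\n",
              max(abs(x$original - x$corrected - x$removed))))
  invisible(x)
}
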