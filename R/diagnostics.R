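# Subspace-angle, per-feature significance and score diagnostics.

#' Principal angles between two subspaces
#'
#' Computes the principal angles between the column spans of `A` and `B` as
#' `acos` of the singular values of `A'B`, in degrees and ascending order.
#' The first angle measures the largest possible alignment between any two
#' unit vectors of the subspaces; each following angle the best alignment
#' orthogonal to the previous pairs. 0 degrees means a shared direction,
#' 90 degrees that no information is shared along that pair.
#'
#' @param A,B Matrices whose columns span the subspaces (single vectors
#'   allowed). Columns are re-orthonormalized internally.
#' @return An object of class `"subspace_angles"`: list with `angles`
#'   (degrees, ascending, length `min(dim A, dim B)`), `dim_a`, `dim_b`.
#' @export
#' @examples
#' principal_angles(c(1, 0), c(0, 1))$angles # 90
principal_angles <- function(A, B) {
  ortho <- function(M) {
    if (is.null(dim(M))) M <- matrix(M, ncol = 1)
    M <- as.matrix(M)
    nrm <- sqrt(colSums(M^2))
    if (any(nrm < 1e-12)) stop("degenerate input: zero column", call. = FALSE)
    Q <- qr.Q(qr(M))[, seq_len(ncol(M)), drop = FALSE]
    Q
  }
  Qa <- ortho(A); Qb <- ortho(B)
  if (nrow(Qa) != nrow(Qb)) stop("ambient dimensions differ", call. = FALSE)
  s <- svd(crossprod(Qa, Qb))$d
  s <- pmin(pmax(s, 0), 1)
  structure(list(
    angles = sort(acos(s) * 180 / pi),
    dim_a = ncol(Qa),
    dim_b = ncol(Qb)
  ), class = "subspace_angles")
}

#' @export
print.subspace_angles <- function(x, ...) {
  cat(sprintf("Principal angles (%d-dim vs %d-dim): %s degrees\n",
              x$dim_a, x$dim_b,
              paste(sprintf("%.1f", x$angles), collapse = ", ")))
  invisible(x)
}

#' Count features differing significantly between groups
#'
#' Runs a Kruskal-Wallis rank test (chi-square approximation with tie
#' correction, via [stats::kruskal.test()]) per feature and counts how many
#' fall below `alpha`, optionally Bonferroni-corrected to `alpha/K`.
#' A feature constant across all samples gets p = 1 by convention.
#'
#' @param data Feature table or numeric matrix (samples x features).
#' @param groups Group labels (used only when `data` is a matrix; for a
#'   feature table pass the column name via `group_col`).
#' @param group_col Label column name for feature tables (default
#'   `"center"`).
#' @param alpha Significance level (default 0.05).
#' @param bonferroni Divide `alpha` by the number of features (default
#'   FALSE).
#' @return List with `count`, `threshold`, and `table` (tibble of per-feature
#'   p-values and significance flags).
#' @export
count_significant_features <- function(data, groups = NULL,
                                       group_col = "center", alpha = 0.05,
                                       bonferroni = FALSE) {
  if (is.data.frame(data)) {
    X <- feature_matrix(data)
    groups <- data[[group_col]]
  } else {
    X <- as.matrix(data)
  }
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(table(groups) < 2L)) stop("every group needs >= 2 samples", call. = FALSE)
  K <- ncol(X)
  pvals <- vapply(seq_len(K), function(j) {
    v <- X[, j]
    if (max(v) - min(v) <= 0) return(1)
    stats::kruskal.test(v, groups)$p.value
  }, numeric(1))
  thr <- if (bonferroni) alpha / K else alpha
  feat <- colnames(X) %||% paste0("f", seq_len(K) - 1L)
  list(
    count = sum(pvals < thr),
    threshold = thr,
    table = tibble::tibble(feature = feat, p_value = pvals,
                           significant = pvals < thr)
  )
}

#' Macro one-vs-rest AUC for multiclass scores
#'
#' Averages, over classes, the rank AUC of that class's score column for
#' separating the class from the rest. For a prototype classifier use the
#' negated relevance distances as scores (see [gmlvq_scores()]).
#'
#' @param scores M x C numeric matrix, columns named (or ordered) by class.
#' @param true True class labels.
#' @return Macro-averaged AUC in `[0, 1]`.
#' @export
multiclass_auc <- function(scores, true) {
  scores <- as.matrix(scores)
  true <- as.character(true)
  classes <- colnames(scores) %||% sort(unique(true))
  if (length(unique(true)) < 2L) {
    stop("undefined: need at least two classes in the true labels",
         call. = FALSE)
  }
  aucs <- vapply(seq_along(classes), function(j) {
    pos <- true == classes[j]
    if (!any(pos) || all(pos)) return(NA_real_)
    r <- rank(scores[, j])
    n1 <- sum(pos); n0 <- sum(!pos)
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Class scores of a GMLVQ model
#'
#' Negated relevance distances to each prototype, suitable for
#' [multiclass_auc()].
#'
#' @param model A `"gmlvq"` model.
#' @param newdata Feature table or matrix.
#' @return M x C matrix with class-named columns.
#' @export
gmlvq_scores <- function(model, newdata) {
  X <- if (is.data.frame(newdata)) feature_matrix(newdata) else as.matrix(newdata)
  D <- .distance_matrix(X, model$prototypes, model$omega)
  colnames(D) <- model$classes
  -D
}
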