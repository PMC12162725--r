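# Internal helpers shared across modules.

#' Derive a stage-specific seed from a run seed
#'
#' All randomness in the package flows from a single user-supplied seed.
#' Stages (fold shuffling per CV repeat, synthetic draws, null replicates)
#' receive independent sub-seeds through a fixed integer hash so that partial
#' reruns of a pipeline reproduce exactly. The result always lies in
#' `[1, 2^31 - 2]`.
#'
#' @param seed Integer run seed.
#' @param stage Integer stage offset (>= 0).
#' @return A single integer seed.
#' @keywords internal
derive_seed <- function(seed, stage) {
  # 2^31 - 1 is prime; the multiplier is the Knuth multiplicative constant.
  # Doubles represent every intermediate value exactly (< 2^53).
  m <- 2147483647
  h <- (as.numeric(seed) %% m) * 48271 %% m
  h <- (h + as.numeric(stage) * 2246822519) %% m
  as.integer(h %% (m - 1) + 1)
}

#' Names of the feature columns of a feature table
#'
#' Feature tables store one sample per row with metadata columns
#' (`sample_id`, `center`, optionally `disease`) followed by numeric feature
#' columns named `f0`, `f1`, ... in order.
#'
#' @param data A feature table (data frame).
#' @return Character vector of feature column names, in feature order.
#' @export
feature_cols <- function(data) {
  nm <- names(data)[grepl("^f[0-9]+$", names(data))]
  if (length(nm) == 0L) {
    stop("no feature columns (named f0, f1, ...) found", call. = FALSE)
  }
  nm[order(as.integer(sub("^f", "", nm)))]
}

#' Extract the numeric feature matrix from a feature table
#'
#' @param data A feature table.
#' @return A numeric matrix (samples x features) with `sample_id` row names
#'   when present.
#' @export
feature_matrix <- function(data) {
  cols <- feature_cols(data)
  X <- as.matrix(as.data.frame(data)[, cols, drop = FALSE])
  storage.mode(X) <- "double"
  if ("sample_id" %in% names(data)) rownames(X) <- as.character(data$sample_id)
  X
}

#' Replace the feature columns of a feature table
#'
#' @param data A feature table.
#' @param X Numeric matrix with one row per row of `data`.
#' @return `data` with its feature columns overwritten by `X`.
#' @export
set_feature_matrix <- function(data, X) {
  cols <- feature_cols(data)
  stopifnot(nrow(X) == nrow(data), ncol(X) == length(cols))
  data[cols] <- as.data.frame(X, col.names = cols)
  data
}

#' Validate a labeled feature table
#'
#' Checks the contract for model-facing tables: a label column with at least
#' two classes each holding at least one sample, numeric feature columns with
#' no missing values, and at least as many samples as classes.
#'
#' @param data Feature table.
#' @param label_col Name of the class-label column (e.g. `"center"`).
#' @return `data`, invisibly, on success.
#' @keywords internal
validate_feature_set <- function(data, label_col) {
  if (!label_col %in% names(data)) {
    stop("label column '", label_col, "' not found", call. = FALSE)
  }
  X <- feature_matrix(data)
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)
    stop("missing feature values, e.g. row ", bad[1, 1], ", column ",
         feature_cols(data)[bad[1, 2]], call. = FALSE)
  }
  y <- data[[label_col]]
  if (anyNA(y)) stop("missing values in label column '", label_col, "'", call. = FALSE)
  tab <- table(y)
  if (length(tab) < 2L) stop("need at least two classes in '", label_col, "'", call. = FALSE)
  if (any(tab < 1L)) stop("every class needs at least one sample", call. = FALSE)
  if (nrow(data) < length(tab)) stop("fewer samples than classes", call. = FALSE)
  invisible(data)
}

# Numerically stable Gram-Schmidt against the columns of V (may be NULL).
# Returns the orthogonalized, renormalized vector, or NULL when the residual
# norm falls below tol (vector linearly dependent on V).
orthogonalize <- function(v, V, tol = 1e-10) {
  v <- as.numeric(v)
  nrm0 <- sqrt(sum(v^2))
  if (nrm0 < tol) return(NULL)
  v <- v / nrm0
  if (!is.null(V) && ncol(V) > 0L) {
    for (pass in 1:2) { # two passes for numerical safety
      v <- v - V %*% crossprod(V, v)
    }
    v <- as.numeric(v)
  }
  nrm <- sqrt(sum(v^2))
  if (nrm < tol) return(NULL)
  v / nrm
}

# Random orthonormal basis: N x k matrix with orthonormal columns, drawn
# uniformly (Haar) via QR of a Gaussian matrix. Uses the current RNG stream.
random_orthonormal <- function(n, k) {
  stopifnot(k <= n)
  qr.Q(qr(matrix(stats::rnorm(n * k), n, k)))[, seq_len(k), drop = FALSE]
}
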