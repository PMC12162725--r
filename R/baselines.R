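# Center-wise z-scoring: the statistics-based harmonization comparator.
# Each feature is standardized separately per center, with mean and sd
# estimated from that center's healthy controls only and applied to every
# sample of the center.

#' Fit a center-wise z-scoring baseline
#'
#' @param data Feature table with a center column.
#' @param center_col Name of the center column (default `"center"`).
#' @param hc Logical vector flagging healthy-control rows, or the name of a
#'   column in `data`. Default: rows whose `disease` column is `NA`, empty
#'   or `"HC"`; all rows when no `disease` column exists.
#' @return An object of class `"center_scaler"`: per-center tibbles of
#'   per-feature means and (unbiased) standard deviations.
#' @export
fit_center_scaler <- function(data, center_col = "center", hc = NULL) {
  X <- feature_matrix(data)
  centers <- as.character(data[[center_col]])
  if (is.character(hc) && length(hc) == 1L) hc <- as.logical(data[[hc]])
  if (is.null(hc)) {
    hc <- if ("disease" %in% names(data)) {
      is.na(data$disease) | data$disease %in% c("", "HC", "control")
    } else {
      rep(TRUE, nrow(data))
    }
  }
  stopifnot(length(hc) == nrow(data))
  params <- lapply(unique(centers), function(ct) {
    rows <- which(centers == ct & hc)
    if (length(rows) < 2L) {
      stop("invalid input: center '", ct, "' has fewer than 2 HC samples",
           call. = FALSE)
    }
    Xi <- X[rows, , drop = FALSE]
    sdv <- apply(Xi, 2, stats::sd)
    if (any(sdv <= 0)) {
      stop("invalid input: zero-variance feature in HCs of center '", ct, "'",
           call. = FALSE)
    }
    list(mean = colMeans(Xi), sd = sdv)
  })
  names(params) <- unique(centers)
  structure(list(params = params, center_col = center_col,
                 n_features = ncol(X)), class = "center_scaler")
}

#' Apply a center-wise z-scoring baseline
#'
#' Standardizes every sample with the HC-estimated parameters of its own
#' center: `(x - mean_center) / sd_center` per feature.
#'
#' @param data Feature table whose centers are all known to `scaler`.
#' @param scaler A `"center_scaler"`.
#' @return The feature table with transformed features.
#' @export
apply_center_scaler <- function(data, scaler) {
  stopifnot(inherits(scaler, "center_scaler"))
  X <- feature_matrix(data)
  stopifnot(ncol(X) == scaler$n_features)
  centers <- as.character(data[[scaler$center_col]])
  unknown <- setdiff(unique(centers), names(scaler$params))
  if (length(unknown)) {
    stop("unknown center(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (ct in unique(centers)) {
    rows <- centers == ct
    p <- scaler$params[[ct]]
    X[rows, ] <- sweep(sweep(X[rows, , drop = FALSE], 2L, p$mean), 2L,
                       p$sd, "/")
  }
  set_feature_matrix(data, X)
}

#' @export
print.center_scaler <- function(x, ...) {
  cat("Center-wise z-scoring baseline:", length(x$params), "center(s),",
      x$n_features, "features\n")
  invisible(x)
}
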