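# Feature-table and artifact serialization.
#
# Feature tables are delimited text (comma or tab), one row per sample,
# header sample_id, center, [disease], f0..f{N-1}. Models, projectors and
# PCA bases serialize to JSON at full double precision so deterministic
# fields round-trip bit-stably.

#' Read a labeled feature table
#'
#' @param path Path to a comma- or tab-delimited file with header columns
#'   `sample_id`, `center`, optionally `disease` (may be empty), and
#'   `f0..f{N-1}`.
#' @return A validated feature tibble.
#' @export
read_feature_table <- function(path) {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  data <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            progress = FALSE)
  need <- c("sample_id", "center")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cols <- feature_cols(data)
  for (cl in cols) {
    if (!is.numeric(data[[cl]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(data[[cl]]))) &
                     !is.na(data[[cl]]))
      stop("non-numeric feature values in column ", cl,
           if (length(bad)) paste0(", e.g. row ", bad[1]) else "",
           call. = FALSE)
    }
  }
  X <- feature_matrix(data)
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)
    stop("missing feature value at row ", bad[1, 1], ", column ",
         cols[bad[1, 2]], call. = FALSE)
  }
  if (anyDuplicated(data$sample_id)) {
    d <- data$sample_id[duplicated(data$sample_id)][1]
    stop("duplicate sample_id: ", d, call. = FALSE)
  }
  if ("disease" %in% names(data)) {
    data$disease <- as.character(data$disease)
    data$disease[data$disease %in% c("", "NA")] <- NA_character_
  }
  data$sample_id <- as.character(data$sample_id)
  data$center <- as.character(data$center)
  data
}

#' Write a feature table
#'
#' @param data Feature tibble.
#' @param path Output path; `.tsv` selects tab delimiting, anything else
#'   comma.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(data, path) {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  readr::write_delim(data, path, delim = delim)
  invisible(path)
}

.to_json <- function(x, path) {
  # 17 significant digits: doubles survive the decimal round trip bit-exactly
  jsonlite::write_json(x, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Serialize a GMLVQ model to JSON
#'
#' Stores prototypes, Omega, class list, configuration and training trace;
#' [read_gmlvq()] restores the model with bit-identical deterministic
#' fields.
#'
#' @param model A `"gmlvq"` model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmlvq <- function(model, path) {
  .to_json(list(
    type = "gmlvq",
    classes = model$classes,
    label_col = model$label_col %||% "center",
    prototypes = model$prototypes,
    omega = model$omega,
    trace = model$trace,
    cost_initial = model$cost_initial,
    cost_final = model$cost_final,
    config = model$config
  ), path)
}

#' Restore a GMLVQ model written by [write_gmlvq()]
#'
#' @param path Path to the JSON archive.
#' @return A `"gmlvq"` model.
#' @export
read_gmlvq <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$type, "gmlvq")) stop("not a gmlvq archive", call. = FALSE)
  W <- as.matrix(j$prototypes)
  rownames(W) <- j$classes
  omega <- as.matrix(j$omega)
  lambda <- crossprod(omega)
  structure(list(
    prototypes = W, omega = omega, lambda = (lambda + t(lambda)) / 2,
    classes = j$classes, trace = j$trace,
    cost_initial = j$cost_initial, cost_final = j$cost_final,
    config = j$config, label_col = j$label_col
  ), class = "gmlvq")
}

#' Serialize a center subspace (IRMA result or projector) to JSON
#'
#' Stores the accumulated vector list, the feature dimension, the class
#' list and the stopping curve (when available).
#'
#' @param x An `"irma_result"` or `"irma_projector"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vspace <- function(x, path) {
  if (inherits(x, "irma_result")) {
    curve <- dplyr::select(x$curve, -"recall")
    .to_json(list(
      type = "vspace", n = nrow(x$vectors), vectors = x$vectors,
      classes = x$classes, stopping_iteration = x$stopping_iteration,
      converged = x$converged, chance = x$chance, curve = curve,
      seed = x$seed
    ), path)
  } else if (inherits(x, "irma_projector")) {
    .to_json(list(type = "vspace", n = x$n, vectors = x$vectors,
                  classes = NULL, stopping_iteration = ncol(x$vectors),
                  converged = TRUE, chance = NULL, curve = NULL,
                  seed = NULL), path)
  } else {
    stop("cannot serialize object of class ", class(x)[1], call. = FALSE)
  }
}

#' Restore a center-subspace projector written by [write_vspace()]
#'
#' @param path Path to the JSON archive.
#' @return An `"irma_projector"`; the archive metadata (stopping curve,
#'   classes) is attached as attribute `"meta"`.
#' @export
read_vspace <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$type, "vspace")) stop("not a vspace archive", call. = FALSE)
  V <- if (length(j$vectors)) as.matrix(j$vectors) else matrix(0, j$n, 0)
  p <- build_projector(V, n = j$n)
  attr(p, "meta") <- j[c("classes", "stopping_iteration", "converged",
                         "chance", "curve", "seed")]
  p
}

#' Serialize a PCA basis to JSON
#'
#' @param basis A `"pca_basis"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pca_basis <- function(basis, path) {
  .to_json(list(
    type = "pca_basis", G = basis$G, reference_mean = basis$reference_mean,
    variance_fractions = basis$variance_fractions, k = basis$k,
    variance_target = basis$variance_target,
    zscore_mean = basis$zscore_mean, zscore_sd = basis$zscore_sd,
    mask_index = basis$mask_index
  ), path)
}

#' Restore a PCA basis written by [write_pca_basis()]
#'
#' @param path Path to the JSON archive.
#' @return A `"pca_basis"`.
#' @export
read_pca_basis <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$type, "pca_basis")) stop("not a pca_basis archive", call. = FALSE)
  structure(list(
    G = as.matrix(j$G), reference_mean = j$reference_mean,
    variance_fractions = j$variance_fractions, k = j$k,
    variance_target = j$variance_target,
    zscore_mean = j$zscore_mean, zscore_sd = j$zscore_sd,
    mask_index = j$mask_index
  ), class = "pca_basis")
}

#' Read masked NIfTI volumes as flattened vectors
#'
#' Loads a binary mask and a set of volumes (requires the RNifti package),
#' flattens each volume over the mask in fastest-varying-first order, and
#' returns the matrix of masked vectors. The mask index list is what a
#' [fit_reference_space()] basis stores for unambiguous back-projection.
#'
#' @param paths Character vector of volume file paths.
#' @param mask_path Path to a binary mask volume of matching dimensions.
#' @return List with `X` (length(paths) x D matrix), `mask_index` (linear
#'   indices of in-mask voxels), `dim` (volume dimensions).
#' @export
read_masked_volumes <- function(paths, mask_path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("read_masked_volumes() requires the RNifti package", call. = FALSE)
  }
  mask <- RNifti::readNifti(mask_path)
  idx <- which(as.array(mask) != 0)
  X <- t(vapply(paths, function(p) {
    v <- as.array(RNifti::readNifti(p))
    if (!identical(dim(v), dim(as.array(mask)))) {
      stop("volume ", p, " does not match the mask dimensions", call. = FALSE)
    }
    as.numeric(v[idx])
  }, numeric(length(idx))))
  list(X = X, mask_index = idx, dim = dim(as.array(mask)))
}

#' Write a masked voxel vector back to NIfTI
#'
#' @param x D-vector of voxel values (masked order).
#' @param mask_index Linear indices of the in-mask voxels.
#' @param dim Volume dimensions.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_voxel_map <- function(x, mask_index, dim, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("write_voxel_map() requires the RNifti package", call. = FALSE)
  }
  vol <- array(0, dim = dim)
  vol[mask_index] <- x
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(path)
}
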