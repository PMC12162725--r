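# Iterated Relevance Matrix Analysis (IRMA).
#
# Repeatedly: cross-validate center classification of healthy controls under
# the current correction projector; if performance is still above chance,
# train once on all samples, harvest the leading relevance eigenvector,
# project it out, and iterate. The accumulated eigenvectors span the
# center-specific subspace V.

#' Repeated stratified k-fold cross-validation of GMLVQ
#'
#' Estimates the balanced accuracy of a (optionally projector-restricted)
#' GMLVQ classifier by `repeats` independent rounds of stratified
#' `folds`-fold cross-validation. Folds are stratified on the label and
#' freshly randomized per repeat from the seed, so every sample is tested
#' exactly once per repeat and the whole procedure is reproducible.
#'
#' @inheritParams gmlvq
#' @param repeats,folds Number of CV repeats and folds (defaults 10 and 10).
#' @param seed Integer seed for the fold shuffles.
#' @return An object of class `"irma_cv"`: a list with `mean_bac`, `se`,
#'   `ci_lower`/`ci_upper` (normal-approximation 95% interval over the
#'   repeats x folds fold-level balanced accuracies), `bac` (all fold
#'   values), `recall` (per-class recall tibble averaged over repeats),
#'   `n_classes`, `repeats`, `folds`.
#' @export
repeated_cv <- function(data, label_col = "center", epochs = 30,
                        step_prototypes = 1, step_matrix = 2,
                        waypoint_window = 10, projector = NULL,
                        repeats = 10, folds = 10, seed = 1) {
  validate_feature_set(data, label_col)
  X <- feature_matrix(data)
  y <- as.character(data[[label_col]])
  classes <- sort(unique(y))
  counts <- table(y)
  if (min(counts) < folds) {
    stop("invalid config: smallest class has ", min(counts),
         " samples, fewer than folds = ", folds, call. = FALSE)
  }

  bac <- numeric(0)
  recall_acc <- matrix(0, repeats, length(classes),
                       dimnames = list(NULL, classes))
  for (r in seq_len(repeats)) {
    fold_id <- integer(length(y))
    rng <- derive_seed(seed, r)
    set.seed(rng)
    for (cl in classes) {
      idx <- which(y == cl)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    pred_all <- character(length(y))
    for (f in seq_len(folds)) {
      te <- which(fold_id == f)
      tr <- which(fold_id != f)
      m <- gmlvq_fit(X[tr, , drop = FALSE], y[tr], epochs = epochs,
                     step_prototypes = step_prototypes,
                     step_matrix = step_matrix,
                     waypoint_window = waypoint_window,
                     projector = projector)
      p <- predict(m, X[te, , drop = FALSE])
      pred_all[te] <- p
      bac <- c(bac, balanced_accuracy(y[te], p))
    }
    recall_acc[r, ] <- vapply(classes, function(cl) {
      mean(pred_all[y == cl] == cl)
    }, numeric(1))
  }

  m <- mean(bac)
  se <- stats::sd(bac) / sqrt(length(bac))
  structure(list(
    mean_bac = m,
    se = se,
    ci_lower = m - 1.96 * se,
    ci_upper = m + 1.96 * se,
    bac = bac,
    recall = tibble::tibble(class = classes,
                            recall = unname(colMeans(recall_acc))),
    n_classes = length(classes),
    repeats = repeats,
    folds = folds
  ), class = "irma_cv")
}

#' @export
print.irma_cv <- function(x, ...) {
  cat(sprintf("%dx repeated %d-fold CV: BAC %.3f [%.3f, %.3f] (chance %.3f)\n",
              x$repeats, x$folds, x$mean_bac, x$ci_lower, x$ci_upper,
              1 / x$n_classes))
  invisible(x)
}

#' Run the IRMA harmonization loop
#'
#' Iteratively removes center-discriminative directions from a
#' healthy-control feature table. Each iteration first estimates the
#' cross-validated balanced accuracy of center classification under the
#' current projector; if the estimate is no longer distinguishable from the
#' chance level `1/C`, the loop stops and the accumulated eigenvectors
#' define the center subspace V. Otherwise a model is trained once on all
#' samples, the leading eigenvector of its relevance matrix is
#' re-orthogonalized against V, appended, and the projector rebuilt.
#'
#' The stopping decision treats the CV estimate as noisy: the loop continues
#' only while `mean BAC > 1/C + stop_z * se`, a one-sided test that the
#' classifier still beats chance. With the default `stop_z = 3` a data set
#' with no center signal stops at iteration 0 with an empty V except in
#' roughly one run per thousand, while genuinely present signal (BAC more
#' than a few CV standard errors above chance) always triggers another
#' iteration.
#'
#' @inheritParams repeated_cv
#' @param max_iter Maximum number of accumulated vectors; defaults to the
#'   feature dimension. Reaching it without chance-level performance flags
#'   the result as non-converged rather than raising an error.
#' @param stop_z Number of CV standard errors above chance that still counts
#'   as chance-level (default 3; 0 reproduces a plain `mean <= 1/C` rule).
#' @param keep_models Keep the per-iteration full-data models (default TRUE).
#' @return An object of class `"irma_result"` with elements `vectors`
#'   (N x k orthonormal columns spanning V), `projector`, `curve` (tibble of
#'   per-iteration mean BAC, 95% CI and per-class recalls), `stopping_iteration`
#'   (= k), `converged`, `chance`, `models` (per-iteration full-data GMLVQ
#'   fits), `label_col`, `seed`.
#' @export
run_irma <- function(data, label_col = "center", epochs = 30,
                     step_prototypes = 1, step_matrix = 2,
                     waypoint_window = 10, repeats = 10, folds = 10,
                     max_iter = NULL, stop_z = 3, seed = 1,
                     keep_models = TRUE) {
  validate_feature_set(data, label_col)
  X <- feature_matrix(data)
  N <- ncol(X)
  classes <- sort(unique(as.character(data[[label_col]])))
  chance <- 1 / length(classes)
  max_iter <- max_iter %||% N
  stopifnot(max_iter <= N)

  vectors <- matrix(0, N, 0)
  models <- list()
  curve <- list()
  converged <- FALSE

  for (i in 0:max_iter) {
    proj <- build_projector(vectors, n = N)
    cv <- repeated_cv(data, label_col = label_col, epochs = epochs,
                      step_prototypes = step_prototypes,
                      step_matrix = step_matrix,
                      waypoint_window = waypoint_window,
                      projector = proj, repeats = repeats, folds = folds,
                      seed = derive_seed(seed, 1000 + i))
    rec <- stats::setNames(cv$recall$recall, cv$recall$class)
    curve[[i + 1L]] <- tibble::tibble(
      iteration = i, mean_bac = cv$mean_bac, se = cv$se,
      ci_lower = cv$ci_lower, ci_upper = cv$ci_upper,
      recall = list(rec)
    )
    if (cv$mean_bac <= chance + stop_z * cv$se) {
      converged <- TRUE
      break
    }
    if (i == max_iter) break

    full <- gmlvq(data, label_col = label_col, epochs = epochs,
                  step_prototypes = step_prototypes,
                  step_matrix = step_matrix,
                  waypoint_window = waypoint_window, projector = proj)
    if (keep_models) models[[i + 1L]] <- full
    v <- leading_eigenvectors(full$lambda, 1)$vectors[, 1]
    v <- orthogonalize(v, if (ncol(vectors)) vectors else NULL)
    if (is.null(v)) {
      # the new direction collapsed onto V: nothing left to remove
      converged <- TRUE
      break
    }
    vectors <- cbind(vectors, v)
    colnames(vectors) <- NULL
  }

  structure(list(
    vectors = vectors,
    projector = build_projector(vectors, n = N),
    curve = dplyr::bind_rows(curve),
    stopping_iteration = ncol(vectors),
    converged = converged,
    chance = chance,
    classes = classes,
    models = models,
    label_col = label_col,
    seed = seed
  ), class = "irma_result")
}

#' @export
print.irma_result <- function(x, ...) {
  k <- x$stopping_iteration
  cat("IRMA result:", k, "center-specific direction(s) removed",
      if (!x$converged) "(NOT converged)" else "", "\n")
  cat(sprintf("  center CV BAC: %.3f (iteration 0) -> %.3f (iteration %d), chance %.3f\n",
              x$curve$mean_bac[1], x$curve$mean_bac[nrow(x$curve)], k,
              x$chance))
  invisible(x)
}

#' Tidy an IRMA result
#'
#' @param x An `"irma_result"`.
#' @param ... Unused.
#' @return The per-iteration curve as a tibble: `iteration`, `mean_bac`,
#'   `se`, `ci_lower`, `ci_upper`, and one `recall_<class>` column per class.
#' @export
tidy.irma_result <- function(x, ...) {
  out <- dplyr::select(x$curve, -"recall")
  rec <- dplyr::bind_rows(lapply(x$curve$recall, function(r) {
    tibble::as_tibble(as.list(r))
  }))
  names(rec) <- paste0("recall_", names(rec))
  dplyr::bind_cols(out, rec)
}

#' Glance at an IRMA result
#'
#' @param x An `"irma_result"`.
#' @param ... Unused.
#' @return One-row tibble with the subspace dimension, convergence flag, and
#'   first/last balanced accuracies.
#' @export
glance.irma_result <- function(x, ...) {
  tibble::tibble(
    dim_v = x$stopping_iteration,
    converged = x$converged,
    chance = x$chance,
    bac_initial = x$curve$mean_bac[1],
    bac_final = x$curve$mean_bac[nrow(x$curve)],
    n_iterations = nrow(x$curve)
  )
}

#' Plot the IRMA balanced-accuracy curve
#'
#' Mean cross-validated balanced accuracy per iteration with its 95%
#' confidence ribbon and the chance level.
#'
#' @param object An `"irma_result"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.irma_result <- function(object, ...) {
  df <- object$curve
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$mean_bac)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lower,
                                      ymax = .data$ci_upper),
                         alpha = 0.25, fill = "seagreen") +
    ggplot2::geom_line(colour = "seagreen") +
    ggplot2::geom_point(colour = "seagreen") +
    ggplot2::geom_hline(yintercept = object$chance, linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = df$iteration) +
    ggplot2::labs(x = "IRMA iteration", y = "balanced accuracy (CV)") +
    ggplot2::theme_minimal()
}
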