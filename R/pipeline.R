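# End-to-end harmonization pipeline: learn the center subspace on healthy
# controls, correct all features, train the disease classifier in the
# complement subspace, and report diagnostics.

#' Run the full harmonization pipeline on feature tables
#'
#' Stages: (1) validate the configuration; (2) run the IRMA loop on the
#' control table to learn the center subspace V; (3) harmonize the control
#' and patient features with the resulting projector; (4) cross-validate
#' and train the disease classifier under the projector restriction;
#' (5) diagnostics: per-feature significance counts across centers before
#' and after harmonization, and principal angles between the disease model
#' space (two leading relevance eigenvectors) and V.
#'
#' @param controls Feature table of healthy controls with a `center` column.
#' @param patients Feature table with `center` and `disease` columns
#'   (disease non-missing rows are used for the disease model).
#' @param epochs,step_prototypes,step_matrix,waypoint_window GMLVQ training
#'   settings (defaults 30, 1, 2, 10).
#' @param repeats,folds Cross-validation design (defaults 10, 10).
#' @param max_iter,stop_z IRMA loop controls, see [run_irma()].
#' @param alpha Significance level for the feature counts (default 0.05).
#' @param seed Single run seed; every stage derives its own stream from it.
#' @param verbose Print per-stage progress (default FALSE).
#' @return An object of class `"irma_pipeline"`: `irma` (the
#'   [run_irma()] result), `projector`, `controls_harmonized`,
#'   `patients_harmonized`, `disease_cv` (projector-restricted
#'   [repeated_cv()] of the disease labels), `disease_model`,
#'   `disease_angles` (angles of the uncorrected disease model space to V),
#'   `feature_counts` (tibble of significant-feature counts before/after,
#'   with and without Bonferroni), `seed`.
#' @export
full_pipeline <- function(controls, patients, epochs = 30,
                          step_prototypes = 1, step_matrix = 2,
                          waypoint_window = 10, repeats = 10, folds = 10,
                          max_iter = NULL, stop_z = 3, alpha = 0.05,
                          seed = 1, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  # validate both tables before any training
  validate_feature_set(controls, "center")
  if (!"disease" %in% names(patients)) {
    stop("stage validate: patients need a 'disease' column", call. = FALSE)
  }
  pat <- dplyr::filter(patients, !is.na(.data$disease))
  validate_feature_set(pat, "disease")
  if (min(table(controls$center)) < folds) {
    stop("stage validate: smallest control center cohort (",
         min(table(controls$center)), ") is smaller than folds = ", folds,
         call. = FALSE)
  }
  if (min(table(pat$disease)) < folds) {
    stop("stage validate: smallest disease cohort (",
         min(table(pat$disease)), ") is smaller than folds = ", folds,
         call. = FALSE)
  }

  say("stage irma: learning center subspace on ", nrow(controls), " controls")
  irma <- run_irma(controls, label_col = "center", epochs = epochs,
                   step_prototypes = step_prototypes,
                   step_matrix = step_matrix,
                   waypoint_window = waypoint_window,
                   repeats = repeats, folds = folds, max_iter = max_iter,
                   stop_z = stop_z, seed = derive_seed(seed, 10))
  proj <- irma$projector
  say("stage irma: dim(V) = ", irma$stopping_iteration,
      if (!irma$converged) " (non-converged)" else "")

  say("stage harmonize: correcting features")
  controls_h <- harmonize_features(controls, proj)
  patients_h <- harmonize_features(patients, proj)

  say("stage disease: cross-validating disease model under the projector")
  disease_cv <- repeated_cv(pat, label_col = "disease", epochs = epochs,
                            step_prototypes = step_prototypes,
                            step_matrix = step_matrix,
                            waypoint_window = waypoint_window,
                            projector = proj, repeats = repeats,
                            folds = folds, seed = derive_seed(seed, 20))
  disease_model <- gmlvq(pat, label_col = "disease", epochs = epochs,
                         step_prototypes = step_prototypes,
                         step_matrix = step_matrix,
                         waypoint_window = waypoint_window,
                         projector = proj)
  uncorrected_model <- gmlvq(pat, label_col = "disease", epochs = epochs,
                             step_prototypes = step_prototypes,
                             step_matrix = step_matrix,
                             waypoint_window = waypoint_window)

  say("stage diagnostics: feature counts and subspace angles")
  counts <- tidyr::expand_grid(
    harmonized = c(FALSE, TRUE), bonferroni = c(FALSE, TRUE)
  )
  counts$count <- purrr::pmap_int(counts, function(harmonized, bonferroni) {
    tab <- if (harmonized) controls_h else controls
    count_significant_features(tab, group_col = "center", alpha = alpha,
                               bonferroni = bonferroni)$count
  })
  disease_angles <- if (irma$stopping_iteration > 0) {
    D2 <- leading_eigenvectors(uncorrected_model$lambda, 2)$vectors
    principal_angles(D2, irma$vectors)
  } else {
    NULL
  }

  structure(list(
    irma = irma,
    projector = proj,
    controls_harmonized = controls_h,
    patients_harmonized = patients_h,
    disease_cv = disease_cv,
    disease_model = disease_model,
    uncorrected_model = uncorrected_model,
    disease_angles = disease_angles,
    feature_counts = counts,
    alpha = alpha,
    seed = seed
  ), class = "irma_pipeline")
}

#' @export
print.irma_pipeline <- function(x, ...) {
  cat("IRMA harmonization pipeline\n")
  cat("  dim(V):", x$irma$stopping_iteration,
      if (!x$irma$converged) "(non-converged)" else "", "\n")
  cat(sprintf("  center CV BAC: %.3f -> %.3f (chance %.3f)\n",
              x$irma$curve$mean_bac[1],
              x$irma$curve$mean_bac[nrow(x$irma$curve)], x$irma$chance))
  cat(sprintf("  disease CV BAC under correction: %.3f [%.3f, %.3f]\n",
              x$disease_cv$mean_bac, x$disease_cv$ci_lower,
              x$disease_cv$ci_upper))
  fc <- x$feature_counts
  cat(sprintf("  significant features (alpha = %.2f): %d -> %d (plain), %d -> %d (Bonferroni)\n",
              x$alpha,
              fc$count[!fc$harmonized & !fc$bonferroni],
              fc$count[fc$harmonized & !fc$bonferroni],
              fc$count[!fc$harmonized & fc$bonferroni],
              fc$count[fc$harmonized & fc$bonferroni]))
  if (!is.null(x$disease_angles)) {
    cat("  angles of uncorrected disease model space to V:",
        paste(sprintf("%.1f", x$disease_angles$angles), collapse = ", "),
        "degrees\n")
  }
  invisible(x)
}
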