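# Seeded multi-center synthetic data with planted ground truth.
#
# Emulates the study design the harmonization targets: C center cohorts
# share one control distribution except for fixed center offsets confined
# to a planted low-dimensional subspace V*; disease classes add a mean
# shift along directions at a controllable principal angle to V*. Noise is
# isotropic (Gaussian by default, heavy-tailed t with 5 df optionally, since
# the harmonization makes no distributional assumption).

# Default center-offset coefficients: rows from the even-parity corners of
# the hypercube {-1, +1}^k, so every center is offset by one unit in every
# planted dimension, the offsets span all k dimensions (for C >= 2 suitable
# corners), pairwise distances are balanced, and the centroid is zero for
# the full parity class. Falls back to random unit-coefficient rows when C
# exceeds the number of parity corners.
hypercube_offsets <- function(n_centers, k) {
  stopifnot(n_centers >= 2, k >= 1)
  corners <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  parity <- corners[apply(corners, 1, prod) == 1, , drop = FALSE]
  if (k == 1) parity <- matrix(c(-1, 1), 2, 1)
  if (n_centers <= nrow(parity)) {
    return(unname(parity[seq_len(n_centers), , drop = FALSE]))
  }
  U <- matrix(stats::rnorm(n_centers * k), n_centers, k)
  U / abs(U) # random sign corners
}

#' Define the ground truth of a synthetic multi-center study
#'
#' Draws (from `seed`) an orthonormal planted center subspace `V*`, fixed
#' per-center offsets inside it, and orthonormal disease directions at a
#' requested principal angle to `V*`. By default the centers sit at
#' even-parity corners of the hypercube `(+-offset_scale)^k` inside `V*`,
#' i.e. every center is offset by `offset_scale` within-class standard
#' deviations along every planted dimension, so all k dimensions carry
#' comparable, fully identifiable center signal.
#'
#' @param n_features Feature dimension N (default 31).
#' @param n_centers Number of centers C (default 4).
#' @param center_dim Dimension k of the planted center subspace (default 3;
#'   the offsets span `min(k, C - 1)` dimensions, so the default C = 4,
#'   k = 3 plants a fully identifiable 3-dimensional subspace).
#' @param offset_scale Magnitude of each center's offset coefficient per
#'   planted dimension, in units of the within-class SD (default 2).
#' @param n_controls Healthy controls per center: scalar or length-C vector
#'   (default 30).
#' @param diseases Character vector of disease class names (default none).
#' @param n_patients Patients per disease per center (scalar; default 10
#'   when diseases are given).
#' @param disease_effect Mean-shift magnitude along each disease direction,
#'   in within-class SDs (default 3).
#' @param disease_angle Principal angle, degrees, between every disease
#'   direction and `V*` (default 90: disease signal orthogonal to the
#'   center subspace).
#' @param noise_sd Isotropic within-class standard deviation (default 1).
#' @param noise `"gaussian"` or `"t5"` (Student t, 5 df, scaled to
#'   `noise_sd`).
#' @param center_offsets Optional explicit C x k offset coefficient matrix
#'   (in SD units) overriding the simplex default.
#' @param seed Integer seed; the truth draw and the later sample draw use
#'   separate streams derived from it.
#' @return An object of class `"irma_truth"` holding `V_star` (N x k
#'   orthonormal), `center_offsets`, `disease_directions` (N x
#'   n_diseases), all sizes and scales, and the seed.
#' @export
synthetic_truth <- function(n_features = 31, n_centers = 4, center_dim = 3,
                            offset_scale = 2, n_controls = 30,
                            diseases = character(), n_patients = NULL,
                            disease_effect = 3, disease_angle = 90,
                            noise_sd = 1, noise = c("gaussian", "t5"),
                            center_offsets = NULL, seed = 1) {
  noise <- match.arg(noise)
  k <- center_dim
  nd <- length(diseases)
  if (k > n_features || nd > n_features - k) {
    stop("invalid config: planted dimensions exceed the feature dimension",
         call. = FALSE)
  }
  n_controls <- rep_len(n_controls, n_centers)
  n_patients <- n_patients %||% (if (nd > 0) 10 else 0)
  stopifnot(all(n_controls >= 1))

  set.seed(derive_seed(seed, 1))
  if (k > 0) {
    basis <- random_orthonormal(n_features, min(n_features, k + nd))
    V_star <- basis[, seq_len(k), drop = FALSE]
  } else {
    basis <- random_orthonormal(n_features, max(nd, 1L))
    V_star <- matrix(0, n_features, 0)
  }

  if (is.null(center_offsets)) {
    center_offsets <- if (k == 0) {
      matrix(0, n_centers, 0)
    } else {
      hypercube_offsets(n_centers, k) * offset_scale
    }
  }
  stopifnot(nrow(center_offsets) == n_centers, ncol(center_offsets) == k)

  disease_directions <- matrix(0, n_features, 0)
  if (nd > 0) {
    theta <- disease_angle * pi / 180
    # B: orthonormal directions fully outside V*
    B <- basis[, k + seq_len(nd), drop = FALSE]
    if (abs(cos(theta)) < 1e-12 || k == 0) {
      disease_directions <- B
    } else {
      if (nd > k) {
        stop("invalid config: ", nd, " disease directions at ", disease_angle,
             " degrees need center_dim >= ", nd, call. = FALSE)
      }
      A <- V_star %*% random_orthonormal(k, nd)  # inside V*
      disease_directions <- cos(theta) * A + sin(theta) * B
    }
    colnames(disease_directions) <- diseases
  }

  structure(list(
    n_features = n_features, n_centers = n_centers, center_dim = k,
    offset_scale = offset_scale, n_controls = n_controls,
    diseases = diseases, n_patients = n_patients,
    disease_effect = disease_effect, disease_angle = disease_angle,
    noise_sd = noise_sd, noise = noise,
    V_star = V_star, center_offsets = center_offsets,
    disease_directions = disease_directions,
    centers = paste0("C", seq_len(n_centers)),
    seed = seed
  ), class = "irma_truth")
}

#' @export
print.irma_truth <- function(x, ...) {
  cat("Synthetic truth:", x$n_centers, "centers,", x$n_features, "features,",
      "planted center subspace dim", x$center_dim, "\n")
  if (length(x$diseases)) {
    cat("  diseases:", paste(x$diseases, collapse = ", "), "at",
        x$disease_angle, "degrees to V*, effect", x$disease_effect, "SD\n")
  }
  invisible(x)
}

#' Generate a multi-center feature table from a synthetic truth
#'
#' Each sample is `center offset (inside V*) + disease shift (patients
#' only) + isotropic noise`; the draw is deterministic given the truth's
#' seed. Controls carry `disease = NA`.
#'
#' @param truth An `"irma_truth"` from [synthetic_truth()].
#' @return Feature table: `sample_id`, `center`, `disease`, `f0...f{N-1}`.
#' @export
generate_multicenter <- function(truth) {
  stopifnot(inherits(truth, "irma_truth"))
  N <- truth$n_features
  set.seed(derive_seed(truth$seed, 2))
  draw_noise <- function(n) {
    if (truth$noise == "gaussian") {
      matrix(stats::rnorm(n * N, sd = truth$noise_sd), n, N)
    } else {
      matrix(stats::rt(n * N, df = 5) * truth$noise_sd / sqrt(5 / 3), n, N)
    }
  }
  rows <- list()
  for (ci in seq_len(truth$n_centers)) {
    offset <- if (truth$center_dim > 0) {
      as.numeric(truth$V_star %*% truth$center_offsets[ci, ]) * truth$noise_sd
    } else {
      numeric(N)
    }
    groups <- c(list(list(disease = NA_character_, n = truth$n_controls[ci])),
                lapply(truth$diseases, function(d) {
                  list(disease = d, n = truth$n_patients)
                }))
    for (g in groups) {
      if (g$n < 1) next
      shift <- if (is.na(g$disease)) {
        numeric(N)
      } else {
        truth$disease_directions[, g$disease] * truth$disease_effect *
          truth$noise_sd
      }
      X <- draw_noise(g$n) +
        matrix(offset + shift, g$n, N, byrow = TRUE)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(center = truth$centers[ci], disease = g$disease),
        tibble::as_tibble(`colnames<-`(X, paste0("f", seq_len(N) - 1L)))
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("s%04d", seq_len(nrow(out)))),
    out
  )
}

#' Recovery error of an estimated center subspace
#'
#' Largest principal angle (degrees) between the span of the recovered
#' vectors and the planted subspace `V*`.
#'
#' @param V_hat N x J matrix of recovered vectors (J >= 1).
#' @param truth An `"irma_truth"` with a nonempty `V_star`.
#' @return Maximum principal angle in degrees.
#' @export
recovery_error <- function(V_hat, truth) {
  if (is.null(dim(V_hat))) V_hat <- matrix(V_hat, ncol = 1)
  if (ncol(V_hat) == 0L) stop("V_hat is empty", call. = FALSE)
  if (ncol(truth$V_star) == 0L) stop("truth has no planted subspace", call. = FALSE)
  max(principal_angles(V_hat, truth$V_star)$angles)
}
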