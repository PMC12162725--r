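# Fixtures are generated in code; nothing is stored on disk.

# Two well-separated isotropic Gaussian classes, mean shift `sep` SD along
# axis 1. Returns a feature tibble.
make_two_gaussians <- function(n = 100, dim = 10, sep = 6, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n * dim), 2 * n, dim)
  X[seq_len(n), 1] <- X[seq_len(n), 1] + sep
  colnames(X) <- paste0("f", seq_len(dim) - 1L)
  dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("s%03d", seq_len(2 * n)),
                   center = rep(c("A", "B"), each = n)),
    tibble::as_tibble(X)
  )
}

# Small labeled feature tibble from an explicit matrix.
make_feature_tbl <- function(X, labels, label_col = "center") {
  colnames(X) <- paste0("f", seq_len(ncol(X)) - 1L)
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("s%03d", seq_len(nrow(X)))),
    tibble::as_tibble(X)
  )
  out[[label_col]] <- labels
  out
}

# Haar-random orthonormal columns.
rand_orth <- function(n, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qr.Q(qr(matrix(rnorm(n * k), n, k)))[, seq_len(k), drop = FALSE]
}

# Reference planted-subspace fixture used across the IRMA tests.
planted_fixture <- function(seed = 1, ...) {
  truth <- synthetic_truth(seed = seed, ...)
  list(truth = truth, data = generate_multicenter(truth))
}
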