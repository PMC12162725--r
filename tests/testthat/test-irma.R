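# The unit suite runs the IRMA machinery at reduced CV size (3x5) on small
# fixtures; the full 10x10 reference configuration is exercised by the
# acceptance tests.

test_that("repeated CV partitions samples and is reproducible", {
  d <- make_two_gaussians(n = 20, dim = 4, sep = 8, seed = 20)
  cv1 <- repeated_cv(d, "center", epochs = 5, repeats = 2, folds = 5, seed = 3)
  cv2 <- repeated_cv(d, "center", epochs = 5, repeats = 2, folds = 5, seed = 3)
  expect_identical(cv1$bac, cv2$bac)
  expect_length(cv1$bac, 2 * 5)
  # perfectly separated classes: every fold model is perfect
  expect_equal(cv1$mean_bac, 1)
  expect_equal(cv1$recall$recall, c(1, 1))
  expect_error(repeated_cv(d, "center", folds = 25), "invalid config")
})

test_that("CV on structureless permuted labels sits at chance", {
  set.seed(21)
  X <- matrix(rnorm(120 * 6), 120, 6)
  d <- make_feature_tbl(X, sample(rep(letters[1:4], each = 30)))
  cv <- repeated_cv(d, "center", epochs = 10, repeats = 3, folds = 5, seed = 5)
  # chance = 0.25; allow the CI of the estimate
  expect_lt(abs(cv$mean_bac - 0.25), 5 * cv$se + 0.02)
})

test_that("irma recovers a planted subspace and stops near its dimension", {
  fx <- planted_fixture(seed = 42, n_features = 12, center_dim = 2,
                        n_centers = 3, offset_scale = 3, n_controls = 25)
  res <- run_irma(fx$data, "center", repeats = 3, folds = 5, seed = 42)
  expect_true(res$converged)
  k <- res$stopping_iteration
  expect_gte(k, 2)
  expect_lte(k, 6)
  expect_equal(ncol(res$vectors), k)
  # accumulated vectors orthonormal
  if (k > 0) {
    expect_lt(max(abs(crossprod(res$vectors) - diag(k))), 1e-8)
  }
  # final CV BAC at chance level
  expect_lte(res$curve$mean_bac[nrow(res$curve)], 1 / 3 + 0.05)
  # harmonization collapses the center means onto each other
  X0 <- feature_matrix(fx$data)
  Xh <- X0 %*% res$projector$matrix
  spread <- function(X) {
    M <- do.call(rbind, lapply(split(as.data.frame(X), fx$data$center),
                               colMeans))
    max(dist(M))
  }
  expect_lt(spread(Xh), spread(X0) / 2)
  # harmonized controls carry no center signal along V
  h <- harmonize_features(fx$data, res$projector)
  expect_lt(subspace_complement_check(res$projector, h), 1e-10)
})

test_that("irma is bitwise deterministic given the seed", {
  fx <- planted_fixture(seed = 9, n_features = 8, center_dim = 1,
                        n_centers = 2, offset_scale = 3, n_controls = 15)
  r1 <- run_irma(fx$data, "center", repeats = 2, folds = 3, seed = 4,
                 keep_models = FALSE)
  r2 <- run_irma(fx$data, "center", repeats = 2, folds = 3, seed = 4,
                 keep_models = FALSE)
  expect_identical(r1$vectors, r2$vectors)
  expect_identical(r1$curve$mean_bac, r2$curve$mean_bac)
})

test_that("identical center distributions give an empty V", {
  fx <- planted_fixture(seed = 33, center_dim = 0, n_controls = 20,
                        n_centers = 3, n_features = 10)
  res <- run_irma(fx$data, "center", repeats = 3, folds = 5, seed = 6)
  expect_true(res$converged)
  expect_equal(res$stopping_iteration, 0)
  expect_equal(ncol(res$vectors), 0)
  expect_equal(res$projector$matrix, diag(10))
})

test_that("result accessors expose the BAC curve", {
  fx <- planted_fixture(seed = 5, n_features = 6, center_dim = 1,
                        n_centers = 2, offset_scale = 4, n_controls = 12)
  res <- run_irma(fx$data, "center", repeats = 2, folds = 3, seed = 2)
  td <- tidy(res)
  expect_true(all(c("iteration", "mean_bac", "ci_lower", "ci_upper") %in%
                    names(td)))
  expect_true(any(grepl("^recall_", names(td))))
  expect_true(all(td$mean_bac >= 0 & td$mean_bac <= 1))
  g <- glance(res)
  expect_equal(g$dim_v, res$stopping_iteration)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
  # serialization round trip
  path <- withr::local_tempfile(fileext = ".json")
  write_vspace(res, path)
  p2 <- read_vspace(path)
  expect_equal(p2$matrix, res$projector$matrix, tolerance = 1e-15)
  expect_identical(attr(p2, "meta")$stopping_iteration,
                   res$stopping_iteration)
})
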