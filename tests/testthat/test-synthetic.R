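test_that("the planted truth satisfies its own geometry", {
  truth <- synthetic_truth(seed = 70, diseases = c("AD", "PD"),
                           disease_angle = 60)
  V <- truth$V_star
  expect_lt(max(abs(crossprod(V) - diag(3))), 1e-10)
  # requested angle between each disease direction and V* achieved
  for (j in 1:2) {
    a <- min(principal_angles(truth$disease_directions[, j], V)$angles)
    expect_lt(abs(a - 60), 0.5)
  }
  # directions mutually orthonormal
  D <- truth$disease_directions
  expect_lt(max(abs(crossprod(D) - diag(2))), 1e-10)
  # 90-degree case is exactly orthogonal to V*
  t90 <- synthetic_truth(seed = 70, diseases = "AD", disease_angle = 90)
  expect_lt(max(abs(crossprod(V, t90$disease_directions))), 1e-10)
  expect_error(synthetic_truth(n_features = 4, center_dim = 3,
                               diseases = c("a", "b")),
               "invalid config")
})

test_that("default center offsets are balanced hypercube corners", {
  truth <- synthetic_truth(seed = 71)
  co <- truth$center_offsets
  expect_equal(dim(co), c(4, 3))
  expect_true(all(abs(co) == 2))
  expect_equal(colSums(co), rep(0, 3)) # centered parity class
  expect_equal(qr(co)$rank, 3) # spans all planted dimensions
})

test_that("generated samples carry the planted structure", {
  truth <- synthetic_truth(seed = 72, diseases = "AD", n_patients = 8,
                           n_controls = 12)
  d <- generate_multicenter(truth)
  expect_equal(nrow(d), 4 * (12 + 8))
  expect_setequal(unique(d$center), paste0("C", 1:4))
  expect_equal(sum(is.na(d$disease)), 48)
  # determinism
  expect_identical(generate_multicenter(truth), d)
  # group means sit near their planted locations
  X <- feature_matrix(d)
  ctl1 <- d$center == "C1" & is.na(d$disease)
  planted <- as.numeric(truth$V_star %*% truth$center_offsets[1, ])
  err <- colMeans(X[ctl1, ]) - planted
  expect_lt(sqrt(sum(err^2)), 3 * sqrt(31 / 12)) # ~3x its expected norm
})

test_that("within-group covariance converges to the isotropic target", {
  truth <- synthetic_truth(seed = 73, n_features = 8, n_centers = 2,
                           center_dim = 1, n_controls = 2000)
  d <- generate_multicenter(truth)
  X <- feature_matrix(d[d$center == "C1", ])
  S <- cov(X)
  expect_lt(max(abs(S - diag(8))), 0.2)
  # heavy-tailed option keeps the target scale
  th <- synthetic_truth(seed = 73, n_features = 8, n_centers = 2,
                        center_dim = 1, n_controls = 2000, noise = "t5")
  Xh <- feature_matrix(generate_multicenter(th))
  expect_lt(abs(sd(Xh[, 5]) - 1), 0.15)
})

test_that("zero offsets leave centers indistinguishable in expectation", {
  truth <- synthetic_truth(seed = 74, center_dim = 0, n_controls = 15,
                           n_features = 6)
  d <- generate_multicenter(truth)
  X <- feature_matrix(d)
  fit <- summary(stats::manova(X ~ d$center))
  expect_gt(fit$stats[1, "Pr(>F)"], 0.01)
})

test_that("recovery error reproduces the principal-angle oracle", {
  truth <- synthetic_truth(seed = 75)
  expect_lt(recovery_error(truth$V_star, truth), 1e-3)
  # orthogonal complement directions are maximally wrong
  set.seed(75)
  W <- rand_orth(31, 6)
  Worth <- W - truth$V_star %*% crossprod(truth$V_star, W)
  Worth <- qr.Q(qr(Worth))[, 1:3]
  expect_equal(recovery_error(Worth, truth), 90, tolerance = 1e-6)
  # perturbed copy matches a direct SVD computation
  V_hat <- qr.Q(qr(truth$V_star + 0.1 * matrix(rnorm(93), 31, 3)))[, 1:3]
  s <- svd(crossprod(V_hat, truth$V_star))$d
  expect_equal(recovery_error(V_hat, truth),
               max(acos(pmin(pmax(s, 0), 1))) * 180 / pi, tolerance = 1e-8)
  expect_error(recovery_error(matrix(0, 31, 0), truth), "empty")
})
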