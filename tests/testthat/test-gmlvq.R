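test_that("omega trace normalization matches the square-sum definition", {
  expect_equal(normalize_omega(diag(2)), diag(2) / sqrt(2))
  m <- matrix(c(1, 1, 1, 1), 2) # squared entries sum to 4
  expect_equal(normalize_omega(m), m / 2)
  set.seed(11)
  o <- matrix(rnorm(25), 5)
  on <- normalize_omega(o)
  # oracle: direct elementwise square sum
  expect_equal(sum(on^2), 1, tolerance = 1e-12)
  expect_equal(sum(diag(crossprod(on))), 1, tolerance = 1e-12)
  expect_error(normalize_omega(matrix(0, 3, 3)), "invalid model")
})

test_that("relevance distance reduces to known closed forms", {
  expect_equal(relevance_distance(c(3, 4), c(0, 0), diag(2)), 25)
  set.seed(2)
  lam <- crossprod(matrix(rnorm(9), 3))
  x <- rnorm(3)
  expect_equal(relevance_distance(x, x, lam), 0)
  # null-space direction is ignored
  expect_equal(relevance_distance(c(2, 5), c(0, 0), diag(c(1, 0))), 4)
  expect_error(relevance_distance(1:3, 1:2, diag(2)), "dimension")
})

test_that("glvq cost matches a term-by-term oracle and handles edge terms", {
  W <- rbind(a = c(0, 0), b = c(4, 0))
  model <- structure(list(prototypes = W, omega = diag(2) / sqrt(2),
                          classes = c("a", "b"), label_col = "center"),
                     class = "gmlvq")
  lam <- crossprod(diag(2) / sqrt(2))
  X <- rbind(c(1, 1), c(3, -2), c(0, 0), c(2, 0))
  y <- c("a", "b", "a", "b")
  oracle <- sum(vapply(seq_len(4), function(i) {
    dp <- relevance_distance(X[i, ], W[y[i], ], lam)
    dm <- relevance_distance(X[i, ], W[setdiff(c("a", "b"), y[i]), ], lam)
    if (dp + dm == 0) 0 else (dp - dm) / (dp + dm)
  }, numeric(1)))
  got <- glvq_cost(model, list(X = X, y = y))
  expect_equal(got, oracle, tolerance = 1e-12)
  # sample at its own prototype contributes -1; equidistant contributes 0
  expect_equal(glvq_cost(model, list(X = rbind(c(0, 0)), y = "a")), -1)
  expect_equal(glvq_cost(model, list(X = rbind(c(2, 3)), y = "a")), 0)
  expect_error(glvq_cost(model, list(X = X, y = c("a", "b", "c", "a"))),
               "invalid model")
})

test_that("prediction equals the brute-force nearest-prototype oracle", {
  set.seed(3)
  for (rep in 1:5) {
    N <- sample(2:10, 1)
    C <- sample(2:4, 1)
    X <- matrix(rnorm(50 * N), 50, N)
    y <- sample(letters[1:C], 50, replace = TRUE)
    y[seq_len(C)] <- letters[1:C] # every class present
    m <- gmlvq_fit(X, y, epochs = 3)
    lam <- m$lambda
    oracle <- apply(X, 1, function(x) {
      d <- vapply(seq_len(C), function(j) {
        relevance_distance(x, m$prototypes[j, ], lam)
      }, numeric(1))
      m$classes[which.min(d)]
    })
    expect_identical(predict(m, X), oracle)
  }
  # tie rule: equidistant prototypes resolve to the smallest class index
  mt <- structure(list(prototypes = rbind(c(-1, 0), c(5, 0), c(1, 0)),
                       omega = diag(2), lambda = diag(2),
                       classes = c("c1", "c2", "c3")), class = "gmlvq")
  expect_identical(predict(mt, rbind(c(0, 3))), "c1")
  expect_identical(predict(mt, mt$prototypes[2, , drop = FALSE]), "c2")
  expect_error(predict(mt, matrix(0, 1, 3)), "features")
})

test_that("balanced accuracy is the mean per-class recall", {
  expect_equal(balanced_accuracy(c("a", "a"), c("a", "a")), 1)
  # confusion [[8,2],[5,5]] -> (0.8 + 0.5) / 2
  tr <- rep(c("a", "b"), c(10, 10))
  pr <- c(rep("a", 8), rep("b", 2), rep("a", 5), rep("b", 5))
  expect_equal(balanced_accuracy(tr, pr), 0.65)
  # constant predictor on a 4-class problem
  tr4 <- rep(letters[1:4], each = 3)
  expect_equal(balanced_accuracy(tr4, rep("a", 12)), 0.25)
  expect_error(balanced_accuracy(c("a"), c("a", "b")), "length")
})

test_that("leading eigenvectors agree with a power-iteration oracle", {
  le <- leading_eigenvectors(diag(c(3, 1, 0)), 2)
  expect_equal(le$values, c(3, 1))
  expect_equal(abs(le$vectors), cbind(c(1, 0, 0), c(0, 1, 0)))
  v <- c(1, -2, 2) / 3
  le1 <- leading_eigenvectors(tcrossprod(v), 1)
  expect_equal(abs(sum(le1$vectors[, 1] * v)), 1, tolerance = 1e-10)
  expect_gt(max(le1$vectors[, 1]) , 0) # sign convention
  set.seed(4)
  lam <- crossprod(matrix(rnorm(36), 6))
  # oracle: plain power iteration
  u <- rnorm(6)
  for (i in 1:500) { u <- lam %*% u; u <- u / sqrt(sum(u^2)) }
  got <- leading_eigenvectors(lam, 1)$vectors[, 1]
  expect_lt(min(sqrt(sum((got - u)^2)), sqrt(sum((got + u)^2))), 1e-6)
  expect_error(leading_eigenvectors(matrix(1:9, 3), 1), "symmetric")
})

test_that("discriminative projection equals explicit inner products", {
  set.seed(5)
  lam <- crossprod(matrix(rnorm(16), 4))
  m <- structure(list(lambda = lam), class = "gmlvq")
  V2 <- leading_eigenvectors(lam, 2)$vectors
  expect_equal(discriminative_projection(m, rbind(V2[, 1])), cbind(1, 0),
               tolerance = 1e-10)
  X <- matrix(rnorm(20), 5, 4)
  expect_equal(discriminative_projection(m, X), unname(X %*% V2),
               tolerance = 1e-12)
})

test_that("training separates well-separated Gaussians and lowers the cost", {
  d <- make_two_gaussians(seed = 1)
  m <- gmlvq(d, "center")
  expect_equal(balanced_accuracy(d$center, predict(m, d)), 1)
  # relevance concentrates on very few directions
  expect_gte(leading_eigenvectors(m$lambda, 1)$values[1], 0.9)
  expect_lte(m$cost_final, m$cost_initial)
  # invariants: Lambda PSD, trace 1, Lambda = t(Omega) Omega
  expect_lt(max(abs(m$lambda - crossprod(m$omega))), 1e-9)
  expect_equal(sum(diag(m$lambda)), 1, tolerance = 1e-9)
  expect_gte(min(eigen(m$lambda, symmetric = TRUE)$values), -1e-10)
})

test_that("planted discriminative directions are recovered at high SNR", {
  # 4-D problem, large sample: the leading relevance eigenvector aligns
  # closely with the only discriminative axis
  set.seed(6)
  n <- 400
  X <- matrix(rnorm(2 * n * 4), 2 * n, 4)
  X[seq_len(n), 1] <- X[seq_len(n), 1] + 6
  y <- rep(c("a", "b"), each = n)
  m <- gmlvq_fit(X, y)
  v <- leading_eigenvectors(m$lambda, 1)$vectors[, 1]
  expect_lt(acos(min(1, abs(v[1]))) * 180 / pi, 10)
})

test_that("a projector restriction confines the metric and removes signal", {
  d <- make_two_gaussians(n = 50, dim = 6, seed = 7)
  proj <- build_projector(list(c(1, rep(0, 5)))) # removes the signal axis
  m <- gmlvq(d, "center", projector = proj)
  # every row of Omega in the projector range
  expect_lt(max(abs(m$omega %*% (diag(6) - proj$matrix))), 1e-8)
  # with the only discriminative axis removed, training accuracy collapses
  # from 1.0 to near chance (residual reflects metric overfit to noise)
  bac <- balanced_accuracy(d$center, predict(m, d))
  expect_lt(bac, 0.75)
  m_un <- gmlvq(d, "center")
  expect_equal(balanced_accuracy(d$center, predict(m_un, d)), 1)
  expect_lte(m$cost_final, m$cost_initial)
})

test_that("tidy, glance and serialization round-trip a model", {
  d <- make_two_gaussians(n = 20, dim = 3, seed = 8)
  m <- gmlvq(d, "center", epochs = 5)
  td <- tidy(m)
  expect_equal(nrow(td), 2 * 3)
  expect_named(td, c("class", "feature", "prototype", "relevance"))
  g <- glance(m)
  expect_equal(g$n_classes, 2)
  expect_equal(g$cost_final, m$cost_final)
  path <- withr::local_tempfile(fileext = ".json")
  write_gmlvq(m, path)
  m2 <- read_gmlvq(path)
  expect_identical(m2$prototypes, m$prototypes)
  expect_identical(m2$omega, m$omega)
  expect_identical(m2$classes, m$classes)
  expect_identical(predict(m2, d), predict(m, d))
})
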