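test_that("principal angles match closed forms", {
  expect_equal(principal_angles(c(1, 0, 0), c(1, 0, 0))$angles, 0)
  expect_equal(principal_angles(c(1, 0), c(0, 1))$angles, 90)
  expect_equal(principal_angles(c(1, 0), c(1, 1) / sqrt(2))$angles, 45,
               tolerance = 1e-10)
  A <- diag(3)[, 1:2]
  expect_equal(principal_angles(A, A)$angles, c(0, 0))
  expect_error(principal_angles(c(0, 0), c(1, 0)), "degenerate")
})

test_that("principal angles agree with a brute-force alignment search", {
  # oracle: grid search over unit vectors of each (<= 2-D) subspace for the
  # best alignment; second angle by deflation within each subspace
  grid_angles <- function(A, B, step = 0.2 * pi / 180) {
    unitize <- function(M) qr.Q(qr(M))[, seq_len(ncol(M)), drop = FALSE]
    A <- unitize(as.matrix(A)); B <- unitize(as.matrix(B))
    span_grid <- function(M) {
      if (ncol(M) == 1) return(M)
      th <- seq(0, pi, by = step)
      M %*% rbind(cos(th), sin(th))
    }
    Ga <- span_grid(A); Gb <- span_grid(B)
    C <- abs(crossprod(Ga, Gb))
    i <- which(C == max(C), arr.ind = TRUE)[1, ]
    first <- acos(min(1, max(C))) * 180 / pi
    if (ncol(A) == 1 || ncol(B) == 1) return(first)
    # deflate: the within-subspace complements of the aligned pair
    a2 <- A %*% c(-sin((i[1] - 1) * step), cos((i[1] - 1) * step))
    b2 <- B %*% c(-sin((i[2] - 1) * step), cos((i[2] - 1) * step))
    c(first, acos(min(1, abs(sum(a2 * b2)))) * 180 / pi)
  }
  set.seed(50)
  for (rep in 1:10) {
    n <- sample(3:6, 1)
    p <- sample(1:2, 1); q <- sample(1:2, 1)
    A <- rand_orth(n, p); B <- rand_orth(n, q)
    got <- principal_angles(A, B)$angles
    oracle <- grid_angles(A, B)
    expect_lt(abs(got[1] - oracle[1]), 0.5)
    if (length(got) == 2) expect_lt(abs(got[2] - oracle[2]), 0.5)
  }
})

test_that("principal angles are symmetric and basis-invariant", {
  set.seed(51)
  A <- rand_orth(7, 2); B <- rand_orth(7, 3)
  ang1 <- principal_angles(A, B)$angles
  expect_equal(principal_angles(B, A)$angles, ang1, tolerance = 1e-8)
  # random rotation within each subspace
  RA <- qr.Q(qr(matrix(rnorm(4), 2)))
  RB <- qr.Q(qr(matrix(rnorm(9), 3)))
  expect_equal(principal_angles(A %*% RA, B %*% RB)$angles, ang1,
               tolerance = 1e-8)
  expect_length(ang1, 2)
  expect_false(is.unsorted(ang1))
})

test_that("significant-feature counting applies the Kruskal-Wallis test", {
  set.seed(52)
  g <- rep(letters[1:3], each = 25)
  X <- matrix(rnorm(75 * 8), 75, 8)
  X[g == "b", 3] <- X[g == "b", 3] + 5 # one strongly shifted feature
  res <- count_significant_features(X, g, alpha = 0.01)
  expect_true(res$table$significant[3])
  expect_equal(res$table$p_value[3],
               stats::kruskal.test(X[, 3], factor(g))$p.value)
  # bonferroni threshold definition
  resb <- count_significant_features(X, g, alpha = 0.05, bonferroni = TRUE)
  expect_equal(resb$threshold, 0.05 / 8)
  # constant feature gets p = 1
  X[, 5] <- 2
  expect_equal(count_significant_features(X, g)$table$p_value[5], 1)
  expect_error(count_significant_features(X, rep("a", 75)), "two groups")
})

test_that("macro one-vs-rest AUC behaves at its extremes and under the null", {
  sc <- rbind(c(5, 0), c(4, 1), c(1, 4), c(0, 5))
  colnames(sc) <- c("a", "b")
  y <- c("a", "a", "b", "b")
  expect_equal(multiclass_auc(sc, y), 1)
  expect_equal(multiclass_auc(-sc, y), 0)
  set.seed(53)
  nulls <- replicate(50, {
    s <- matrix(rnorm(60 * 3), 60, 3, dimnames = list(NULL, letters[1:3]))
    multiclass_auc(s, sample(letters[1:3], 60, replace = TRUE))
  })
  expect_lt(abs(mean(nulls) - 0.5), 0.03)
  expect_error(multiclass_auc(sc, c("a", "a", "a", "a")), "undefined")
})

test_that("gmlvq scores feed the AUC with sensible orderings", {
  d <- make_two_gaussians(n = 30, dim = 4, seed = 54)
  m <- gmlvq(d, "center", epochs = 10)
  sc <- gmlvq_scores(m, d)
  expect_identical(colnames(sc), m$classes)
  expect_gt(multiclass_auc(sc, d$center), 0.95)
})
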