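# Generalized Matrix Learning Vector Quantization (GMLVQ).
#
# A nearest-prototype classifier with an adaptive squared distance
#   d_Lambda(w, x) = (x - w)' Lambda (x - w),   Lambda = Omega' Omega,
# trained by batch waypoint gradient descent on the GLVQ cost
#   E = sum_mu phi[(d+ - d-) / (d+ + d-)],  phi(z) = z,
# where d+ is the distance to the prototype of the sample's own class and
# d- the closest prototype of any other class. Omega is trace-normalized so
# that Tr(Lambda) = 1; an optional orthogonal projector Psi restricts the
# metric by Omega -> Omega Psi after every matrix update.

#' Trace-normalize an auxiliary relevance matrix
#'
#' Scales `omega` so that the relevance matrix `Lambda = t(omega) %*% omega`
#' has unit trace, i.e. divides by the square root of the sum of squared
#' entries.
#'
#' @param omega Square numeric matrix with at least one nonzero entry.
#' @return The rescaled matrix.
#' @export
#' @examples
#' normalize_omega(diag(2)) # identity / sqrt(2)
normalize_omega <- function(omega) {
  s <- sum(omega^2)
  if (s <= 0 || !is.finite(s)) {
    stop("invalid model: omega has no nonzero entries", call. = FALSE)
  }
  omega / sqrt(s)
}

#' Relevance (generalized Euclidean) distance
#'
#' Computes `(x - w)' Lambda (x - w)` for a positive semi-definite relevance
#' matrix.
#'
#' @param x,w Numeric vectors of equal length.
#' @param lambda PSD relevance matrix.
#' @return Nonnegative scalar; zero exactly when `x - w` lies in the null
#'   space of `lambda`.
#' @export
relevance_distance <- function(x, w, lambda) {
  x <- as.numeric(x); w <- as.numeric(w)
  if (length(x) != length(w) || nrow(lambda) != length(x) ||
      ncol(lambda) != length(x)) {
    stop("dimension mismatch between x, w and lambda", call. = FALSE)
  }
  u <- x - w
  as.numeric(u %*% lambda %*% u)
}

# All pairwise squared relevance distances ||Omega (x_i - w_j)||^2.
# X: P x N, W: C x N, omega: N x N. Returns P x C.
.distance_matrix <- function(X, W, omega) {
  XO <- X %*% t(omega)            # P x N
  WO <- W %*% t(omega)            # C x N
  # ||a - b||^2 = ||a||^2 - 2 a.b + ||b||^2
  d <- rowSums(XO^2) - 2 * XO %*% t(WO)
  d <- sweep(d, 2L, rowSums(WO^2), "+")
  d[d < 0] <- 0
  d
}

# Per-sample cost terms mu = (d+ - d-)/(d+ + d-) with the removable
# singularity d+ = d- = 0 mapped to 0. y_idx: class index per sample.
.cost_terms <- function(D, y_idx) {
  P <- nrow(D)
  dplus <- D[cbind(seq_len(P), y_idx)]
  Dneg <- D
  Dneg[cbind(seq_len(P), y_idx)] <- Inf
  jminus <- max.col(-Dneg, ties.method = "first")
  dminus <- Dneg[cbind(seq_len(P), jminus)]
  denom <- dplus + dminus
  mu <- ifelse(denom > 0, (dplus - dminus) / denom, 0)
  list(mu = mu, dplus = dplus, dminus = dminus, jminus = jminus, denom = denom)
}

#' GLVQ cost of a model on a data set
#'
#' Sums `phi[(d+ - d-)/(d+ + d-)]` with identity `phi` over all samples,
#' where `d+` is the relevance distance to the sample's own-class prototype
#' and `d-` the closest other-class prototype. Each term lies in `[-1, 1]`;
#' a term with `d+ = d- = 0` is defined as 0.
#'
#' @param model A fitted [gmlvq()] model (or any list with `prototypes`,
#'   `omega`, `classes`).
#' @param data Feature table with the model's label column, or a list with
#'   elements `X` (matrix) and `y` (labels).
#' @return The summed cost, in `[-P, P]` for `P` samples.
#' @export
glvq_cost <- function(model, data) {
  if (is.data.frame(data)) {
    X <- feature_matrix(data)
    y <- as.character(data[[model$label_col %||% "center"]])
  } else {
    X <- data$X
    y <- as.character(data$y)
  }
  y_idx <- match(y, model$classes)
  if (anyNA(y_idx)) {
    stop("invalid model: data contains classes without a prototype: ",
         paste(unique(y[is.na(y_idx)]), collapse = ", "), call. = FALSE)
  }
  D <- .distance_matrix(X, model$prototypes, model$omega)
  sum(.cost_terms(D, y_idx)$mu)
}

# Batch mean gradient of the GLVQ cost wrt prototypes and omega.
.gmlvq_gradient <- function(X, y_idx, W, omega) {
  P <- nrow(X); C <- nrow(W)
  D <- .distance_matrix(X, W, omega)
  ct <- .cost_terms(D, y_idx)
  denom2 <- ct$denom^2
  gp <- ifelse(ct$denom > 0, 2 * ct$dminus / denom2, 0)   # dmu/dd+
  gm <- ifelse(ct$denom > 0, -2 * ct$dplus / denom2, 0)   # dmu/dd-
  Uplus <- X - W[y_idx, , drop = FALSE]
  Uminus <- X - W[ct$jminus, , drop = FALSE]
  lambda <- crossprod(omega)
  gW <- matrix(0, C, ncol(X))
  for (j in seq_len(C)) {
    ip <- which(y_idx == j)
    im <- which(ct$jminus == j)
    s <- numeric(ncol(X))
    if (length(ip)) s <- s + colSums(Uplus[ip, , drop = FALSE] * gp[ip])
    if (length(im)) s <- s + colSums(Uminus[im, , drop = FALSE] * gm[im])
    gW[j, ] <- -2 * as.numeric(lambda %*% s) / P
  }
  S <- crossprod(Uplus * gp, Uplus) + crossprod(Uminus * gm, Uminus)
  gO <- 2 * (omega %*% S) / P
  list(gW = gW, gO = gO, cost = sum(ct$mu))
}

# Apply the projector restriction (if any) and trace normalization to omega.
.restrict_omega <- function(omega, psi) {
  if (!is.null(psi)) omega <- omega %*% psi
  normalize_omega(omega)
}

#' Train a GMLVQ model
#'
#' Fits a one-prototype-per-class GMLVQ classifier by batch waypoint gradient
#' descent. Prototypes start at the class-conditional means and the auxiliary
#' matrix Omega at the (trace-normalized) identity, so training is fully
#' deterministic given the data. After every matrix update Omega is
#' right-multiplied by the optional projector and re-normalized, which
#' confines the learned metric to the projector's range (the subspace U
#' orthogonal to previously removed directions).
#'
#' The waypoint scheme keeps a rolling window of recent parameter states;
#' after each raw gradient step the window average is adopted instead
#' whenever it achieves a lower cost, and both step sizes are halved whenever
#' the accepted cost increases. The returned model is the visited state with
#' the lowest training cost, so its cost never exceeds the initial cost.
#'
#' @param data Feature table (rows = samples) with a label column and feature
#'   columns `f0...`.
#' @param label_col Name of the class-label column. Default `"center"`.
#' @param epochs Number of batch gradient iterations (default 30).
#' @param step_prototypes,step_matrix Initial step sizes for the prototype
#'   and matrix updates (defaults 1 and 2).
#' @param waypoint_window Number of recent states averaged by the waypoint
#'   scheme (default 10).
#' @param projector Optional [build_projector()] result restricting the
#'   metric.
#' @return An object of class `"gmlvq"` with elements `prototypes` (C x N),
#'   `omega`, `lambda`, `classes`, `label_col`, `trace` (cost per epoch),
#'   `cost_initial`, `cost_final`, and the configuration used.
#' @export
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(
#'   sample_id = sprintf("s%02d", 1:40),
#'   center = rep(c("A", "B"), each = 20),
#'   f0 = rnorm(40, mean = rep(c(0, 3), each = 20)),
#'   f1 = rnorm(40)
#' )
#' m <- gmlvq(d, "center")
#' balanced_accuracy(d$center, predict(m, d))
gmlvq <- function(data, label_col = "center", epochs = 30,
                  step_prototypes = 1, step_matrix = 2,
                  waypoint_window = 10, projector = NULL) {
  validate_feature_set(data, label_col)
  X <- feature_matrix(data)
  y <- as.character(data[[label_col]])
  fit <- gmlvq_fit(X, y, epochs = epochs, step_prototypes = step_prototypes,
                   step_matrix = step_matrix, waypoint_window = waypoint_window,
                   projector = projector)
  fit$label_col <- label_col
  fit
}

#' Matrix-interface GMLVQ trainer
#'
#' Lower-level entry point used by [gmlvq()], cross-validation and the IRMA
#' loop; takes a plain feature matrix and label vector.
#'
#' @inheritParams gmlvq
#' @param X Numeric samples x features matrix.
#' @param y Class labels (character or factor), one per row of `X`.
#' @return See [gmlvq()].
#' @export
gmlvq_fit <- function(X, y, epochs = 30, step_prototypes = 1, step_matrix = 2,
                      waypoint_window = 10, projector = NULL) {
  stopifnot(epochs >= 1, step_prototypes > 0, step_matrix > 0)
  X <- as.matrix(X); storage.mode(X) <- "double"
  dimnames(X) <- NULL
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("need at least two classes", call. = FALSE)
  y_idx <- match(y, classes)
  N <- ncol(X)
  psi <- NULL
  if (!is.null(projector)) {
    psi <- if (inherits(projector, "irma_projector")) projector$matrix else projector
    stopifnot(nrow(psi) == N, ncol(psi) == N)
  }

  W <- do.call(rbind, lapply(classes, function(cl) {
    colMeans(X[y == cl, , drop = FALSE])
  }))
  omega <- .restrict_omega(diag(N), psi)

  cost_of <- function(W, omega) {
    sum(.cost_terms(.distance_matrix(X, W, omega), y_idx)$mu)
  }

  cost0 <- cost_of(W, omega)
  best <- list(W = W, omega = omega)
  best_cost <- cost0
  prev_cost <- cost0
  aw <- step_prototypes
  am <- step_matrix
  window <- list(list(W = W, omega = omega))
  trace <- numeric(epochs)

  for (ep in seq_len(epochs)) {
    g <- .gmlvq_gradient(X, y_idx, W, omega)
    rawW <- W - aw * g$gW
    rawO <- .restrict_omega(omega - am * g$gO, psi)
    c_raw <- cost_of(rawW, rawO)

    # waypoint average over the recent window plus the raw step
    states <- c(window, list(list(W = rawW, omega = rawO)))
    avgW <- Reduce(`+`, lapply(states, `[[`, "W")) / length(states)
    avgO <- .restrict_omega(
      Reduce(`+`, lapply(states, `[[`, "omega")) / length(states), psi)
    c_avg <- cost_of(avgW, avgO)

    if (c_avg < c_raw) {
      W <- avgW; omega <- avgO; cost <- c_avg
    } else {
      W <- rawW; omega <- rawO; cost <- c_raw
    }
    if (cost > prev_cost) {
      aw <- max(aw / 2, 1e-6)
      am <- max(am / 2, 1e-6)
    }
    prev_cost <- cost
    trace[ep] <- cost
    window <- c(window, list(list(W = W, omega = omega)))
    if (length(window) > waypoint_window) {
      window <- window[(length(window) - waypoint_window + 1):length(window)]
    }
    if (cost < best_cost) {
      best <- list(W = W, omega = omega)
      best_cost <- cost
    }
  }

  lambda <- crossprod(best$omega)
  lambda <- (lambda + t(lambda)) / 2
  dimnames(best$W) <- list(classes, NULL)
  structure(list(
    prototypes = best$W,
    omega = best$omega,
    lambda = lambda,
    classes = classes,
    trace = trace,
    cost_initial = cost0,
    cost_final = best_cost,
    config = list(epochs = epochs, step_prototypes = step_prototypes,
                  step_matrix = step_matrix, waypoint_window = waypoint_window,
                  restricted = !is.null(psi))
  ), class = "gmlvq")
}

#' Predict classes with a GMLVQ model
#'
#' Assigns each sample the class of the prototype with the smallest relevance
#' distance; exact ties go to the smallest class index.
#'
#' @param object A `"gmlvq"` model.
#' @param newdata Feature table or numeric matrix.
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.gmlvq <- function(object, newdata, ...) {
  X <- if (is.data.frame(newdata)) feature_matrix(newdata) else as.matrix(newdata)
  if (ncol(X) != ncol(object$prototypes)) {
    stop("newdata has ", ncol(X), " features; model expects ",
         ncol(object$prototypes), call. = FALSE)
  }
  D <- .distance_matrix(X, object$prototypes, object$omega)
  object$classes[max.col(-D, ties.method = "first")]
}

#' Balanced accuracy (mean per-class recall)
#'
#' @param true True class labels; every class must occur at least once.
#' @param pred Predicted labels of the same length.
#' @return Mean over the true classes of the within-class recall, in `[0, 1]`.
#'   Uniform random guessing has expectation `1/C` for `C` classes.
#' @export
#' @examples
#' balanced_accuracy(c("a", "a", "b", "b"), c("a", "b", "b", "b")) # 0.75
balanced_accuracy <- function(true, pred) {
  true <- as.character(true); pred <- as.character(pred)
  if (length(true) != length(pred)) stop("length mismatch", call. = FALSE)
  if (length(true) == 0L) stop("empty label vectors", call. = FALSE)
  classes <- sort(unique(true))
  mean(vapply(classes, function(cl) mean(pred[true == cl] == cl), numeric(1)))
}

#' Leading eigenvectors of a relevance matrix
#'
#' @param lambda Symmetric PSD matrix.
#' @param m Number of leading eigenvectors to return (`m <= N`).
#' @return List with `vectors` (N x m, orthonormal columns, eigenvalue
#'   descending; each column's largest-magnitude entry is positive) and
#'   `values`.
#' @export
leading_eigenvectors <- function(lambda, m = 1) {
  lambda <- as.matrix(lambda)
  if (nrow(lambda) != ncol(lambda) ||
      max(abs(lambda - t(lambda))) > 1e-8) {
    stop("lambda must be a symmetric matrix", call. = FALSE)
  }
  stopifnot(m >= 1, m <= nrow(lambda))
  e <- eigen((lambda + t(lambda)) / 2, symmetric = TRUE)
  V <- e$vectors[, seq_len(m), drop = FALSE]
  for (j in seq_len(m)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  list(vectors = V, values = e$values[seq_len(m)])
}

#' Project data onto the two leading relevance eigenvectors
#'
#' Gives the 2-D coordinates (inner products with the two leading
#' eigenvectors of Lambda) that visualize the decision space of a trained
#' model; prototypes can be projected with the same call.
#'
#' @param model A `"gmlvq"` model.
#' @param X Feature table or numeric matrix.
#' @return M x 2 numeric matrix of coordinates.
#' @export
discriminative_projection <- function(model, X) {
  if (is.data.frame(X)) X <- feature_matrix(X)
  X <- as.matrix(X)
  V <- leading_eigenvectors(model$lambda, 2)$vectors
  unname(X %*% V)
}

#' @export
print.gmlvq <- function(x, ...) {
  cat("GMLVQ model:", length(x$classes), "classes x", ncol(x$prototypes),
      "features\n")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  ev <- leading_eigenvectors(x$lambda, min(3L, ncol(x$lambda)))$values
  cat("  leading relevance eigenvalues:",
      paste(signif(ev, 3), collapse = ", "), "\n")
  cat("  cost:", signif(x$cost_initial, 4), "->", signif(x$cost_final, 4),
      "over", x$config$epochs, "epochs",
      if (isTRUE(x$config$restricted)) "(projector-restricted)" else "", "\n")
  invisible(x)
}

#' Tidy a GMLVQ model
#'
#' One row per (class, feature) prototype coordinate, with the diagonal
#' relevance of the feature attached.
#'
#' @param x A `"gmlvq"` model.
#' @param ... Unused.
#' @return A tibble with columns `class`, `feature`, `prototype`,
#'   `relevance`.
#' @export
tidy.gmlvq <- function(x, ...) {
  N <- ncol(x$prototypes)
  feat <- paste0("f", seq_len(N) - 1L)
  tibble::tibble(
    class = rep(x$classes, each = N),
    feature = rep(feat, times = length(x$classes)),
    prototype = as.numeric(t(x$prototypes)),
    relevance = rep(diag(x$lambda), times = length(x$classes))
  )
}

#' Glance at a GMLVQ model
#'
#' @param x A `"gmlvq"` model.
#' @param ... Unused.
#' @return One-row tibble with class/feature counts, initial and final cost,
#'   and the leading relevance eigenvalue.
#' @export
glance.gmlvq <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$classes),
    n_features = ncol(x$prototypes),
    epochs = x$config$epochs,
    cost_initial = x$cost_initial,
    cost_final = x$cost_final,
    leading_eigenvalue = leading_eigenvectors(x$lambda, 1)$values[1],
    restricted = isTRUE(x$config$restricted)
  )
}

#' Plot the discriminative projection of a GMLVQ model
#'
#' Scatters data (colored by class) and prototypes on the two leading
#' relevance eigenvectors.
#'
#' @param object A `"gmlvq"` model.
#' @param data Feature table to project; must contain the model's label
#'   column.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gmlvq <- function(object, data, ...) {
  P <- discriminative_projection(object, data)
  df <- tibble::tibble(x = P[, 1], y = P[, 2],
                       class = as.character(data[[object$label_col %||% "center"]]))
  Wp <- discriminative_projection(object, object$prototypes)
  dw <- tibble::tibble(x = Wp[, 1], y = Wp[, 2], class = object$classes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_point(data = dw, shape = 21, size = 4, stroke = 1.2,
                        fill = "white") +
    ggplot2::labs(x = "leading relevance eigenvector",
                  y = "second relevance eigenvector",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
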