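# Kernel extreme learning machine and reference baselines.
#
# The kernel ELM has the closed form beta = (Omega + I/C)^{-1} y with
# Omega_ij = K(x_i, x_j), here an RBF kernel K(a,b) = exp(-gamma*||a-b||^2).
# A test point scores f(x) = k(x)' beta with k(x)_i = K(x, x_i); the sign
# is the class, the value feeds the ROC. For C > 0 the system is symmetric
# positive definite, so a Cholesky solve always succeeds.
#
# No SVM or random-forest package ships with the target environment, so the
# two comparison baselines are implemented here: an L2-regularized
# squared-hinge linear SVM (BFGS) and a compact Gini CART bagging forest.
# All three share the fit/decision interface of the CV harness.

rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

#' Train a kernel extreme learning machine
#'
#' Solves `(Omega + I/C) beta = y` for the stored training set, with an
#' RBF kernel of width `gamma` (default `1/d` on standardized features) and
#' regularization coefficient `reg_C` (default 1).
#'
#' @param features Numeric matrix (N x d) of training features.
#' @param labels Vector in \{-1, +1\} (or \{0, 1\}, recoded); both classes
#'   must be present.
#' @param gamma RBF width; default `1/ncol(features)`.
#' @param reg_C Regularization coefficient C (> 0).
#' @return Object of class `elm_model`.
#' @export
train_elm <- function(features, labels, gamma = NULL, reg_C = 1) {
  X <- as.matrix(features)
  y <- recode_pm1(labels)
  if (nrow(X) < 2 || length(unique(y)) < 2)
    stop("ELM training needs >= 2 samples with both classes present")
  if (length(y) != nrow(X)) stop("one label per row is required")
  if (reg_C <= 0) stop("reg_C must be > 0")
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  if (gamma <= 0) stop("gamma must be > 0")
  Omega <- rbf_kernel(X, X, gamma)
  Kmat <- Omega + diag(nrow(X)) / reg_C
  R <- chol(Kmat)                      # SPD by construction for reg_C > 0
  beta <- backsolve(R, forwardsolve(t(R), y))
  structure(list(train_features = X, train_labels = y, gamma = gamma,
                 reg_C = reg_C, beta = beta),
            class = "elm_model")
}

recode_pm1 <- function(labels) {
  y <- as.numeric(labels)
  if (all(y %in% c(0, 1))) y <- 2 * y - 1
  if (!all(y %in% c(-1, 1))) stop("labels must be binary (+1/-1 or 1/0)")
  y
}

#' ELM decision scores
#'
#' Continuous decision values `f(x) = k(x)' beta`; also the ROC input.
#'
#' @param model An [train_elm()] model.
#' @param x Matrix of test rows (or a single feature vector).
#' @return Numeric vector of scores.
#' @export
elm_decision <- function(model, x) {
  stopifnot(inherits(model, "elm_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != ncol(model$train_features))
    stop("feature dimension does not match the trained ELM")
  drop(rbf_kernel(x, model$train_features, model$gamma) %*% model$beta)
}

#' ELM class predictions
#'
#' Thresholds [elm_decision()] at 0 (ties to +1).
#'
#' @inheritParams elm_decision
#' @return Vector in \{-1, +1\}.
#' @export
elm_predict <- function(model, x) {
  ifelse(elm_decision(model, x) >= 0, 1, -1)
}

# ---- baseline: linear SVM (squared hinge, L2), deterministic BFGS fit ----

#' Train a linear SVM baseline
#'
#' L2-regularized squared-hinge linear SVM,
#' `min 0.5*||w||^2 + cost * sum_i max(0, 1 - y_i*(x_i'w + b))^2`,
#' fit by BFGS with analytic gradients (deterministic).
#'
#' @param features Numeric matrix (N x d).
#' @param labels Binary labels (+1/-1 or 1/0).
#' @param cost Misclassification cost (default 1).
#' @return Object of class `linear_svm_model`.
#' @export
train_linear_svm <- function(features, labels, cost = 1) {
  X <- as.matrix(features)
  y <- recode_pm1(labels)
  if (length(unique(y)) < 2) stop("SVM training needs both classes")
  d <- ncol(X)
  obj <- function(th) {
    w <- th[1:d]; b <- th[d + 1]
    m <- 1 - y * (drop(X %*% w) + b)
    0.5 * sum(w^2) + cost * sum(pmax(m, 0)^2)
  }
  grd <- function(th) {
    w <- th[1:d]; b <- th[d + 1]
    m <- 1 - y * (drop(X %*% w) + b)
    act <- m > 0
    gw <- w - 2 * cost * drop(crossprod(X[act, , drop = FALSE],
                                        (y * m)[act]))
    gb <- -2 * cost * sum((y * m)[act])
    c(gw, gb)
  }
  fit <- stats::optim(numeric(d + 1), obj, grd, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  structure(list(w = fit$par[1:d], b = fit$par[d + 1]),
            class = "linear_svm_model")
}

#' Linear SVM decision scores
#' @param model A [train_linear_svm()] model.
#' @param x Matrix of test rows.
#' @return Numeric vector of signed margins.
#' @export
svm_decision <- function(model, x) {
  stopifnot(inherits(model, "linear_svm_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  drop(as.matrix(x) %*% model$w) + model$b
}

# ---- baseline: compact random forest (Gini CART, bagging, mtry) ----

rf_grow_tree <- function(X, y, mtry, max_depth, min_node) {
  # y in {-1, +1}; returns a nested list tree; leaf value = mean(y)
  grow <- function(rows, depth) {
    ys <- y[rows]
    if (depth >= max_depth || length(rows) < min_node ||
        length(unique(ys)) == 1)
      return(list(leaf = TRUE, value = mean(ys)))
    feats <- sample.int(ncol(X), mtry)
    best <- NULL
    n <- length(rows)
    base_pos <- sum(ys == 1)
    for (f in feats) {
      xv <- X[rows, f]
      ordv <- order(xv)
      xs <- xv[ordv]; yv <- ys[ordv] == 1
      cum_pos <- cumsum(yv)
      nl <- seq_len(n - 1)
      ok <- xs[nl] < xs[nl + 1]           # valid split points
      if (!any(ok)) next
      pl <- cum_pos[nl] / nl
      pr <- (base_pos - cum_pos[nl]) / (n - nl)
      gini <- nl / n * 2 * pl * (1 - pl) + (n - nl) / n * 2 * pr * (1 - pr)
      gini[!ok] <- Inf
      k <- which.min(gini)
      if (is.null(best) || gini[k] < best$gini)
        best <- list(gini = gini[k], feature = f,
                     threshold = (xs[k] + xs[k + 1]) / 2)
    }
    if (is.null(best)) return(list(leaf = TRUE, value = mean(ys)))
    left <- rows[X[rows, best$feature] <= best$threshold]
    right <- setdiff(rows, left)
    if (length(left) == 0 || length(right) == 0)
      return(list(leaf = TRUE, value = mean(ys)))
    list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
         left = grow(left, depth + 1), right = grow(right, depth + 1))
  }
  grow(seq_len(nrow(X)), 0)
}

rf_tree_predict <- function(tree, x) {
  while (!tree$leaf)
    tree <- if (x[tree$feature] <= tree$threshold) tree$left else tree$right
  tree$value
}

#' Train a random-forest baseline
#'
#' Bagged Gini CART trees with per-split feature subsampling; the decision
#' score is the mean of the trees' leaf values (in \[-1, 1\]).
#'
#' @param features Numeric matrix (N x d).
#' @param labels Binary labels (+1/-1 or 1/0).
#' @param n_trees Number of trees (default 200).
#' @param mtry Features tried per split (default `floor(sqrt(d))`).
#' @param max_depth,min_node Tree growth limits.
#' @param seed Seed for bootstrap and feature subsampling.
#' @return Object of class `random_forest_model`.
#' @export
train_random_forest <- function(features, labels, n_trees = 200, mtry = NULL,
                                max_depth = 8, min_node = 2, seed = 1) {
  X <- as.matrix(features)
  y <- recode_pm1(labels)
  if (length(unique(y)) < 2) stop("random forest training needs both classes")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  set.seed(seed)
  trees <- lapply(seq_len(n_trees), function(t) {
    boot <- sample.int(nrow(X), replace = TRUE)
    rf_grow_tree(X[boot, , drop = FALSE], y[boot], mtry, max_depth, min_node)
  })
  structure(list(trees = trees), class = "random_forest_model")
}

#' Random-forest decision scores
#' @param model A [train_random_forest()] model.
#' @param x Matrix of test rows.
#' @return Mean tree vote per row, in \[-1, 1\].
#' @export
rf_decision <- function(model, x) {
  stopifnot(inherits(model, "random_forest_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  vapply(seq_len(nrow(x)), function(i) {
    mean(vapply(model$trees, rf_tree_predict, numeric(1), x = x[i, ]))
  }, numeric(1))
}

#' Classifier registry for the CV harness
#'
#' Returns a fit/decision pair so the ELM, the linear SVM and the random
#' forest run through the identical cross-validation protocol (same folds,
#' same features).
#'
#' @param name `"elm"`, `"svm"` or `"rf"`.
#' @param ... Passed to the classifier's training function.
#' @return List with `fit(features, labels)` and `decision(model, x)`.
#' @export
classifier_spec <- function(name = c("elm", "svm", "rf"), ...) {
  name <- match.arg(name)
  extra <- list(...)
  switch(name,
    elm = list(name = "elm",
               fit = function(x, y) do.call(train_elm, c(list(x, y), extra)),
               decision = elm_decision),
    svm = list(name = "svm",
               fit = function(x, y) do.call(train_linear_svm, c(list(x, y), extra)),
               decision = svm_decision),
    rf = list(name = "rf",
              fit = function(x, y) do.call(train_random_forest, c(list(x, y), extra)),
              decision = rf_decision))
}
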