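test_that("standardizer: train statistics, reapplication, constant columns", {
  x <- matrix(c(1, 2, 3, 10, 20, 30), 3, 2)
  s <- standardize(x)
  expect_equal(colMeans(s$values), c(0, 0))
  expect_equal(apply(s$values, 2, sd), c(1, 1))

  # test rows use the *train* statistics, not their own
  xtest <- matrix(c(4, 40), 1, 2)
  z <- apply_standardizer(s$scaler, xtest)
  expect_equal(as.vector(z), c((4 - 2) / 1, (40 - 20) / 10))

  xc <- cbind(c(1, 2, 3), c(5, 5, 5))
  expect_warning(sc <- fit_standardizer(xc), "constant")
  expect_equal(suppressWarnings(standardize(xc))$values[, 2], rep(0, 3))

  expect_error(apply_standardizer(s$scaler, matrix(1, 2, 3)), "column count")
})

test_that("PCA: rank-1 data, orthonormal components, full reconstruction", {
  set.seed(2)
  # variance along a single direction
  t_ <- rnorm(50)
  x1 <- cbind(t_, 2 * t_, -t_) + matrix(rnorm(150, sd = 1e-4), 50, 3)
  p1 <- fit_pca(x1, 1)
  expect_gt(p1$explained_variance[1] / p1$total_variance, 0.999)

  x <- matrix(rnorm(40 * 6), 40, 6)
  p <- fit_pca(x, 6)
  expect_equal(crossprod(p$components), diag(6), tolerance = 1e-10)
  # full-rank projection reconstructs the centered data
  proj <- apply_pca(p, x)
  recon <- proj %*% t(p$components)
  xc <- sweep(x, 2, colMeans(x), "-")
  expect_lt(max(abs(recon - xc)), 1e-8)

  expect_error(fit_pca(x, 7), "kept_dim")
})

test_that("LARS first entry matches the max-correlation oracle", {
  set.seed(4)
  n <- 40; p <- 12
  X <- scale(matrix(rnorm(n * p), n, p))
  attributes(X)[c("scaled:center", "scaled:scale")] <- NULL
  y <- rep(c(1, -1), n / 2)
  X[, 3] <- y                      # column 3 equals the labels exactly
  # the exact column saturates the path after one entry, so ask for one
  sel <- lars_lasso_select(X, y, 1)
  expect_equal(sel$selected, 3)
  expect_equal(unname(which.max(abs(cor(X, y)))), 3)  # the oracle agrees

  # with a noisy (non-degenerate) strong column, later entries follow it
  X[, 3] <- y + rnorm(n, sd = 0.5)
  sel4 <- lars_lasso_select(X, y, 4)
  expect_equal(sel4$selected[1], unname(which.max(abs(cor(X, y)))))
  expect_length(unique(sel4$selected), 4)

  expect_length(lars_lasso_select(X, y, 0)$selected, 0)
})

test_that("LARS prefix property holds across n_select", {
  set.seed(7)
  n <- 50; p <- 25
  X <- scale(matrix(rnorm(n * p), n, p))
  attributes(X)[c("scaled:center", "scaled:scale")] <- NULL
  beta <- c(rnorm(5, sd = 2), rep(0, p - 5))
  y <- sign(drop(X %*% beta) + rnorm(n, sd = 0.3))
  s_full <- lars_lasso_select(X, y, 15)
  for (k in c(1, 3, 8, 12)) {
    sk <- lars_lasso_select(X, y, k)
    expect_identical(sk$selected, s_full$selected[seq_len(k)])
  }
  expect_length(unique(s_full$selected), 15)
})

test_that("LARS path coefficients agree with glmnet at the matched penalty", {
  skip_if_not_installed("glmnet")
  set.seed(3)
  n <- 60; p <- 30
  X <- scale(matrix(rnorm(n * p), n, p))
  attributes(X)[c("scaled:center", "scaled:scale")] <- NULL
  y <- drop(X %*% c(3, -2, 1.5, rep(0, p - 3))) + rnorm(n, sd = 0.5)
  yb <- sign(y); yc <- yb - mean(yb)
  for (L in c(5, 10, 20)) {
    path <- mci25d:::lars_lasso_path(X, yc, L)
    lam <- max(abs(crossprod(X, yc - drop(X %*% path$beta))))
    g <- glmnet::glmnet(X, yc, lambda = lam / n, standardize = FALSE,
                        intercept = FALSE, thresh = 1e-14)
    expect_lt(max(abs(as.vector(g$beta) - path$beta)), 1e-6)
  }
})

test_that("LARS errors when the path cannot reach n_select", {
  set.seed(5)
  X <- matrix(rnorm(5 * 10), 5, 10)   # rank 5: at most ~4 entries possible
  y <- c(1, -1, 1, -1, 1)
  expect_error(lars_lasso_select(X, y, 10), "cannot select")
  expect_error(lars_lasso_select(X, y, 11), "cannot select")
  expect_error(lars_lasso_select(X, c(1, 1, 1, 1, 1), 2), "identical")
})

test_that("fusion concatenates CNN-selected then structure-selected columns", {
  a <- matrix(1:6, 2, 3, dimnames = list(c("s1", "s2"), c("c1", "c2", "c3")))
  b <- matrix(7:10, 2, 2, dimnames = list(c("s1", "s2"), c("f1", "f2")))
  fused <- build_fused_feature_vector(a, b)
  expect_identical(colnames(fused), c("c1", "c2", "c3", "f1", "f2"))
  expect_identical(dim(fused), c(2L, 5L))
  # single-route ablations pass through
  expect_identical(build_fused_feature_vector(a, NULL), a)
  expect_identical(build_fused_feature_vector(NULL, b), b)
  # ordering mismatch is an error
  b2 <- b[c(2, 1), ]
  expect_error(build_fused_feature_vector(a, b2), "ordering")
  expect_error(build_fused_feature_vector(a, b[1, , drop = FALSE]), "numbers")
})
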