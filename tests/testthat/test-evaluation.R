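test_that("metrics follow the count definitions", {
  truth <- c(rep(1, 10), rep(-1, 10))
  pred <- c(rep(1, 8), rep(-1, 2),      # 8/10 converters correct
            rep(-1, 6), rep(1, 4))      # 6/10 non-converters correct
  scores <- pred + rnorm(20, sd = 0.1)
  r <- compute_metrics(truth, pred, scores)
  expect_equal(r$accuracy, 0.70)
  expect_equal(r$sensitivity, 0.80)
  expect_equal(r$specificity, 0.60)
})

test_that("perfectly ranked scores give AUC 1", {
  truth <- c(rep(1, 5), rep(-1, 5))
  scores <- c(5:1, 0:-4)
  r <- compute_metrics(truth, ifelse(scores > 0, 1, -1), scores)
  expect_equal(r$auc, 1.0)
})

test_that("AUC equals the pairwise Mann-Whitney statistic to 1e-12", {
  for (s in 1:10) {
    set.seed(s)
    n <- sample(8:40, 1)
    truth <- sample(c(-1, 1), n, replace = TRUE)
    truth[1] <- 1; truth[2] <- -1
    scores <- round(rnorm(n), 1)          # coarse rounding forces ties
    r <- compute_metrics(truth, sign(scores + 1e-9), scores)
    expect_lt(abs(r$auc - pairwise_auc(truth, scores)), 1e-12)
    # ROC runs monotonically from (0,0) to (1,1)
    expect_equal(unlist(r$roc_points[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(r$roc_points[nrow(r$roc_points), ]),
                 c(fpr = 1, tpr = 1))
    expect_true(all(diff(r$roc_points$fpr) >= 0))
    expect_true(all(diff(r$roc_points$tpr) >= 0))
  }
})

test_that("single-class truth reports missing sensitivity/specificity", {
  expect_warning(r <- compute_metrics(rep(1, 4), rep(1, 4), 1:4),
                 "single-class")
  expect_true(is.na(r$specificity))
  expect_equal(r$sensitivity, 1)
})

make_mci_features <- function(n_pos, n_neg, n_patch = 2, d = 16, effect = 2,
                              seed = 1) {
  set.seed(seed)
  n <- n_pos + n_neg
  labels <- c(rep(1, n_pos), rep(-1, n_neg))
  cnn <- matrix(rnorm(n * n_patch * d), n * n_patch, d)
  cnn[, 1] <- cnn[, 1] + effect * rep(labels, each = n_patch)
  struct <- matrix(rnorm(n * d), n, d)
  struct[, 1:3] <- struct[, 1:3] + effect * labels
  list(cnn_feats = cnn, struct_feats = struct, labels = labels,
       ids = sprintf("m%03d", 1:n), n_patch = n_patch)
}

small_params <- function(...) {
  pipeline_params(p_c = 4, p_f = 4, l_c = 4, l_f = 3, ...)
}

test_that("LOOCV produces one fold per subject, each held out once", {
  f <- make_mci_features(6, 6)
  seen <- character(0)
  train_sizes <- integer(0)
  r <- loocv(f$cnn_feats, f$struct_feats, f$labels, f$ids, f$n_patch,
             small_params(),
             fold_hook = function(test_ids, train_ids, model) {
               seen <<- c(seen, test_ids)
               train_sizes <<- c(train_sizes, length(train_ids))
               expect_false(any(test_ids %in% train_ids))
             })
  expect_identical(sort(seen), sort(f$ids))
  expect_true(all(train_sizes == 11))
  expect_s3_class(r, "eval_result")
})

test_that("a 169 + 139 cohort yields exactly 308 LOOCV folds", {
  f <- make_mci_features(169, 139, n_patch = 1, d = 8, seed = 2)
  n_folds <- 0L
  p <- pipeline_params(p_f = 4, l_f = 3, use_cnn = FALSE)
  r <- loocv(NULL, f$struct_feats, f$labels, f$ids, 1, p,
             fold_hook = function(...) n_folds <<- n_folds + 1L)
  expect_equal(n_folds, 308L)
  expect_equal(nrow(r$per_subject), 308L)
})

test_that("no test-subject row reaches any fit: sentinel leakage check", {
  f <- make_mci_features(8, 8, d = 6)
  sentinel <- 3L
  f$struct_feats[sentinel, ] <- 1e6      # poisoned subject
  f$cnn_feats[mci25d:::patch_rows(sentinel, f$n_patch), ] <- 1e6
  centers <- list()
  loocv(f$cnn_feats, f$struct_feats, f$labels, f$ids, f$n_patch,
        small_params(),
        fold_hook = function(test_ids, train_ids, model) {
          centers[[test_ids]] <<- model$struct$pca$scaler$center
        })
  # when the sentinel is held out, its 1e6 rows must not touch the scaler
  expect_lt(max(abs(centers[[f$ids[sentinel]]])), 1e3)
  # in every other fold the sentinel is in training and dominates the mean
  expect_gt(max(abs(centers[[f$ids[1]]])), 1e4)
})

test_that("stratified k-fold partitions subjects with balanced classes", {
  f <- make_mci_features(13, 9, n_patch = 1, d = 8, seed = 3)
  p <- pipeline_params(p_f = 4, l_f = 3, use_cnn = FALSE)
  fold_tests <- list()
  kfold_cv(NULL, f$struct_feats, f$labels, f$ids, 1, p, k = 4, seed = 2,
           fold_hook = function(test_ids, train_ids, model)
             fold_tests[[length(fold_tests) + 1L]] <<- test_ids)
  all_test <- unlist(fold_tests)
  expect_identical(sort(all_test), sort(f$ids))     # exact partition
  # class proportions within one subject of the global ratio
  for (ft in fold_tests) {
    pos <- sum(f$labels[match(ft, f$ids)] == 1)
    expect_lte(abs(pos - 13 / 22 * length(ft)), 1)
  }
  expect_error(kfold_cv(NULL, f$struct_feats, f$labels, f$ids, 1, p, k = 23),
               "exceed")
})

test_that("k = n reduces to the LOOCV fold structure", {
  f <- make_mci_features(5, 5, n_patch = 1, d = 8, seed = 4)
  p <- pipeline_params(p_f = 3, l_f = 2, use_cnn = FALSE)
  sizes <- integer(0)
  kfold_cv(NULL, f$struct_feats, f$labels, f$ids, 1, p, k = 10, seed = 1,
           fold_hook = function(test_ids, ...) sizes <<- c(sizes, length(test_ids)))
  expect_identical(sizes, rep(1L, 10))
})

test_that("degenerate class counts are explicit errors", {
  f <- make_mci_features(1, 10, n_patch = 1, d = 8, seed = 5)
  p <- pipeline_params(p_f = 3, l_f = 2, use_cnn = FALSE)
  expect_error(loocv(NULL, f$struct_feats, f$labels, f$ids, 1, p),
               ">= 2 subjects")
  # a fold whose training part lost a class errors inside the harness
  expect_error(
    mci25d:::run_cv_folds(list(1:2), NULL,
                          f$struct_feats[1:4, ], c(1, 1, -1, -1),
                          f$ids[1:4], 1, p),
    "lost one of the classes")
})

test_that("fused width equals l_c + l_f and prediction is reproducible", {
  f <- make_mci_features(10, 10)
  m <- fit_conversion_model(f$cnn_feats, f$struct_feats, f$labels,
                            f$n_patch, small_params())
  expect_equal(m$fused_width, 4 + 3)
  s1 <- predict_conversion(m, f$cnn_feats, f$struct_feats)
  s2 <- predict_conversion(m, f$cnn_feats, f$struct_feats)
  expect_identical(s1, s2)
  expect_length(s1, 20)
})
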