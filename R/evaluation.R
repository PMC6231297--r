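# Metrics, cross-validation harnesses and the experiment driver.
#
# Positive class = MCI converter throughout. The CNN and the volumetric
# age-correction model are fit once per experiment on AD/NC subjects (they
# never see MCI labels); standardization, PCA (by default), LASSO and the
# classifier are refit inside every cross-validation fold.

#' Classification metrics and ROC
#'
#' Accuracy = correct subjects / all subjects; sensitivity = correctly
#' classified converters / all converters; specificity = correctly
#' classified non-converters / all non-converters. The ROC is traced over
#' the distinct score thresholds (ties grouped, trapezoidal interpolation)
#' and the AUC is the trapezoidal area, which equals the pairwise
#' Mann-Whitney statistic with ties counted 1/2.
#'
#' @param truth True labels (+1 converter / -1, or 1/0 recoded).
#' @param pred Predicted labels, same coding.
#' @param scores Continuous decision values (larger = more converter-like).
#' @param ids Optional subject ids for the per-subject table.
#' @return Object of class `eval_result`: `accuracy`, `sensitivity`,
#'   `specificity`, `auc`, `roc_points` (data.frame `fpr`, `tpr`),
#'   `per_subject`.
#' @export
compute_metrics <- function(truth, pred, scores, ids = NULL) {
  truth <- recode_pm1(truth)
  pred <- recode_pm1(pred)
  n <- length(truth)
  if (length(pred) != n || length(scores) != n)
    stop("truth, pred and scores must have equal length")
  acc <- mean(truth == pred)
  npos <- sum(truth == 1); nneg <- sum(truth == -1)
  sens <- spec <- NA_real_
  if (npos == 0 || nneg == 0) {
    warning("single-class truth vector: sensitivity/specificity undefined")
  }
  if (npos > 0) sens <- sum(truth == 1 & pred == 1) / npos
  if (nneg > 0) spec <- sum(truth == -1 & pred == -1) / nneg
  roc <- roc_points(truth, scores)
  auc <- if (npos > 0 && nneg > 0) trapezoid_auc(roc) else NA_real_
  if (is.null(ids)) ids <- as.character(seq_len(n))
  structure(list(accuracy = acc, sensitivity = sens, specificity = spec,
                 auc = auc, roc_points = roc,
                 per_subject = data.frame(subject_id = ids, truth = truth,
                                          pred = pred, score = scores,
                                          stringsAsFactors = FALSE)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> n=%d  acc=%.3f  sens=%.3f  spec=%.3f  auc=%.3f\n",
              nrow(x$per_subject), x$accuracy, x$sensitivity,
              x$specificity, x$auc))
  invisible(x)
}

# ROC over distinct thresholds, ties grouped; rows from (0,0) to (1,1)
roc_points <- function(truth, scores) {
  npos <- sum(truth == 1); nneg <- sum(truth == -1)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; t <- truth[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(t == 1); fp <- cumsum(t == -1)
  last <- !duplicated(grp, fromLast = TRUE)   # last row of each tie block
  tpr <- c(0, tp[last] / max(npos, 1))
  fpr <- c(0, fp[last] / max(nneg, 1))
  data.frame(fpr = fpr, tpr = tpr)
}

trapezoid_auc <- function(roc) {
  dx <- diff(roc$fpr)
  sum(dx * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

# ---- per-fold feature pipeline -------------------------------------------

#' Pipeline parameters for the conversion classifier
#'
#' @param p_c,p_f PCA dimensions for the deep (per patch) and structural
#'   routes (published values 29 and 150).
#' @param l_c,l_f LASSO selection counts (35 and 40; fused width 75).
#' @param use_cnn,use_struct Route ablation switches.
#' @param gamma,reg_c Kernel ELM hyperparameters (defaults `1/d` and 1).
#' @param classifier `"elm"`, `"svm"` or `"rf"` (identical CV protocol).
#' @param pca_scope `"fold"` refits PCA inside each CV fold (default,
#'   leak-free); `"global"` fits it once on all subjects before CV.
#' @return List of class `pipeline_params`.
#' @export
pipeline_params <- function(p_c = 29, p_f = 150, l_c = 35, l_f = 40,
                            use_cnn = TRUE, use_struct = TRUE,
                            gamma = NULL, reg_c = 1,
                            classifier = "elm",
                            pca_scope = c("fold", "global")) {
  if (!use_cnn && !use_struct) stop("enable at least one feature route")
  structure(list(p_c = as.integer(p_c), p_f = as.integer(p_f),
                 l_c = as.integer(l_c), l_f = as.integer(l_f),
                 use_cnn = use_cnn, use_struct = use_struct,
                 gamma = gamma, reg_c = reg_c, classifier = classifier,
                 pca_scope = match.arg(pca_scope)),
            class = "pipeline_params")
}

# subject-major patch rows -> per-subject concatenation of reduced blocks
concat_patch_blocks <- function(reduced, n_subjects, n_patch) {
  pc <- ncol(reduced)
  A <- t(reduced)
  dim(A) <- c(pc * n_patch, n_subjects)
  t(A)
}

#' Fit the per-fold selection + classification stack
#'
#' Training-fold-only fitting of the whole tail of the pipeline:
#' standardize deep patch rows, PCA to `p_c`, concatenate the patch blocks
#' per subject, standardize, LARS-LASSO to `l_c`; same for the structural
#' route (`p_f`, `l_f`); fuse; train the classifier. Pre-fitted PCA models
#' may be supplied (global-PCA protocol).
#'
#' @param cnn_feats Deep features of the training subjects, subject-major
#'   patch rows (`n_train * n_patch` x 1024), or `NULL`.
#' @param struct_feats Structural features (`n_train` x F), or `NULL`.
#' @param labels Training labels (+1 converter / -1).
#' @param n_patch Patches per subject.
#' @param params A [pipeline_params()].
#' @param pca_cnn,pca_struct Optional pre-fitted `(scaler, pca)` pairs.
#' @return Object of class `conversion_model`.
#' @export
fit_conversion_model <- function(cnn_feats, struct_feats, labels, n_patch,
                                 params = pipeline_params(),
                                 pca_cnn = NULL, pca_struct = NULL) {
  y <- recode_pm1(labels)
  if (length(unique(y)) < 2) stop("training fold lacks one of the classes")
  n <- length(y)
  model <- list(params = params, n_patch = n_patch)

  blocks <- list()
  if (params$use_cnn) {
    if (is.null(cnn_feats)) stop("use_cnn = TRUE but no deep features given")
    if (nrow(cnn_feats) != n * n_patch)
      stop("deep feature rows must be n_subjects * n_patch, subject-major")
    if (is.null(pca_cnn)) {
      sc1 <- fit_standardizer(cnn_feats)
      pc1 <- fit_pca(apply_standardizer(sc1, cnn_feats), params$p_c)
      pca_cnn <- list(scaler = sc1, pca = pc1)
    }
    red <- apply_pca(pca_cnn$pca, apply_standardizer(pca_cnn$scaler, cnn_feats))
    concat <- concat_patch_blocks(red, n, n_patch)
    sc2 <- fit_standardizer(concat)
    z <- apply_standardizer(sc2, concat)
    sel <- lars_lasso_select(z, y, params$l_c)
    model$cnn <- list(pca = pca_cnn, scaler2 = sc2, selection = sel)
    blocks$cnn <- z[, sel$selected, drop = FALSE]
  }
  if (params$use_struct) {
    if (is.null(struct_feats)) stop("use_struct = TRUE but no structural features given")
    if (nrow(struct_feats) != n)
      stop("structural feature rows must match the training subjects")
    if (is.null(pca_struct)) {
      sc3 <- fit_standardizer(struct_feats)
      pc3 <- fit_pca(apply_standardizer(sc3, struct_feats), params$p_f)
      pca_struct <- list(scaler = sc3, pca = pc3)
    }
    red <- apply_pca(pca_struct$pca, apply_standardizer(pca_struct$scaler, struct_feats))
    sc4 <- fit_standardizer(red)
    z <- apply_standardizer(sc4, red)
    sel <- lars_lasso_select(z, y, params$l_f)
    model$struct <- list(pca = pca_struct, scaler4 = sc4, selection = sel)
    blocks$struct <- z[, sel$selected, drop = FALSE]
  }
  fused <- build_fused_feature_vector(blocks$cnn, blocks$struct)
  model$fused_width <- ncol(fused)
  spec <- if (identical(params$classifier, "elm"))
    classifier_spec("elm", gamma = params$gamma, reg_C = params$reg_c)
  else classifier_spec(params$classifier)
  model$classifier_name <- spec$name
  model$classifier <- spec$fit(fused, y)
  model$decision_fun <- spec$decision
  structure(model, class = "conversion_model")
}

#' Decision scores of a fitted conversion model
#'
#' @param model A [fit_conversion_model()] object.
#' @param cnn_feats Test subjects' deep features (`n_test * n_patch` x
#'   1024, subject-major), or `NULL`.
#' @param struct_feats Test subjects' structural features, or `NULL`.
#' @return Numeric score per test subject (positive = converter).
#' @export
predict_conversion <- function(model, cnn_feats = NULL, struct_feats = NULL) {
  stopifnot(inherits(model, "conversion_model"))
  params <- model$params
  blocks <- list()
  if (params$use_cnn) {
    n_test <- nrow(cnn_feats) / model$n_patch
    if (n_test != round(n_test)) stop("deep feature rows not a multiple of n_patch")
    red <- apply_pca(model$cnn$pca$pca,
                     apply_standardizer(model$cnn$pca$scaler, cnn_feats))
    concat <- concat_patch_blocks(red, n_test, model$n_patch)
    z <- apply_standardizer(model$cnn$scaler2, concat)
    blocks$cnn <- z[, model$cnn$selection$selected, drop = FALSE]
  }
  if (params$use_struct) {
    red <- apply_pca(model$struct$pca$pca,
                     apply_standardizer(model$struct$pca$scaler, struct_feats))
    z <- apply_standardizer(model$struct$scaler4, red)
    blocks$struct <- z[, model$struct$selection$selected, drop = FALSE]
  }
  fused <- build_fused_feature_vector(blocks$cnn, blocks$struct)
  model$decision_fun(model$classifier, fused)
}

# rows of the subject-major patch-row matrix belonging to subjects `which`
patch_rows <- function(which, n_patch) {
  rep((which - 1L) * n_patch, each = n_patch) + seq_len(n_patch)
}

run_cv_folds <- function(folds, cnn_feats, struct_feats, labels, ids,
                         n_patch, params, fold_hook = NULL) {
  y <- recode_pm1(labels)
  n <- length(y)
  pca_cnn <- pca_struct <- NULL
  if (params$pca_scope == "global") {
    if (params$use_cnn) {
      sc <- fit_standardizer(cnn_feats)
      pca_cnn <- list(scaler = sc,
                      pca = fit_pca(apply_standardizer(sc, cnn_feats), params$p_c))
    }
    if (params$use_struct) {
      sc <- fit_standardizer(struct_feats)
      pca_struct <- list(scaler = sc,
                         pca = fit_pca(apply_standardizer(sc, struct_feats), params$p_f))
    }
  }
  scores <- numeric(n); preds <- numeric(n)
  for (f in folds) {
    tr <- setdiff(seq_len(n), f)
    if (length(unique(y[tr])) < 2)
      stop("a training fold lost one of the classes; rebalance the folds")
    model <- fit_conversion_model(
      if (params$use_cnn) cnn_feats[patch_rows(tr, n_patch), , drop = FALSE] else NULL,
      if (params$use_struct) struct_feats[tr, , drop = FALSE] else NULL,
      y[tr], n_patch, params, pca_cnn = pca_cnn, pca_struct = pca_struct)
    s <- predict_conversion(
      model,
      if (params$use_cnn) cnn_feats[patch_rows(f, n_patch), , drop = FALSE] else NULL,
      if (params$use_struct) struct_feats[f, , drop = FALSE] else NULL)
    scores[f] <- s
    preds[f] <- ifelse(s >= 0, 1, -1)
    if (!is.null(fold_hook)) fold_hook(ids[f], ids[tr], model)
  }
  compute_metrics(y, preds, scores, ids)
}

#' Leave-one-out cross-validation of the conversion pipeline
#'
#' One fold per subject: the selection/classification stack is refit on
#' the remaining subjects, the held-out subject is scored, and metrics are
#' pooled over all folds (308 folds for the published 169 + 139 cohort).
#' The CNN and volumetric age correction are fit upstream, outside this
#' loop, because they are trained on AD/NC only.
#'
#' @param cnn_feats Deep features, subject-major patch rows, or `NULL`.
#' @param struct_feats Structural features (subjects x F), or `NULL`.
#' @param labels Labels (+1 converter / -1), one per subject.
#' @param ids Subject ids.
#' @param n_patch Patches per subject.
#' @param params A [pipeline_params()].
#' @param fold_hook Optional `function(test_ids, train_ids, model)` called
#'   after each fold (used by the leakage tests).
#' @return An `eval_result`.
#' @export
loocv <- function(cnn_feats, struct_feats, labels, ids, n_patch,
                  params = pipeline_params(), fold_hook = NULL) {
  n <- length(labels)
  y <- recode_pm1(labels)
  if (sum(y == 1) < 2 || sum(y == -1) < 2)
    stop("leave-one-out needs >= 2 subjects per class")
  folds <- as.list(seq_len(n))
  run_cv_folds(folds, cnn_feats, struct_feats, labels, ids, n_patch,
               params, fold_hook)
}

#' Stratified k-fold cross-validation
#'
#' Subjects of each class are shuffled (seed-controlled) and dealt
#' round-robin into `k` folds, so fold class proportions are within one
#' subject of the global ratio; `k = n` reduces to the leave-one-out fold
#' structure.
#'
#' @inheritParams loocv
#' @param k Number of folds.
#' @param seed Shuffle seed.
#' @return An `eval_result`.
#' @export
kfold_cv <- function(cnn_feats, struct_feats, labels, ids, n_patch,
                     params = pipeline_params(), k = 10, seed = 1,
                     fold_hook = NULL) {
  n <- length(labels)
  if (k > n) stop("k must not exceed the number of subjects")
  y <- recode_pm1(labels)
  set.seed(seed)
  folds <- rep(list(integer(0)), k)
  slot <- 0L   # continues across classes so fold sizes stay balanced
  for (cls in c(1, -1)) {
    idx <- sample(which(y == cls))
    for (i in seq_along(idx)) {
      f <- (slot %% k) + 1L
      folds[[f]] <- c(folds[[f]], idx[i])
      slot <- slot + 1L
    }
  }
  folds <- folds[vapply(folds, length, integer(1)) > 0]
  run_cv_folds(folds, cnn_feats, struct_feats, labels, ids, n_patch,
               params, fold_hook)
}
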