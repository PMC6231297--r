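# End-to-end experiment driver.
#
# Chain: synthetic cohort (or user-supplied data) -> optional histogram
# matching -> age correction (volumes on NC; features on NC) -> fixed patch
# locations -> CNN trained on AD/NC patches -> deep features for MCI ->
# per-fold PCA/LASSO/classifier under LOOCV or stratified k-fold.

#' Experiment configuration
#'
#' Bundles the stage configurations and switches of one experiment run.
#'
#' @param synth A [synthetic_config()] describing the cohort.
#' @param cnn A [cnn_config()].
#' @param params A [pipeline_params()].
#' @param n_locations Patch locations per image (default 151).
#' @param min_distance Minimum pairwise center distance (default 2 voxels).
#' @param histogram_match Match every volume's histogram to the mean NC
#'   volume before age correction.
#' @param age_correction Apply the voxel/feature aging model (fit on NC).
#' @param cv `"loocv"` or `"kfold"`.
#' @param k Folds for `cv = "kfold"`.
#' @param seed Master seed for location sampling and fold shuffling.
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(synth = synthetic_config(),
                              cnn = cnn_config(),
                              params = pipeline_params(),
                              n_locations = 151, min_distance = 2,
                              histogram_match = FALSE, age_correction = TRUE,
                              cv = c("loocv", "kfold"), k = 10, seed = 1) {
  structure(list(synth = synth, cnn = cnn, params = params,
                 n_locations = as.integer(n_locations),
                 min_distance = min_distance,
                 histogram_match = isTRUE(histogram_match),
                 age_correction = isTRUE(age_correction),
                 cv = match.arg(cv), k = as.integer(k),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

mean_volume <- function(volumes) {
  acc <- volumes[[1]]$data
  for (v in volumes[-1]) acc <- acc + v$data
  brain_volume(acc / length(volumes), "template")
}

#' Run the full pipeline on a (synthetic) cohort
#'
#' Executes preprocessing, patch extraction, CNN training on AD/NC, deep
#' feature extraction for MCI, and cross-validated selection +
#' classification. The CNN never sees MCI labels; the volumetric aging
#' model is fit on NC only. Deterministic given the configuration.
#'
#' @param config An [experiment_config()].
#' @param cohort Optional pre-built cohort (as from [generate_cohort()],
#'   plus `$struct` feature matrix); generated from `config$synth` when
#'   omitted.
#' @param verbose Print stage progress.
#' @return List of class `experiment_result`: `eval` (an `eval_result`),
#'   `features` (MCI deep/structural features for route re-evaluation),
#'   `locations`, `cnn` (trained model), `config`.
#' @export
run_experiment <- function(config, cohort = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (verbose) message(...)

  if (is.null(cohort)) {
    say("generating synthetic cohort")
    cohort <- generate_cohort(config$synth)
    cohort$struct <- generate_structural_features(config$synth, cohort$records)
  }
  records <- cohort$records
  volumes <- cohort$volumes
  mask <- cohort$mask
  struct <- cohort$struct

  nc_idx <- which(records$group == "NC")
  ad_idx <- which(records$group == "AD")
  mci_idx <- which(records$group %in% c("MCIc", "MCInc"))
  if (length(mci_idx) < 4) stop("need MCI converters and non-converters to evaluate")

  if (config$histogram_match) {
    say("histogram matching to the mean NC volume")
    template <- mean_volume(volumes[nc_idx])
    volumes <- lapply(volumes, match_histogram, template = template)
  }
  if (config$age_correction) {
    say("fitting and applying age correction (NC-trained)")
    acm <- fit_age_correction(volumes[nc_idx], records$age[nc_idx])
    volumes <- lapply(seq_along(volumes), function(i)
      apply_age_correction(acm, volumes[[i]], records$age[i]))
    if (config$params$use_struct)
      struct <- fit_and_apply_feature_age_correction(struct, records)
  }

  say("sampling ", config$n_locations, " patch locations")
  locs <- sample_locations(mask, config$n_locations, config$min_distance,
                           seed = config$seed)

  say("extracting patches")
  patch_sets <- lapply(volumes, extract_patch_set, locs = locs)

  train_idx <- c(ad_idx, nc_idx)
  train_patches <- unlist(patch_sets[train_idx], recursive = FALSE)
  train_labels <- rep(as.integer(records$group[train_idx] == "AD"),
                      each = config$n_locations)
  say("training CNN on ", length(train_patches), " AD/NC patches")
  cnn <- build_cnn(config$cnn)
  cnn <- train_cnn(cnn, train_patches, train_labels, verbose = verbose)

  say("extracting deep features for ", length(mci_idx), " MCI subjects")
  mci_patches <- unlist(patch_sets[mci_idx], recursive = FALSE)
  cnn_feats <- extract_cnn_features(cnn, mci_patches)
  mci_labels <- ifelse(records$group[mci_idx] == "MCIc", 1, -1)
  mci_ids <- records$subject_id[mci_idx]
  struct_mci <- struct[mci_idx, , drop = FALSE]
  features <- list(cnn_feats = cnn_feats, struct_feats = struct_mci,
                   labels = mci_labels, ids = mci_ids,
                   n_patch = config$n_locations)

  say("running ", config$cv, " cross-validation over ", length(mci_idx),
      " MCI subjects")
  eval_res <- evaluate_routes(features, config$params,
                              cv = config$cv, k = config$k,
                              seed = config$seed)

  structure(list(eval = eval_res, features = features, locations = locs,
                 cnn = cnn, config = config),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>\n")
  print(x$eval)
  invisible(x)
}

#' Re-evaluate stored features under different pipeline parameters
#'
#' Reuses the extracted MCI features of a finished [run_experiment()] to
#' run the CV stage again, e.g. for the single-route ablations or for a
#' different classifier, without retraining the CNN.
#'
#' @param features The `$features` element of an `experiment_result` (or a
#'   compatible list).
#' @param params A [pipeline_params()].
#' @param cv,k,seed Cross-validation protocol.
#' @return An `eval_result`.
#' @export
evaluate_routes <- function(features, params, cv = "loocv", k = 10, seed = 1) {
  if (cv == "loocv") {
    loocv(features$cnn_feats, features$struct_feats, features$labels,
          features$ids, features$n_patch, params)
  } else {
    kfold_cv(features$cnn_feats, features$struct_feats, features$labels,
             features$ids, features$n_patch, params, k = k, seed = seed)
  }
}

#' Run the feature-route ablation suite
#'
#' Four arms on one cohort: fused (both routes), deep-features only,
#' structural only, and fused without age correction. The CNN is trained
#' twice (with and without age-corrected volumes); the single-route arms
#' reuse the age-corrected features.
#'
#' @param config An [experiment_config()] with both routes enabled.
#' @param verbose Print stage progress.
#' @return Named list of `eval_result`s: `fused`, `cnn_only`,
#'   `struct_only`, `no_age_correction`, plus `experiment` (the fused run).
#' @export
run_ablation_suite <- function(config, verbose = FALSE) {
  stopifnot(config$params$use_cnn, config$params$use_struct)
  exp_fused <- run_experiment(config, verbose = verbose)
  p <- config$params
  p_cnn <- p; p_cnn$use_struct <- FALSE
  p_struct <- p; p_struct$use_cnn <- FALSE
  res <- list(
    fused = exp_fused$eval,
    cnn_only = evaluate_routes(exp_fused$features, p_cnn,
                               cv = config$cv, k = config$k, seed = config$seed),
    struct_only = evaluate_routes(exp_fused$features, p_struct,
                                  cv = config$cv, k = config$k, seed = config$seed))
  cfg_noac <- config
  cfg_noac$age_correction <- FALSE
  res$no_age_correction <- run_experiment(cfg_noac, verbose = verbose)$eval
  res$experiment <- exp_fused
  res
}

#' Compare CNN training cohorts by patch vote
#'
#' Reproduces the transfer protocol in structure: one CNN is trained on
#' AD/NC patches, another on the patches of a held-out-free half of the
#' MCI subjects; both classify the same MCI test half by majority patch
#' vote. With stronger AD/NC effects the AD/NC-trained arm should match or
#' beat the MCI-trained arm.
#'
#' @param config An [experiment_config()].
#' @param verbose Print stage progress.
#' @return List with `acc_adnc_trained`, `acc_mci_trained`, `gap`
#'   (AD/NC-trained minus MCI-trained) and the test ids.
#' @export
compare_training_cohorts <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  cohort <- generate_cohort(config$synth)
  records <- cohort$records
  volumes <- cohort$volumes
  if (config$age_correction) {
    nc_idx <- which(records$group == "NC")
    acm <- fit_age_correction(volumes[nc_idx], records$age[nc_idx])
    volumes <- lapply(seq_along(volumes), function(i)
      apply_age_correction(acm, volumes[[i]], records$age[i]))
  }
  locs <- sample_locations(cohort$mask, config$n_locations,
                           config$min_distance, seed = config$seed)
  patch_sets <- lapply(volumes, extract_patch_set, locs = locs)

  ad_nc <- which(records$group %in% c("AD", "NC"))
  mci <- which(records$group %in% c("MCIc", "MCInc"))
  set.seed(config$seed)
  mcic <- sample(intersect(mci, which(records$group == "MCIc")))
  mcinc <- sample(intersect(mci, which(records$group == "MCInc")))
  test_idx <- c(mcic[seq_len(floor(length(mcic) / 2))],
                mcinc[seq_len(floor(length(mcinc) / 2))])
  train_mci <- setdiff(mci, test_idx)

  fit_arm <- function(subjects, positive) {
    patches <- unlist(patch_sets[subjects], recursive = FALSE)
    labels <- rep(as.integer(records$group[subjects] %in% positive),
                  each = config$n_locations)
    train_cnn(build_cnn(config$cnn), patches, labels)
  }
  vote_acc <- function(model) {
    pred <- vapply(test_idx, function(i)
      classify_subject_by_patch_vote(model, patch_sets[[i]]), integer(1))
    mean(pred == as.integer(records$group[test_idx] == "MCIc"))
  }
  if (verbose) message("training AD/NC arm")
  acc_adnc <- vote_acc(fit_arm(ad_nc, "AD"))
  if (verbose) message("training MCI arm")
  acc_mci <- vote_acc(fit_arm(train_mci, "MCIc"))
  list(acc_adnc_trained = acc_adnc, acc_mci_trained = acc_mci,
       gap = acc_adnc - acc_mci,
       test_ids = records$subject_id[test_idx])
}

#' Compare classifiers under the identical CV protocol
#'
#' Runs the same folds and feature pipeline with the kernel ELM, the
#' linear SVM and the random forest.
#'
#' @param features The `$features` element of an `experiment_result`.
#' @param params A [pipeline_params()]; its `classifier` field is swapped.
#' @param classifiers Names from [classifier_spec()].
#' @param cv,k,seed Cross-validation protocol.
#' @return `data.frame` with one row per classifier: accuracy,
#'   sensitivity, specificity, AUC.
#' @export
compare_classifiers <- function(features, params = pipeline_params(),
                                classifiers = c("elm", "svm", "rf"),
                                cv = "loocv", k = 10, seed = 1) {
  rows <- lapply(classifiers, function(cl) {
    p <- params; p$classifier <- cl
    r <- evaluate_routes(features, p, cv = cv, k = k, seed = seed)
    data.frame(classifier = cl, accuracy = r$accuracy,
               sensitivity = r$sensitivity, specificity = r$specificity,
               auc = r$auc)
  })
  do.call(rbind, rows)
}

#' Read an experiment configuration from a YAML file
#'
#' Top-level keys `synth`, `cnn`, `params` hold the arguments of
#' [synthetic_config()], [cnn_config()] and [pipeline_params()]; remaining
#' keys are passed to [experiment_config()].
#'
#' @param path YAML file path.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  synth <- do.call(synthetic_config, as.list(cfg$synth %||% list()))
  cnn <- do.call(cnn_config, as.list(cfg$cnn %||% list()))
  params <- do.call(pipeline_params, as.list(cfg$params %||% list()))
  rest <- cfg[setdiff(names(cfg), c("synth", "cnn", "params"))]
  do.call(experiment_config,
          c(list(synth = synth, cnn = cnn, params = params), rest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
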