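# Intensity normalization and age correction.
#
# Age-correction model: at each voxel m a linear trend y_m = w_m * age + b_m
# is fit across healthy subjects; subject n at age a_n is then shifted to a
# common reference age C by y'_mn = w_m * (C - a_n) + y_mn. The same model
# applies per column to tabular structural features.

#' Match a volume's histogram to a template
#'
#' Monotone quantile mapping: the subject's empirical quantiles are mapped
#' onto the template's at `n_quantiles` anchor points with linear
#' interpolation (clamped outside the anchors). Voxel ordering is preserved.
#'
#' @param subject,template [brain_volume()]s on the same grid.
#' @param n_quantiles Number of quantile anchors (default 256).
#' @return A [brain_volume()] with the subject's id and matched intensities.
#' @export
match_histogram <- function(subject, template, n_quantiles = 256) {
  stopifnot(inherits(subject, "brain_volume"), inherits(template, "brain_volume"))
  stop_if_shape_mismatch(subject$data, template$data)
  if (max(subject$data) == min(subject$data))
    stop("subject volume is constant; quantile mapping is degenerate")
  probs <- seq(0, 1, length.out = n_quantiles)
  sq <- stats::quantile(subject$data, probs, names = FALSE, type = 7)
  tq <- stats::quantile(template$data, probs, names = FALSE, type = 7)
  # collapse duplicated subject quantiles so approx() sees strictly
  # increasing x; ties map to the mean template quantile of the tied block
  keep <- !duplicated(sq)
  if (sum(keep) < 2) stop("subject volume is nearly constant; cannot match histogram")
  tq <- vapply(split(tq, cumsum(keep)), mean, numeric(1))
  sq <- sq[keep]
  mapped <- stats::approx(sq, tq, xout = as.vector(subject$data), rule = 2)$y
  brain_volume(array(mapped, dim(subject$data)), subject$subject_id)
}

#' Fit the voxelwise age-correction model
#'
#' Independent ordinary-least-squares fit of intensity on age at every
#' voxel (optionally restricted to a mask), across healthy subjects.
#'
#' @param healthy_volumes List of [brain_volume()]s (same grid), normally
#'   the normal-control subjects.
#' @param ages Numeric vector of ages, one per volume.
#' @param reference_age Reference age C to which subjects are shifted
#'   (default 75 years).
#' @param mask Optional [hippocampus_mask()] or logical/0-1 array limiting
#'   the fit; outside the mask the correction is the identity.
#' @return Object of class `age_correction_model` with per-voxel `slope`
#'   and `intercept`, the `reference_age`, the grid `shape` and the fit
#'   `mask` (or `NULL` for whole-volume).
#' @export
fit_age_correction <- function(healthy_volumes, ages, reference_age = 75,
                               mask = NULL) {
  n <- length(healthy_volumes)
  if (n < 3) stop("need at least 3 healthy subjects to fit the aging model")
  if (length(ages) != n) stop("one age per volume is required")
  if (length(unique(ages)) < 2) stop("all ages identical; aging fit is singular")
  shape <- dim(healthy_volumes[[1]]$data)
  for (v in healthy_volumes) stop_if_shape_mismatch(v$data, healthy_volumes[[1]]$data)
  sel <- NULL
  if (!is.null(mask)) {
    m <- if (inherits(mask, "hippocampus_mask")) mask$data else mask
    if (!identical(dim(m), shape)) stop("mask grid does not match the volumes")
    sel <- which(m != 0)
  }
  nv <- if (is.null(sel)) prod(shape) else length(sel)
  Y <- matrix(0, nv, n)
  for (i in seq_len(n)) {
    d <- healthy_volumes[[i]]$data
    Y[, i] <- if (is.null(sel)) as.vector(d) else d[sel]
  }
  ac <- ages - mean(ages)
  slope <- drop(Y %*% ac) / sum(ac^2)
  intercept <- rowMeans(Y) - slope * mean(ages)
  structure(list(slope = slope, intercept = intercept,
                 reference_age = reference_age, shape = shape,
                 mask_index = sel),
            class = "age_correction_model")
}

#' Apply the age correction to a volume
#'
#' Shifts every covered voxel to the model's reference age C:
#' `y' = slope * (C - age) + y`. A subject at age C is returned unchanged.
#'
#' @param model An [fit_age_correction()] model.
#' @param volume A [brain_volume()] on the model's grid.
#' @param age The subject's age in years.
#' @return Corrected [brain_volume()].
#' @export
apply_age_correction <- function(model, volume, age) {
  stopifnot(inherits(model, "age_correction_model"),
            inherits(volume, "brain_volume"))
  if (!identical(dim(volume$data), model$shape))
    stop("volume grid does not match the age-correction model")
  out <- volume$data
  delta <- model$slope * (model$reference_age - age)
  if (is.null(model$mask_index)) {
    out <- out + array(delta, model$shape)
  } else {
    out[model$mask_index] <- out[model$mask_index] + delta
  }
  brain_volume(out, volume$subject_id)
}

#' Age-correct a structural feature table
#'
#' Fits the per-column linear aging model on the normal-control rows only,
#' then applies `f' = slope * (C - age) + f` to every row.
#'
#' @param features Feature matrix (subjects x features), rows in the order
#'   of `records`.
#' @param records Subject table with `group` and `age` columns.
#' @param reference_age Reference age C (default 75 years).
#' @return Corrected feature matrix of the same shape.
#' @export
fit_and_apply_feature_age_correction <- function(features, records,
                                                 reference_age = 75) {
  features <- feature_matrix(features)
  if (nrow(features) != nrow(records))
    stop("feature rows and subject records differ in length")
  nc <- which(records$group == "NC")
  if (length(nc) < 3) stop("need at least 3 NC subjects to fit the aging model")
  if (length(unique(records$age[nc])) < 2)
    stop("all NC ages identical; aging fit is singular")
  a <- records$age[nc]
  ac <- a - mean(a)
  slope <- drop(crossprod(features[nc, , drop = FALSE], ac)) / sum(ac^2)
  shift <- outer(reference_age - records$age, slope)
  feature_matrix(features + shift, rownames(features), colnames(features))
}
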