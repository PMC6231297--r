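# Synthetic brain-phantom cohorts.
#
# Each phantom is a smooth "brain" background plus two ellipsoidal
# hippocampi on a shared template grid. Disease is emulated as an ordered
# reduction of hippocampal intensity together with a mild shrinkage of the
# bright core (a checkable surrogate for gray-matter loss), normal aging as
# a linear intensity trend inside the hippocampi, and acquisition noise as
# additive i.i.d. Gaussian noise. One mask is shared by the whole cohort,
# mirroring an overlapped per-subject segmentation.

#' Synthetic cohort configuration
#'
#' Defaults state the emulated world once: group sizes follow the clinical
#' cohort the pipeline targets (188 AD / 229 NC / 169 MCIc / 139 MCInc),
#' ages are uniform on 55–91 years, hippocampal atrophy is ordered
#' AD > MCIc > MCInc > NC, and normal aging removes intensity linearly
#' with age. See the methods vignette for the rationale behind each value.
#'
#' @param n_per_group Named integer vector: subjects per group
#'   (`AD`, `NC`, `MCIc`, `MCInc`).
#' @param volume_shape Grid size `(nx, ny, nz)`; each must be >= 64 so
#'   32x32 patch windows fit.
#' @param atrophy_effect Named fractional hippocampal intensity reduction
#'   per group, monotone `AD >= MCIc >= MCInc >= NC`, each in \[0, 1\].
#' @param age_slope Intensity units per year of normal aging inside the
#'   hippocampus (negative: older = darker).
#' @param age_range Years, ages drawn uniformly from this interval.
#' @param noise_sd Standard deviation of additive Gaussian noise
#'   (intensity units; hippocampal contrast is ~0.45 units).
#' @param n_struct_features Number of columns of the structural
#'   (FreeSurfer-like) feature table.
#' @param n_informative How many leading structural columns carry group
#'   signal.
#' @param struct_effect_size Standardized mean difference between MCIc and
#'   MCInc injected into each informative structural column.
#' @param feature_age_slope Age trend (per year, in SD units) added to
#'   informative structural columns.
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   full configuration.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_group = c(AD = 188, NC = 229, MCIc = 169, MCInc = 139),
                             volume_shape = c(64, 64, 64),
                             atrophy_effect = c(AD = 0.30, MCIc = 0.18, MCInc = 0.08, NC = 0),
                             age_slope = -0.004,
                             age_range = c(55, 91),
                             noise_sd = 0.05,
                             n_struct_features = 325,
                             n_informative = 40,
                             struct_effect_size = 0.8,
                             feature_age_slope = 0.02,
                             seed = 1) {
  groups <- c("AD", "NC", "MCIc", "MCInc")
  n_per_group <- n_per_group[groups]
  names(n_per_group) <- groups
  if (any(is.na(n_per_group)) || any(n_per_group < 0))
    stop("n_per_group must give a non-negative count for AD, NC, MCIc and MCInc")
  if (length(volume_shape) != 3 || any(volume_shape < 64))
    stop("volume_shape must be three values, each >= 64, so 32x32 patches fit")
  atrophy_effect <- atrophy_effect[groups]
  if (any(is.na(atrophy_effect)) || any(atrophy_effect < 0) || any(atrophy_effect > 1))
    stop("atrophy_effect must be in [0, 1] for each group")
  if (!(atrophy_effect["AD"] >= atrophy_effect["MCIc"] &&
        atrophy_effect["MCIc"] >= atrophy_effect["MCInc"] &&
        atrophy_effect["MCInc"] >= atrophy_effect["NC"]))
    stop("atrophy_effect must be monotone AD >= MCIc >= MCInc >= NC")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(
    n_per_group = as.integer(n_per_group),
    volume_shape = as.integer(volume_shape),
    atrophy_effect = atrophy_effect,
    age_slope = age_slope,
    age_range = age_range,
    noise_sd = noise_sd,
    n_struct_features = as.integer(n_struct_features),
    n_informative = as.integer(n_informative),
    struct_effect_size = struct_effect_size,
    feature_age_slope = feature_age_slope,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Geometry shared by every phantom in a cohort: a soft-edged brain
# ellipsoid (intensity 0.4) and two hippocampal ellipsoids (bright core
# 0.85 before atrophy). Returns coordinate fields reused per subject.
phantom_geometry <- function(shape) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  x <- (seq_len(nx) - cx) / (nx / 2)
  y <- (seq_len(ny) - cy) / (ny / 2)
  z <- (seq_len(nz) - cz) / (nz / 2)
  X <- array(rep(x, times = ny * nz), shape)
  Y <- array(rep(rep(y, each = nx), times = nz), shape)
  Z <- array(rep(z, each = nx * ny), shape)

  brain_r2 <- (X / 0.9)^2 + (Y / 0.95)^2 + (Z / 0.85)^2
  background <- 0.4 / (1 + exp((brain_r2 - 1) * 12))   # soft brain edge

  hip <- function(side) {
    ((X - side * 0.36) / 0.19)^2 + (Y / 0.28)^2 + (Z / 0.19)^2
  }
  r2L <- hip(-1); r2R <- hip(+1)
  mask <- (r2L <= 1) | (r2R <= 1)
  list(background = background, r2L = r2L, r2R = r2R, mask = mask)
}

# One phantom volume. Atrophy shrinks the bright hippocampal core (the
# core covers radius^2 <= 1 - 0.5*atrophy of the masked ellipsoid) and dims
# it; aging dims it linearly. Noise is seeded per subject so cohorts can be
# generated in one pass or streamed subject-by-subject identically.
synth_volume <- function(cfg, geom, group, age, subject_index, subject_id) {
  atr <- cfg$atrophy_effect[[group]]
  core2 <- 1 - 0.5 * atr
  hippo_gain <- 0.45 * (1 - atr) + cfg$age_slope * (age - 75)
  core <- (geom$r2L <= core2) | (geom$r2R <= core2)
  vol <- geom$background + hippo_gain * core
  if (cfg$noise_sd > 0) {
    set.seed(cfg$seed + 7919L * subject_index)
    vol <- vol + array(stats::rnorm(length(vol), sd = cfg$noise_sd), dim(vol))
  }
  brain_volume(vol, subject_id)
}

#' Generate a synthetic phantom cohort
#'
#' Draws ages and group labels, then renders one phantom volume per subject
#' plus the shared hippocampus mask. Deterministic given the configuration:
#' the same `cfg` yields a bit-identical cohort, whether volumes are built
#' here or streamed later with [generate_volume()].
#'
#' @param cfg A [synthetic_config()].
#' @param keep_volumes If `FALSE`, skip rendering volumes (records and mask
#'   only); use [generate_volume()] to render subjects one at a time when a
#'   full cohort would not fit in memory.
#' @return List with `records` (subject `data.frame`), `volumes` (list of
#'   [brain_volume()] or `NULL`), and `mask` (a [hippocampus_mask()]).
#' @export
generate_cohort <- function(cfg, keep_volumes = TRUE) {
  stopifnot(inherits(cfg, "synthetic_config"))
  groups <- rep(c("AD", "NC", "MCIc", "MCInc"), times = cfg$n_per_group)
  n <- length(groups)
  if (n == 0) stop("empty cohort: all group counts are zero")
  set.seed(cfg$seed)
  ages <- stats::runif(n, cfg$age_range[1], cfg$age_range[2])
  ids <- sprintf("S%04d_%s", seq_len(n), groups)
  records <- data.frame(subject_id = ids,
                        group = factor(groups, levels = GROUP_LEVELS),
                        age = ages, stringsAsFactors = FALSE)
  geom <- phantom_geometry(cfg$volume_shape)
  mask <- hippocampus_mask(array(as.integer(geom$mask), cfg$volume_shape))
  volumes <- NULL
  if (keep_volumes) {
    volumes <- lapply(seq_len(n), function(i) {
      synth_volume(cfg, geom, groups[i], ages[i], i, ids[i])
    })
  }
  list(records = records, volumes = volumes, mask = mask)
}

#' Render one subject's phantom volume
#'
#' Streams a single volume of a cohort defined by `cfg` and the records of
#' [generate_cohort()]; identical to the volume `generate_cohort()` itself
#' would have produced at that row.
#'
#' @param cfg The [synthetic_config()] used for the cohort.
#' @param records Subject table from [generate_cohort()].
#' @param i Row index of the subject to render.
#' @return A [brain_volume()].
#' @export
generate_volume <- function(cfg, records, i) {
  stopifnot(inherits(cfg, "synthetic_config"), i >= 1, i <= nrow(records))
  geom <- phantom_geometry(cfg$volume_shape)
  synth_volume(cfg, geom, as.character(records$group[i]), records$age[i],
               i, records$subject_id[i])
}

#' Generate a structural (FreeSurfer-like) feature table
#'
#' Emulates a per-subject morphometric table: the first `n_informative`
#' columns carry a group mean shift (in pooled-SD units, MCIc vs MCInc
#' separated by `struct_effect_size`; AD vs NC by twice that) plus a linear
#' age trend; the remaining columns are pure standard-normal noise.
#'
#' @param cfg A [synthetic_config()].
#' @param records Subject table from [generate_cohort()].
#' @return Feature matrix (subjects x `n_struct_features`), rows named by
#'   subject id, columns `sf001`, `sf002`, ...
#' @export
generate_structural_features <- function(cfg, records) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- nrow(records)
  p <- cfg$n_struct_features
  set.seed(cfg$seed + 1L)
  vals <- matrix(stats::rnorm(n * p), n, p)
  k <- min(cfg$n_informative, p)
  if (k > 0 && cfg$struct_effect_size != 0) {
    gshift <- c(AD = 1, MCIc = 0.5, MCInc = -0.5, NC = -1, MCIun = 0)
    shift <- cfg$struct_effect_size * gshift[as.character(records$group)]
    vals[, seq_len(k)] <- vals[, seq_len(k)] + shift
  }
  if (k > 0 && cfg$feature_age_slope != 0) {
    vals[, seq_len(k)] <- vals[, seq_len(k)] +
      cfg$feature_age_slope * (records$age - 75)
  }
  feature_matrix(vals, records$subject_id,
                 sprintf("sf%03d", seq_len(p)))
}
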