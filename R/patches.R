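# Hippocampus-constrained 2.5D patch sampling.
#
# A 2.5D patch stacks three orthogonal 32x32 windows centered at one voxel:
# channel 1 transverse (fixed z), channel 2 coronal (fixed y), channel 3
# sagittal (fixed x). For the even window size 32 the center voxel sits at
# 1-based position 17 (offset 16); the window spans [c-16, c+15].

PATCH_SIZE <- 32L
PATCH_LO <- 16L   # voxels before the center
PATCH_HI <- 15L   # voxels after the center

# candidate voxels: in-mask AND all three windows fit inside the volume
patch_candidates <- function(mask_data) {
  shape <- dim(mask_data)
  idx <- which(mask_data != 0, arr.ind = TRUE)
  fits <- idx[, 1] > PATCH_LO & idx[, 1] <= shape[1] - PATCH_HI &
          idx[, 2] > PATCH_LO & idx[, 2] <= shape[2] - PATCH_HI &
          idx[, 3] > PATCH_LO & idx[, 3] <= shape[3] - PATCH_HI
  idx[fits, , drop = FALSE]
}

#' Sample fixed patch locations inside the hippocampus mask
#'
#' Random rejection sampling under the three constraints: centers lie in
#' the (left or right) hippocampus mask, all three 32x32 windows fit inside
#' the volume, and every pair of accepted centers is more than
#' `min_distance` voxels apart (Euclidean). The location list is meant to
#' be sampled once and reused for every subject of an experiment.
#'
#' @param mask A [hippocampus_mask()].
#' @param n Number of locations (default 151).
#' @param min_distance Pairwise Euclidean distance that every accepted pair
#'   must strictly exceed (default 2 voxels).
#' @param seed Integer seed; the returned list is deterministic given the
#'   mask and seed.
#' @param max_draws Rejection-sampling budget before the request is
#'   declared infeasible.
#' @return `data.frame` with columns `x`, `y`, `z` (1-based voxel indices),
#'   `n` rows, in acceptance order.
#' @export
sample_locations <- function(mask, n = 151, min_distance = 2, seed = 1,
                             max_draws = 10000) {
  stopifnot(inherits(mask, "hippocampus_mask"))
  if (n < 1) stop("n must be >= 1")
  cand <- patch_candidates(mask$data)
  if (nrow(cand) < n)
    stop("mask has only ", nrow(cand), " voxels where a 32x32x3 patch fits; ",
         n, " requested")
  set.seed(seed)
  acc <- matrix(0, n, 3)
  n_acc <- 0L
  draws <- 0L
  while (n_acc < n) {
    if (draws >= max_draws)
      stop("could not place ", n, " locations more than ", min_distance,
           " voxels apart within ", max_draws, " draws; mask too small")
    draws <- draws + 1L
    p <- cand[sample.int(nrow(cand), 1L), ]
    if (n_acc > 0L) {
      d2 <- (acc[seq_len(n_acc), 1] - p[1])^2 +
            (acc[seq_len(n_acc), 2] - p[2])^2 +
            (acc[seq_len(n_acc), 3] - p[3])^2
      if (any(d2 <= min_distance^2)) next
    }
    n_acc <- n_acc + 1L
    acc[n_acc, ] <- p
  }
  data.frame(x = as.integer(acc[, 1]), y = as.integer(acc[, 2]),
             z = as.integer(acc[, 3]))
}

#' Extract one 2.5D tri-planar patch
#'
#' Copies the three orthogonal 32x32 windows centered at `loc` into a
#' 32x32x3 array (channels: transverse, coronal, sagittal). Values are
#' copied untransformed; the center voxel's value appears at position
#' (17, 17) of all three channels.
#'
#' @param volume A [brain_volume()].
#' @param loc One location: a list/row with `x`, `y`, `z` (1-based).
#' @return 32x32x3 array of class `patch25d` with attributes `center` and
#'   `subject_id`.
#' @export
extract_patch <- function(volume, loc) {
  stopifnot(inherits(volume, "brain_volume"))
  x <- as.integer(loc[["x"]]); y <- as.integer(loc[["y"]]); z <- as.integer(loc[["z"]])
  shape <- dim(volume$data)
  if (x <= PATCH_LO || x > shape[1] - PATCH_HI ||
      y <= PATCH_LO || y > shape[2] - PATCH_HI ||
      z <= PATCH_LO || z > shape[3] - PATCH_HI)
    stop("patch window at (", x, ",", y, ",", z, ") falls outside the volume")
  xr <- (x - PATCH_LO):(x + PATCH_HI)
  yr <- (y - PATCH_LO):(y + PATCH_HI)
  zr <- (z - PATCH_LO):(z + PATCH_HI)
  patch <- array(0, c(PATCH_SIZE, PATCH_SIZE, 3L))
  patch[, , 1] <- volume$data[xr, yr, z]   # transverse: (x, y) at fixed z
  patch[, , 2] <- volume$data[xr, y, zr]   # coronal:    (x, z) at fixed y
  patch[, , 3] <- volume$data[x, yr, zr]   # sagittal:   (y, z) at fixed x
  structure(patch, center = c(x = x, y = y, z = z),
            subject_id = volume$subject_id, class = "patch25d")
}

#' Extract the patch set of one volume
#'
#' One [extract_patch()] per row of `locs`, order preserved; with the
#' default 151 locations this expands each image into 151 training samples.
#'
#' @param volume A [brain_volume()].
#' @param locs Locations `data.frame` from [sample_locations()].
#' @return List of `patch25d` arrays, `nrow(locs)` long.
#' @export
extract_patch_set <- function(volume, locs) {
  lapply(seq_len(nrow(locs)), function(i) extract_patch(volume, locs[i, ]))
}

#' Write patch locations to CSV
#' @param locs Locations `data.frame` from [sample_locations()].
#' @param path Output CSV path.
#' @export
write_locations <- function(locs, path) {
  utils::write.csv(locs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read patch locations from CSV
#' @param path CSV with columns `x`, `y`, `z`.
#' @return Locations `data.frame`.
#' @export
read_locations <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("x", "y", "z") %in% names(df)))
    stop("locations CSV must have columns x, y, z")
  df[, c("x", "y", "z")]
}
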