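# Domain containers and table I/O.
#
# Conventions used by every module (documented in the vignette):
#   * voxel indices are 1-based (R convention) with axis order (x, y, z);
#   * plane definitions: transverse = fixed z, coronal = fixed y,
#     sagittal = fixed x;
#   * all volumes live on one common template grid — mismatched shapes are
#     an error, never a resample trigger.

#' Diagnostic group labels
#'
#' The five labels a subject table may carry: Alzheimer's disease, normal
#' control, MCI converter, MCI non-converter and MCI with unknown outcome.
#' @export
GROUP_LEVELS <- c("AD", "NC", "MCIc", "MCInc", "MCIun")

#' Construct a brain volume
#'
#' A brain volume is a plain numeric 3D array tagged with a subject id.
#' All intensities must be finite and all dimensions strictly positive.
#'
#' @param data Numeric 3D array of intensities.
#' @param subject_id Character scalar.
#' @return Object of class `brain_volume` (list with `data`, `subject_id`).
#' @export
brain_volume <- function(data, subject_id = "") {
  if (is.null(dim(data)) || length(dim(data)) != 3L)
    stop("a brain volume must be a 3D array")
  if (any(dim(data) <= 0L)) stop("volume dimensions must be strictly positive")
  if (!all(is.finite(data))) stop("volume contains non-finite intensities")
  structure(list(data = data, subject_id = as.character(subject_id)),
            class = "brain_volume")
}

#' @export
print.brain_volume <- function(x, ...) {
  cat("<brain_volume> subject:", x$subject_id,
      " shape:", paste(dim(x$data), collapse = "x"),
      " range: [", format(min(x$data), digits = 4), ",",
      format(max(x$data), digits = 4), "]\n")
  invisible(x)
}

#' Construct a hippocampus mask
#'
#' Binary 3D array (values 0/1) marking the left and right hippocampal
#' regions on the template grid; must contain at least one nonzero voxel.
#'
#' @param data 3D array with values in \{0, 1\}.
#' @return Object of class `hippocampus_mask`.
#' @export
hippocampus_mask <- function(data) {
  if (is.null(dim(data)) || length(dim(data)) != 3L)
    stop("a hippocampus mask must be a 3D array")
  if (!all(data %in% c(0, 1))) stop("mask values must be 0 or 1")
  if (sum(data) < 1) stop("mask has no nonzero voxel")
  structure(list(data = array(as.integer(data), dim(data))),
            class = "hippocampus_mask")
}

#' @export
print.hippocampus_mask <- function(x, ...) {
  cat("<hippocampus_mask> shape:", paste(dim(x$data), collapse = "x"),
      " voxels:", sum(x$data), "\n")
  invisible(x)
}

stop_if_shape_mismatch <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b)))
    stop(what, " are on different grids (", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"),
         "); volumes must be pre-registered to one template grid")
}

#' Read a brain volume from a NIfTI file
#'
#' @param path `.nii` / `.nii.gz` file containing a 3D volume.
#' @param subject_id Subject id to tag the volume with; defaults to the
#'   file name without extensions.
#' @return A [brain_volume()].
#' @export
read_volume <- function(path, subject_id = NULL) {
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  arr <- read_nifti(path)
  attr(arr, "pixdim") <- NULL
  brain_volume(arr, subject_id)
}

#' Write a brain volume to a NIfTI file
#' @param volume A [brain_volume()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "brain_volume"))
  write_nifti(volume$data, path)
}

#' Read a hippocampus mask from a NIfTI file
#' @param path `.nii` / `.nii.gz` file containing a binary 3D volume.
#' @return A [hippocampus_mask()].
#' @export
read_mask <- function(path) {
  arr <- read_nifti(path)
  attr(arr, "pixdim") <- NULL
  hippocampus_mask(arr)
}

#' Write a hippocampus mask to a NIfTI file
#' @param mask A [hippocampus_mask()].
#' @param path Output path.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "hippocampus_mask"))
  write_nifti(mask$data, path, datatype = "int16")
}

#' Read a subject table
#'
#' CSV with header columns `subject_id` (or `id`), `group`, `age`; extra
#' columns (e.g. sex) are kept. Group labels are validated against
#' [GROUP_LEVELS] and ages against the plausible range 40–110 years.
#'
#' @param path CSV file path.
#' @return `data.frame` with `subject_id` (character), `group` (factor with
#'   levels [GROUP_LEVELS]) and `age` (numeric), one row per subject.
#' @export
read_subject_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "id"] <- "subject_id"
  needed <- c("subject_id", "group", "age")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0)
    stop("subject table lacks column(s): ", paste(missing, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  bad <- setdiff(unique(df$group), GROUP_LEVELS)
  if (length(bad) > 0)
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(GROUP_LEVELS, collapse = "/"), ")")
  age <- suppressWarnings(as.numeric(df$age))
  if (nrow(df) > 0 && any(is.na(age))) stop("unparsable age in subject table")
  if (nrow(df) > 0 && any(age < 40 | age > 110))
    stop("age outside plausible range [40, 110]")
  df$group <- factor(df$group, levels = GROUP_LEVELS)
  df$age <- age
  df
}

#' Write a subject table
#' @param records Subject `data.frame` as returned by [read_subject_table()].
#' @param path Output CSV path.
#' @export
write_subject_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a feature matrix
#'
#' Numeric matrix of per-subject features with subject ids as row names and
#' feature names as column names; entries must be finite.
#'
#' @param values Numeric matrix (subjects x features).
#' @param subject_ids Character vector, one id per row.
#' @param feature_names Character vector, one name per column.
#' @return Numeric matrix with dimnames set.
#' @export
feature_matrix <- function(values, subject_ids = rownames(values),
                           feature_names = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(subject_ids)) subject_ids <- as.character(seq_len(nrow(values)))
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(values)))
  if (length(subject_ids) != nrow(values))
    stop("subject_ids length must equal the row count")
  if (length(feature_names) != ncol(values))
    stop("feature_names length must equal the column count")
  if (!all(is.finite(values))) stop("feature matrix contains non-finite entries")
  dimnames(values) <- list(as.character(subject_ids), as.character(feature_names))
  values
}

#' Write a feature matrix to CSV at full precision
#'
#' Values are serialized with 17 significant digits so a write/read
#' round-trip is lossless for doubles.
#'
#' @param fm Feature matrix (see [feature_matrix()]).
#' @param path Output CSV path.
#' @export
write_feature_matrix <- function(fm, path) {
  fm <- feature_matrix(fm)
  header <- paste(c("subject_id", colnames(fm)), collapse = ",")
  body <- vapply(seq_len(nrow(fm)), function(i) {
    paste(c(rownames(fm)[i], sprintf("%.17g", fm[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a feature matrix from CSV
#'
#' Expects the layout of [write_feature_matrix()]: a `subject_id` column
#' followed by numeric feature columns. Ragged rows are an error.
#'
#' @param path CSV file path.
#' @return Numeric matrix with subject ids as row names.
#' @export
read_feature_matrix <- function(path) {
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) > 1) stop("ragged rows in feature CSV: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"subject_id" %in% names(df))
    stop("feature CSV lacks a subject_id column: ", path)
  ids <- as.character(df$subject_id)
  vals <- as.matrix(df[, setdiff(names(df), "subject_id"), drop = FALSE])
  storage.mode(vals) <- "double"
  feature_matrix(vals, ids, colnames(vals))
}
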