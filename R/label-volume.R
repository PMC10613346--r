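# LabelVolume: a 3D integer label grid plus its voxel-index -> anatomical-mm
# affine. All downstream measurement happens in mm space with a fixed axis
# convention: x = medial-lateral (ML), y = posterior-anterior (PA, +y
# anterior), z = inferior-superior (IS) -- RAS-like. Volumes are reoriented to
# this convention on load, and left knees are mirrored across the ML axis so
# the lateral compartment always lies at positive x.

#' Default label encoding
#'
#' Segmentation label ids for the three structures the pipeline measures.
#' @export
default_label_map <- function() {
  c(medial_meniscus = 1L, lateral_meniscus = 2L, tibial_plateau = 3L)
}

#' Construct a label volume
#'
#' @param voxels 3D array of non-negative integer labels.
#' @param affine 4x4 invertible matrix mapping 0-based voxel indices to mm.
#' @param label_map named integer vector assigning structure names to label
#'   ids; defaults to [default_label_map()].
#' @param side `"right"` or `"left"` knee. The stored volume is always in
#'   right-knee convention (lateral at +x); construction does not mirror,
#'   [read_label_volume()] does.
#' @return object of class `label_volume`.
#' @export
label_volume <- function(voxels, affine, label_map = default_label_map(),
                         side = "right") {
  if (length(dim(voxels)) != 3L) {
    stop("label_volume: voxels must be a 3D array", call. = FALSE)
  }
  storage.mode(voxels) <- "integer"
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4L, 4L)) ||
      abs(det(affine[1:3, 1:3])) < 1e-12) {
    stop("affine_singular: affine must be an invertible 4x4 matrix",
         call. = FALSE)
  }
  side <- match.arg(side, c("right", "left"))
  vol <- structure(
    list(voxels = voxels, affine = affine,
         spacing = sqrt(colSums(affine[1:3, 1:3]^2)),
         label_map = label_map, side = side),
    class = "label_volume")
  validate_label_volume(vol)
  vol
}

validate_label_volume <- function(vol) {
  if (any(vol$spacing <= 0)) {
    stop("label_volume: voxel spacing must be strictly positive", call. = FALSE)
  }
  present <- sort(unique(as.vector(vol$voxels)))
  if (any(present < 0L)) {
    stop("label_volume: negative labels present", call. = FALSE)
  }
  undeclared <- setdiff(present, c(0L, unname(vol$label_map)))
  if (length(undeclared)) {
    stop("label_undeclared: labels present but not in label_map: ",
         paste(undeclared, collapse = ", "), call. = FALSE)
  }
  invisible(vol)
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, ", x$side, " knee\n", sep = "")
  counts <- table(factor(x$voxels[x$voxels > 0L], levels = unname(x$label_map)))
  for (nm in names(x$label_map)) {
    cat(sprintf("  %-18s (label %d): %d voxels\n", nm, x$label_map[[nm]],
                counts[[as.character(x$label_map[[nm]])]]))
  }
  invisible(x)
}

# mm coordinates of voxel centers along each axis (requires normalized,
# axis-aligned affine)
axis_coords <- function(vol, axis) {
  n <- dim(vol$voxels)[axis]
  vol$affine[axis, 4] + (seq_len(n) - 1) * vol$affine[axis, axis]
}

#' Reorient a label volume to the package axis convention
#'
#' Permutes and flips the voxel axes so that voxel axis 1 advances along +x
#' (ML), axis 2 along +y (PA) and axis 3 along +z (IS), leaving every voxel at
#' the same mm position. Requires an affine whose direction vectors are
#' axis-dominant (no extreme obliquity). Idempotent.
#'
#' @param vol a `label_volume`.
#' @return reoriented `label_volume`.
#' @export
normalize_orientation <- function(vol) {
  R <- vol$affine[1:3, 1:3]
  perm <- apply(abs(R), 2, which.max)
  if (length(unique(perm)) != 3L) {
    stop("affine_oblique: cannot infer a voxel-axis to anatomical-axis ",
         "permutation from the affine", call. = FALSE)
  }
  # order voxel axes by the anatomical axis they dominate
  ord <- order(perm)
  vox <- aperm(vol$voxels, ord)
  R <- R[, ord, drop = FALSE]
  origin <- vol$affine[1:3, 4]
  for (ax in 1:3) {
    if (R[ax, ax] < 0) {
      vox <- flip_axis(vox, ax)
      origin <- origin + R[, ax] * (dim(vox)[ax] - 1)
      R[, ax] <- -R[, ax]
    }
  }
  affine <- rbind(cbind(R, origin), c(0, 0, 0, 1))
  label_volume(vox, affine, vol$label_map, vol$side)
}

flip_axis <- function(a, axis) {
  idx <- rep(list(quote(expr = )), 3)
  idx[[axis]] <- rev(seq_len(dim(a)[axis]))
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

# Mirror across the ML axis (x -> -x in mm space). Turns a left knee into
# right-knee convention so the lateral compartment is at +x.
mirror_ml <- function(vol) {
  vox <- flip_axis(vol$voxels, 1L)
  affine <- vol$affine
  nx <- dim(vox)[1]
  affine[1, 4] <- -(vol$affine[1, 4] + (nx - 1) * vol$affine[1, 1])
  label_volume(vox, affine, vol$label_map, side = "right")
}

#' Read a label volume from NIfTI
#'
#' Reads a 3D NIfTI-1 label image, checks that the data are integer labels,
#' reorients to the package convention (x = ML, y = PA, z = IS) and mirrors
#' left knees so the lateral compartment sits at positive x.
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @param label_map named integer vector of structure label ids.
#' @param side `"right"` or `"left"`; left knees are mirrored on load.
#' @param require_labels character vector of structure names that must be
#'   present in the volume (default: none).
#' @return a normalized `label_volume`.
#' @export
read_label_volume <- function(path, label_map = default_label_map(),
                              side = "right",
                              require_labels = character()) {
  nii <- read_nifti(path)
  dat <- nii$data
  if (any(dat != round(dat))) {
    stop("label_not_integer: volume contains non-integer values", call. = FALSE)
  }
  storage.mode(dat) <- "integer"
  vol <- label_volume(dat, nii$affine, label_map, side)
  vol <- normalize_orientation(vol)
  if (identical(side, "left")) vol <- mirror_ml(vol)
  for (nm in require_labels) {
    if (!nm %in% names(label_map)) {
      stop("label_absent: unknown structure name '", nm, "'", call. = FALSE)
    }
    if (!any(vol$voxels == label_map[[nm]])) {
      stop("label_absent: structure '", nm, "' (label ", label_map[[nm]],
           ") not present in ", path, call. = FALSE)
    }
  }
  vol
}

#' Write a label volume to NIfTI
#'
#' Round-trips exactly through [read_label_volume()]: labels bit-identical,
#' voxel mm positions identical up to float32 affine storage.
#'
#' @param vol a `label_volume`.
#' @param path output `.nii` or `.nii.gz` path.
#' @return the path, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  validate_label_volume(vol)
  write_nifti(vol$voxels, vol$affine, path)
}

# ---- tabular IO -------------------------------------------------------------

measurement_columns <- c(
  "subject_id", "group", "tear", "dlm_type",
  "a_body_min_width_mm", "b_tibia_max_width_mm", "c_anterior_horn_mm",
  "d_posterior_horn_mm", "e_max_ap_diameter_mm", "L_lateral_ap_mm",
  "M_medial_ap_mm", "rmt", "pcm", "lm_ratio")

#' Write a per-knee measurement table to CSV
#'
#' @param table data.frame with one row per knee; must contain the index
#'   columns (`rmt`, `pcm`, `lm_ratio`) and raw lengths in mm.
#' @param path output CSV path.
#' @export
write_measurements <- function(table, path) {
  validate_measurement_table(table)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-knee measurement table from CSV
#'
#' @param path CSV written by [write_measurements()] (RFC 4180, header row).
#' @return validated data.frame.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) {
    stop("table_file_missing: no such file: ", path, call. = FALSE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_measurement_table(tab)
  tab
}

validate_measurement_table <- function(tab) {
  missing_cols <- setdiff(c("subject_id", "rmt", "pcm", "lm_ratio"),
                          names(tab))
  if (length(missing_cols)) {
    stop("table_invalid: missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab$subject_id)) {
    stop("table_invalid: duplicated subject_id (one row per knee)",
         call. = FALSE)
  }
  idx <- as.matrix(tab[, c("rmt", "pcm", "lm_ratio")])
  if (any(!is.finite(idx)) || any(idx < 0)) {
    stop("table_invalid: indices must be finite and non-negative",
         call. = FALSE)
  }
  if (any(tab$pcm > 1 + 1e-9)) {
    stop("table_invalid: pcm exceeds 1", call. = FALSE)
  }
  invisible(tab)
}

#' Read a rater-by-subject rating table
#'
#' Wide-format CSV: first column names the rater (or rater/session), remaining
#' columns are one numeric measurement per subject. Used for reliability
#' (ICC) analysis. Every cell must be filled.
#'
#' @param path CSV path.
#' @return numeric matrix raters x subjects with dimnames.
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) {
    stop("table_file_missing: no such file: ", path, call. = FALSE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2L) {
    stop("ratings_invalid: need a rater column plus >= 1 subject column",
         call. = FALSE)
  }
  raters <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad)) {
    cells <- apply(bad, 1, function(ij) {
      paste0("(", raters[ij[1]], ", ", colnames(m)[ij[2]], ")")
    })
    stop("ratings_missing_cells: blank or non-numeric cells at ",
         paste(cells, collapse = ", "), call. = FALSE)
  }
  rownames(m) <- raters
  m
}

#' Write a rating table to CSV
#'
#' @param ratings numeric matrix raters x subjects.
#' @param path output CSV path.
#' @export
write_ratings <- function(ratings, path) {
  df <- data.frame(rater = rownames(ratings), ratings,
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
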