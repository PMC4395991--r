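#' Brain volume container
#'
#' Holds one subject's 3-D tracer-uptake grid (arbitrary units, e.g. FDG-PET
#' glucose metabolism). Non-finite and negative voxels are set to 0 on
#' construction so that the downstream intensity mask excludes them; the log
#' transform then only ever sees strictly positive masked voxels.
#'
#' @param grid 3-D numeric array of tracer-uptake intensities.
#' @param subject_id Character scalar identifying the subject.
#' @return A `brain_volume` object: list with `subject_id`, `grid`,
#'   `voxel_shape`.
#' @export
brain_volume <- function(grid, subject_id = "subject") {
  if (!is.array(grid) || length(dim(grid)) != 3L) {
    stop_ssm("`grid` must be a 3-D array")
  }
  grid[!is.finite(grid) | grid < 0] <- 0
  if (!any(grid > 0)) {
    stop_ssm("volume '", subject_id, "' has no strictly positive voxel")
  }
  structure(
    list(
      subject_id = as.character(subject_id),
      grid = grid,
      voxel_shape = as.integer(dim(grid))
    ),
    class = "brain_volume"
  )
}

#' @export
print.brain_volume <- function(x, ...) {
  cat(
    "<brain_volume> ", x$subject_id, ": ",
    paste(x$voxel_shape, collapse = " x "),
    " voxels, max intensity ", format(max(x$grid), digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Read a brain volume from disk
#'
#' Reads a NIfTI file (`.nii` / `.nii.gz`) or a plain-text 3-D stack. The
#' text format is a whitespace-delimited file whose first line gives the
#' three grid dimensions and whose remaining numbers list the voxel values
#' in grid order (first coordinate varying fastest). The subject id is the
#' filename stem.
#'
#' @param path Path to the volume file.
#' @return A [brain_volume()].
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) {
    stop_ssm("cannot read volume: file '", path, "' does not exist")
  }
  stem <- sub("\\.(nii(\\.gz)?|txt|tsv)$", "", basename(path))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    grid <- array(as.numeric(img), dim = dim(img))
  } else {
    tokens <- scan(path, what = numeric(), quiet = TRUE)
    dims <- as.integer(tokens[1:3])
    vals <- tokens[-(1:3)]
    if (length(vals) != prod(dims)) {
      stop_ssm("text volume '", path, "': expected ", prod(dims),
               " voxel values, found ", length(vals))
    }
    grid <- array(vals, dim = dims)
  }
  brain_volume(grid, subject_id = stem)
}

#' Write a brain volume
#'
#' @param volume A [brain_volume()].
#' @param path Output path; `.nii`/`.nii.gz` writes NIfTI, anything else the
#'   plain-text stack format of [load_volume()].
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    RNifti::writeNifti(RNifti::asNifti(volume$grid), path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(volume$voxel_shape, collapse = " "), con)
    writeLines(paste(format(as.vector(volume$grid), digits = 17), collapse = " "), con)
  }
  invisible(path)
}

#' Threshold mask at a fraction of the whole-brain maximum
#'
#' Keeps every voxel whose intensity is at least `threshold_fraction` times
#' the volume's maximum; voxels strictly below the threshold are removed.
#' The default 0.35 discards out-of-brain background and low-uptake tissue
#' before covariance-pattern extraction.
#'
#' @param volume A [brain_volume()].
#' @param threshold_fraction Fraction in (0, 1) of the whole-brain maximum.
#' @return A `voxel_mask`: list with logical array `keep`, count `n_kept`,
#'   and `threshold_fraction`.
#' @export
compute_mask <- function(volume, threshold_fraction = 0.35) {
  if (!is.numeric(threshold_fraction) || length(threshold_fraction) != 1L ||
      threshold_fraction <= 0 || threshold_fraction >= 1) {
    stop_ssm("`threshold_fraction` must be a single number in (0, 1)")
  }
  mx <- max(volume$grid)
  if (mx <= 0) stop_ssm("degenerate volume: maximum intensity is 0")
  keep <- volume$grid >= threshold_fraction * mx
  new_voxel_mask(keep, threshold_fraction)
}

new_voxel_mask <- function(keep, threshold_fraction = NA_real_) {
  structure(
    list(
      keep = keep,
      n_kept = sum(keep),
      threshold_fraction = threshold_fraction
    ),
    class = "voxel_mask"
  )
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat("<voxel_mask> ", x$n_kept, "/", length(x$keep), " voxels kept",
      if (!is.na(x$threshold_fraction))
        paste0(" (threshold ", x$threshold_fraction, " of max)"),
      "\n", sep = "")
  invisible(x)
}

#' Intersect voxel masks
#'
#' Voxel-wise logical AND of per-subject masks, giving the common voxel
#' space every subject's profile is expressed in.
#'
#' @param masks Non-empty list of congruent `voxel_mask` objects.
#' @return A `voxel_mask`.
#' @export
combine_masks <- function(masks) {
  if (length(masks) == 0L) stop_ssm("`masks` must be a non-empty list")
  dims <- lapply(masks, function(m) dim(m$keep))
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop_ssm("masks are not congruent in shape")
  }
  keep <- Reduce(`&`, lapply(masks, `[[`, "keep"))
  if (!any(keep)) {
    stop_ssm("mask intersection is empty; lower `threshold_fraction`")
  }
  new_voxel_mask(keep, masks[[1]]$threshold_fraction)
}

#' Extract a volume's masked voxels as a vector
#'
#' Voxels are flattened in a fixed grid order: the first coordinate varies
#' fastest, then the second, then the third. This order is what makes
#' pattern vectors reproducible across runs and models.
#'
#' @param volume A [brain_volume()].
#' @param mask A `voxel_mask` congruent with the volume.
#' @return Numeric vector of length `mask$n_kept`.
#' @export
masked_voxels <- function(volume, mask) {
  if (!identical(dim(mask$keep), dim(volume$grid))) {
    stop_ssm("mask shape does not match volume '", volume$subject_id, "'")
  }
  volume$grid[mask$keep]
}

#' Restore a masked voxel vector to a full grid
#'
#' Inverse of [masked_voxels()]: unmasked voxels are filled with `fill`.
#'
#' @param values Numeric vector of length `mask$n_kept`.
#' @param mask A `voxel_mask`.
#' @param fill Value for voxels outside the mask.
#' @return 3-D array of the mask's shape.
#' @export
unmask_voxels <- function(values, mask, fill = 0) {
  if (length(values) != mask$n_kept) {
    stop_ssm("`values` has length ", length(values), ", mask keeps ", mask$n_kept)
  }
  grid <- array(fill, dim = dim(mask$keep))
  grid[mask$keep] <- values
  grid
}

#' Assemble the subject-by-voxel data matrix
#'
#' Computes a per-subject intensity mask with [compute_mask()], intersects
#' the masks across subjects with [combine_masks()], and stacks the masked
#' voxel values into a subjects-by-voxels matrix. All entries inside the
#' common mask must be strictly positive (the log transform follows).
#'
#' @param volumes List of congruent [brain_volume()]s (at least 2).
#' @param labels Character vector of class labels, one per volume.
#' @param threshold_fraction Mask threshold, see [compute_mask()].
#' @return An `ssm_data_matrix`: list with `values` (M x V matrix, rows
#'   named by subject), `subject_ids`, `labels`, `mask`.
#' @export
build_data_matrix <- function(volumes, labels, threshold_fraction = 0.35) {
  if (length(volumes) < 2L) stop_ssm("need at least 2 volumes")
  if (length(labels) != length(volumes)) {
    stop_ssm("`labels` must have one entry per volume")
  }
  shapes <- lapply(volumes, function(v) v$voxel_shape)
  if (!all(vapply(shapes, identical, logical(1), shapes[[1]]))) {
    stop_ssm("volumes do not share a common grid shape")
  }
  masks <- lapply(volumes, compute_mask, threshold_fraction = threshold_fraction)
  mask <- combine_masks(masks)
  values <- t(vapply(volumes, masked_voxels, numeric(mask$n_kept), mask = mask))
  ids <- vapply(volumes, `[[`, character(1), "subject_id")
  bad <- which(values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop_ssm("non-positive intensity inside the common mask: subject '",
             ids[bad[1, 1]], "', masked voxel ", bad[1, 2])
  }
  rownames(values) <- ids
  structure(
    list(
      values = values,
      subject_ids = ids,
      labels = as.character(labels),
      mask = mask
    ),
    class = "ssm_data_matrix"
  )
}

#' @export
print.ssm_data_matrix <- function(x, ...) {
  cat("<ssm_data_matrix> ", nrow(x$values), " subjects x ", ncol(x$values),
      " masked voxels\n", sep = "")
  cat("labels:", paste(sprintf("%s (%d)", names(table(x$labels)),
                               table(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn build_data_matrix Masked intensities as a tibble
#'   (`subject_id`, `label`, then one column per voxel `v1..vV`).
#' @param x An `ssm_data_matrix`.
#' @param ... Unused.
#' @export
as_tibble.ssm_data_matrix <- function(x, ...) {
  vals <- tibble::as_tibble(x$values, .name_repair = ~ paste0("v", seq_along(.x)))
  dplyr::bind_cols(
    tibble::tibble(subject_id = x$subject_ids, label = x$labels),
    vals
  )
}
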