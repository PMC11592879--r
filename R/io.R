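#' Write an EEG recording to CSV (channel per column) with a JSON sidecar
#'
#' The CSV has one column per bipolar channel (header row = montage
#' names) and one row per sample; the sidecar JSON records the sampling
#' rate and the annotated ictal intervals.
#'
#' @param rec An `eeg_recording`.
#' @param path Output CSV path.
#' @param intervals_path Sidecar path; default `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_eeg_csv <- function(rec, path, intervals_path = paste0(path, ".json")) {
  df <- as.data.frame(t(rec$signals))
  names(df) <- rec$channel_names
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(fs = rec$fs,
         ictal_intervals = lapply(rec$ictal_intervals, as.numeric)),
    intervals_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load an EEG recording from CSV + JSON sidecar
#'
#' Channel order is normalized to the canonical montage; a file missing
#' any of the 18 channels is refused with the full list of absentees.
#' Channel-name matching is case-insensitive.
#'
#' @param path CSV with one named column per channel.
#' @param intervals_path JSON with fields `fs` (Hz) and
#'   `ictal_intervals` (list of `[start_s, end_s]`); default
#'   `<path>.json`.
#' @return An `eeg_recording`.
#' @export
load_eeg <- function(path, intervals_path = paste0(path, ".json")) {
  df <- read.csv(path, check.names = FALSE)
  chans <- tle_montage()
  idx <- match_channels(chans, names(df))
  sig <- t(as.matrix(df[, idx]))
  rownames(sig) <- chans

  meta <- jsonlite::read_json(intervals_path, simplifyVector = TRUE)
  if (is.null(meta$fs) || !is.numeric(meta$fs) || meta$fs <= 0)
    stop("sidecar must give a positive sampling rate 'fs'")
  ivs <- meta$ictal_intervals
  if (is.matrix(ivs)) ivs <- lapply(seq_len(nrow(ivs)), function(i) ivs[i, ])
  if (is.null(ivs) || length(ivs) == 0) stop("sidecar has no ictal_intervals")
  dur <- ncol(sig) / meta$fs
  for (iv in ivs) {
    if (length(iv) != 2 || !is.numeric(iv) || iv[1] < 0 || iv[2] <= iv[1] ||
        iv[1] > dur) {
      stop("unparsable or out-of-range ictal interval: ",
           paste(iv, collapse = ", "))
    }
  }
  structure(list(signals = sig, fs = meta$fs, channel_names = chans,
                 ictal_intervals = ivs),
            class = "eeg_recording")
}

#' Write a 3D volume to NIfTI-1
#'
#' @param volume 3D numeric or logical array (logical is stored as uint8).
#' @param path Output `.nii` or `.nii.gz` path.
#' @param affine 4x4 voxel-to-world matrix (world +x = subject right).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, affine) {
  stopifnot(length(dim(volume)) == 3, all(dim(affine) == c(4, 4)))
  is_mask <- is.logical(volume)
  img <- RNifti::asNifti(volume * 1)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path,
                     datatype = if (is_mask) "uint8" else "double")
  invisible(path)
}

#' Load a 3D volume and its affine from NIfTI-1
#'
#' @param path `.nii` or `.nii.gz` path; must be 3D.
#' @return List with `data` (3D array) and `affine` (4x4 voxel-to-world
#'   matrix, 0-based voxel convention). A 4D file or a non-invertible
#'   affine is refused.
#' @export
load_volume <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3) stop("expected a 3D volume, got ",
                                  length(dim(img)), "D: ", path)
  a <- unclass(RNifti::xform(img))
  a <- matrix(as.numeric(a), 4, 4)
  if (abs(det(a[1:3, 1:3])) < .Machine$double.eps) {
    stop("non-invertible affine in ", path)
  }
  list(data = as.array(img), affine = a)
}

#' Write a ground-truth sidecar for a synthetic dataset
#'
#' @param truth List of planted ground-truth values.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Assemble a GM cohort from NIfTI files
#'
#' Reads the patient GM map, every control map in a directory, and the
#' two hemisphere ROI masks, checking that all share the patient's shape
#' and affine (inputs are assumed co-registered; mismatches are refused).
#'
#' @param patient_path Patient GM NIfTI.
#' @param controls_dir Directory whose `.nii`/`.nii.gz` files are the
#'   control GM maps (>= 3).
#' @param roi_left_path,roi_right_path Hemisphere ROI mask NIfTIs.
#' @return A `gm_cohort` usable by [vbm_lateralize()].
#' @export
load_gm_cohort <- function(patient_path, controls_dir,
                           roi_left_path, roi_right_path) {
  pat <- load_volume(patient_path)
  files <- list.files(controls_dir, pattern = "\\.nii(\\.gz)?$",
                      full.names = TRUE)
  if (length(files) < 3) stop("need >= 3 control volumes in ", controls_dir)
  controls <- lapply(files, load_volume)
  rl <- load_volume(roi_left_path)
  rr <- load_volume(roi_right_path)
  for (v in c(controls, list(rl, rr))) {
    if (!identical(dim(v$data), dim(pat$data)) ||
        max(abs(v$affine - pat$affine)) > 1e-4) {
      stop("cohort volumes must share the patient's shape and affine ",
           "(co-registered inputs)")
    }
  }
  vs <- sqrt(colSums(pat$affine[1:3, 1:3]^2))
  structure(list(patient_gm = pat$data,
                 controls_gm = lapply(controls, `[[`, "data"),
                 voxel_size = vs, affine = pat$affine,
                 roi_left = rl$data != 0, roi_right = rr$data != 0),
            class = "gm_cohort")
}
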