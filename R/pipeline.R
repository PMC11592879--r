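#' Run the full lateralization pipeline for one patient
#'
#' Executes whichever analyses the inputs support — hippocampal
#' morphometry (Analysis-1), VBM (Analysis-2), EEG symmetry analysis
#' (Analysis-3) — and fuses the resulting labels. A missing modality
#' contributes the neutral label `"NONE"` (encoding 0), generalizing the
#' MRI-negative convention; at least one modality must be present.
#'
#' @param eeg List of `eeg_recording`s, or `NULL`.
#' @param hippo A `hippo_study` plus the LDA training set, as
#'   `list(study =, train_x =, train_y =)`, or `NULL`.
#' @param gm A `gm_cohort`, or `NULL`.
#' @param vbm_args List of [vbm_lateralize()] parameters
#'   (`p_thresh`, `min_cluster`, `fwhm`, `connectivity`).
#' @param epoch_len Optional EEG sub-epoch length in seconds.
#' @return A `patient_report`: list with `L1`, `L2`, `L3` (sides),
#'   `final`, `evidence` (per-analysis detail: morphometric features,
#'   the VBM decision, per-pair asymmetry scores) and `parameters`
#'   (every threshold applied).
#' @export
#' @examples
#' rec <- gen_ictal_eeg(synth_eeg_config(duration = 6, ictal_interval = c(2, 5)))
#' run_pipeline(eeg = list(rec))$final
run_pipeline <- function(eeg = NULL, hippo = NULL, gm = NULL,
                         vbm_args = list(), epoch_len = NULL) {
  if (is.null(eeg) && is.null(hippo) && is.null(gm)) {
    stop("at least one modality (eeg, hippo, gm) must be provided")
  }
  evidence <- list()

  L1 <- "NONE"
  if (!is.null(hippo)) {
    stopifnot(all(c("study", "train_x", "train_y") %in% names(hippo)))
    feats <- extract_features(hippo$study)
    L1 <- hippo_lateralize(feats, hippo$train_x, hippo$train_y,
                           feature_set = hippo$feature_set %||% "volumes")
    evidence$analysis1 <- list(features = feats, side = L1)
  }

  L2 <- "NONE"
  if (!is.null(gm)) {
    dec <- do.call(vbm_lateralize, c(list(cohort = gm), vbm_args))
    L2 <- if (dec$side == "MRI_NEGATIVE") "NONE" else dec$side
    evidence$analysis2 <- dec
  }

  L3 <- "NONE"
  if (!is.null(eeg)) {
    res <- eeg_lateralize(eeg, epoch_len = epoch_len)
    L3 <- res$patient_side
    evidence$analysis3 <- res
  }

  final <- fuse(L1, L2, L3)
  params <- list(
    fusion_rule = "sum of {LEFT=+1, RIGHT=-1, NONE=0}; sum > 0 -> LEFT, else RIGHT",
    pair_label_rule = "A > 1 -> +1, else -1",
    vbm = c(list(p_thresh = 0.001, min_cluster = 50, fwhm = 8,
                 connectivity = 26)[setdiff(
                   c("p_thresh", "min_cluster", "fwhm", "connectivity"),
                   names(vbm_args))], vbm_args),
    epoch_len = epoch_len
  )
  structure(list(L1 = L1, L2 = L2, L3 = L3, final = final,
                 evidence = evidence, parameters = params),
            class = "patient_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.patient_report <- function(x, ...) {
  cat(sprintf("<patient_report> L1 = %s, L2 = %s, L3 = %s -> final %s\n",
              x$L1, x$L2, x$L3, x$final))
  invisible(x)
}

#' Serialize a patient report to JSON
#'
#' @param report A `patient_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_patient_report <- function(report, path) {
  slim <- list(
    L1 = report$L1, L2 = report$L2, L3 = report$L3, final = report$final,
    parameters = report$parameters
  )
  if (!is.null(report$evidence$analysis1)) {
    slim$analysis1_features <- unclass(report$evidence$analysis1$features)
  }
  if (!is.null(report$evidence$analysis2)) {
    d <- report$evidence$analysis2
    slim$analysis2 <- list(
      side = d$side, p_threshold = d$p_threshold,
      min_cluster = d$min_cluster, fwhm = d$fwhm,
      cluster_size = if (is.null(d$winning_cluster)) NULL else d$winning_cluster$size,
      peak_t = if (is.null(d$winning_cluster)) NULL else d$winning_cluster$peak_t,
      peak_world = if (is.null(d$winning_cluster)) NULL else d$winning_cluster$peak_world)
  }
  if (!is.null(report$evidence$analysis3)) {
    a3 <- report$evidence$analysis3
    slim$analysis3 <- list(
      patient_side = a3$patient_side,
      recording_sides = a3$recording_sides,
      pair_scores = lapply(a3$recordings, function(r) r$pairs))
  }
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
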