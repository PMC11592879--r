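#' VBM lateralization of a patient against a control cohort (Analysis-2)
#'
#' The simplified voxel-based morphometry decision: smooth the patient
#' and control GM maps, compute the single-case reduction t-map, extract
#' suprathreshold clusters exceeding the extent threshold, keep those
#' intersecting the temporal+limbic ROI of either hemisphere, and take as
#' winning cluster the one containing the maximum t inside the ROI union.
#' The side is the hemisphere of the winning cluster's peak (world x
#' sign); a midline peak is resolved by the hemisphere holding the
#' majority of the cluster's voxels. No surviving cluster means
#' MRI-negative.
#'
#' @param cohort A `gm_cohort` ([gen_gm_cohort()] or assembled from
#'   [load_volume()] calls); must carry `patient_gm`, `controls_gm`,
#'   `affine`, `voxel_size`, `roi_left`, `roi_right`. Shapes must match —
#'   mismatched cohorts are refused (inputs are assumed co-registered).
#' @param p_thresh Voxel-level one-tailed p threshold (default 0.001).
#' @param min_cluster Cluster-extent threshold, strictly exceeded
#'   (default 50).
#' @param fwhm Smoothing FWHM in mm (default 8).
#' @param connectivity Cluster connectivity (default 26).
#' @return A `vbm_decision`: `side` (`"LEFT"`, `"RIGHT"` or
#'   `"MRI_NEGATIVE"`), `winning_cluster` (a cluster or `NULL`),
#'   `clusters` (all ROI-intersecting survivors), `p_threshold`,
#'   `min_cluster`, `fwhm`, `stat` (the `stat_map`).
#' @export
#' @examples
#' co <- gen_gm_cohort(synth_gm_config(grid_shape = c(24, 24, 24),
#'                                     voxel_size = 6, n_controls = 6,
#'                                     atrophy_radius = 12, seed = 5))
#' vbm_lateralize(co, min_cluster = 5)$side
vbm_lateralize <- function(cohort, p_thresh = 0.001, min_cluster = 50,
                           fwhm = 8, connectivity = 26) {
  req <- c("patient_gm", "controls_gm", "affine", "voxel_size",
           "roi_left", "roi_right")
  miss <- setdiff(req, names(cohort))
  if (length(miss)) stop("cohort is missing: ", paste(miss, collapse = ", "))
  d <- dim(cohort$patient_gm)
  same <- vapply(c(cohort$controls_gm, list(cohort$roi_left, cohort$roi_right)),
                 function(v) identical(dim(v), d), logical(1))
  if (!all(same)) stop("cohort volumes/ROIs have mismatched shapes; ",
                       "inputs must be co-registered")
  if (any(cohort$roi_left & cohort$roi_right)) stop("hemisphere ROIs overlap")

  sm_patient <- gaussian_smooth(cohort$patient_gm, fwhm, cohort$voxel_size)
  sm_controls <- lapply(cohort$controls_gm, gaussian_smooth,
                        fwhm_mm = fwhm, voxel_size = cohort$voxel_size)
  stat <- single_subject_tmap(sm_patient, sm_controls)
  clusters <- threshold_and_cluster(stat, p_thresh, min_cluster,
                                    affine = cohort$affine,
                                    connectivity = connectivity)

  roi <- cohort$roi_left | cohort$roi_right
  roi_ids <- which(roi)
  clusters <- Filter(function(cl) any(cl$voxel_ids %in% roi_ids), clusters)

  if (length(clusters) == 0) {
    return(structure(list(side = "MRI_NEGATIVE", winning_cluster = NULL,
                          clusters = list(), p_threshold = p_thresh,
                          min_cluster = min_cluster, fwhm = fwhm, stat = stat),
                     class = "vbm_decision"))
  }

  # winning cluster: the one holding the global max t inside the ROI union
  best_in_roi <- vapply(clusters, function(cl) {
    inside <- intersect(cl$voxel_ids, roi_ids)
    max(stat$t[inside])
  }, numeric(1))
  win <- clusters[[which.max(best_in_roi)]]

  side <- hemisphere_from_world(win$peak_world[1])
  if (side == "MIDLINE") {
    # resolve by the hemisphere containing most of the cluster's voxels
    xw <- world_x_grid(d, cohort$affine)[win$voxel_ids]
    side <- if (sum(xw < 0) >= sum(xw > 0)) "LEFT" else "RIGHT"
    message("midline peak resolved by cluster-majority hemisphere: ", side)
  }

  structure(list(side = side, winning_cluster = win, clusters = clusters,
                 p_threshold = p_thresh, min_cluster = min_cluster,
                 fwhm = fwhm, stat = stat),
            class = "vbm_decision")
}

#' @export
print.vbm_decision <- function(x, ...) {
  cat("<vbm_decision> side:", x$side,
      sprintf("(p < %g, cluster > %d voxels, FWHM %g mm)\n",
              x$p_threshold, x$min_cluster, x$fwhm))
  if (!is.null(x$winning_cluster)) print(x$winning_cluster)
  invisible(x)
}
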