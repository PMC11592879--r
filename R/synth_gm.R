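#' Configuration for the synthetic gray-matter cohort
#'
#' Emulates a co-registered VBM dataset: a smooth baseline gray-matter
#' (GM) probability template shared by a control cohort (template + iid
#' voxel noise) and one patient whose map additionally carries a spherical
#' atrophy — GM probability reduced by `atrophy_depth` inside a ball of
#' `atrophy_radius` mm planted inside one hemisphere's region of interest
#' (ROI). The ROIs are axis-aligned boxes standing in for the temporal +
#' limbic lobes of each hemisphere; atlas parcellation is out of scope.
#'
#' @param grid_shape Volume dimensions in voxels (default `c(48, 48, 48)`).
#' @param voxel_size Isotropic voxel size in mm (default 3).
#' @param n_controls Number of control subjects (>= 3; default 14).
#' @param focus_side `"LEFT"`, `"RIGHT"` or `"NONE"` (no atrophy).
#' @param atrophy_center World coordinates (mm) of the atrophy; default
#'   `(-35, -20, -15)` mirrored to `+35` for a right focus — inside the
#'   mesial temporal portion of the ROI box.
#' @param atrophy_radius Ball radius in mm (default 6).
#' @param atrophy_depth GM-probability reduction in (0, 1] (default 0.4);
#'   0 is allowed and produces a null patient.
#' @param control_noise_sd Per-voxel iid noise sd (default 0.02).
#' @param seed Integer seed.
#' @return An object of class `synth_gm_config`.
#' @export
synth_gm_config <- function(grid_shape = c(48, 48, 48), voxel_size = 3,
                            n_controls = 14,
                            focus_side = c("LEFT", "RIGHT", "NONE"),
                            atrophy_center = NULL, atrophy_radius = 6,
                            atrophy_depth = 0.4, control_noise_sd = 0.02,
                            seed = 1L) {
  focus_side <- match.arg(focus_side)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 8), voxel_size > 0,
            n_controls >= 3, atrophy_radius > 0,
            atrophy_depth >= 0, atrophy_depth <= 1, control_noise_sd > 0)
  if (is.null(atrophy_center)) {
    atrophy_center <- switch(focus_side,
                             LEFT = c(-35, -20, -15),
                             RIGHT = c(35, -20, -15),
                             NONE = c(-35, -20, -15))
  }
  structure(list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
                 n_controls = as.integer(n_controls), focus_side = focus_side,
                 atrophy_center = atrophy_center,
                 atrophy_radius = atrophy_radius, atrophy_depth = atrophy_depth,
                 control_noise_sd = control_noise_sd, seed = as.integer(seed)),
            class = "synth_gm_config")
}

# temporal+limbic stand-in ROI boxes in world mm; side = "LEFT"/"RIGHT"
roi_box_mask <- function(grid_shape, affine, side) {
  w <- world_coord_grids(grid_shape, affine)
  x <- w[[1]]; y <- w[[2]]; z <- w[[3]]
  xr <- if (side == "LEFT") c(-62, -12) else c(12, 62)
  (x >= xr[1] & x <= xr[2]) & (y >= -62 & y <= 22) & (z >= -42 & z <= 22)
}

#' Generate a synthetic GM cohort with a planted atrophy of known side
#'
#' Controls share a smooth radially decaying GM template plus iid noise;
#' the patient gets the same template and noise model minus
#' `atrophy_depth` inside the planted ball. All maps are clipped to
#' \[0, 1\]. The atrophy must lie entirely within one hemisphere's ROI; a
#' ball touching both ROIs is a configuration error.
#'
#' @param cfg A [synth_gm_config()].
#' @return A `gm_cohort`: list with `patient_gm` (3D array), `controls_gm`
#'   (list of 3D arrays), `voxel_size`, `affine`, `roi_left`, `roi_right`
#'   (logical arrays) and `truth` (`focus_side`, `atrophy_center`,
#'   `atrophy_radius`, `atrophy_depth`, `blob_voxels` = planted ball voxel
#'   count).
#' @export
#' @examples
#' co <- gen_gm_cohort(synth_gm_config(grid_shape = c(24, 24, 24),
#'                                     n_controls = 5, seed = 2))
#' range(co$patient_gm)
gen_gm_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synth_gm_config"))
  set.seed(cfg$seed)
  gs <- cfg$grid_shape
  affine <- default_affine(gs, cfg$voxel_size)
  w <- world_coord_grids(gs, affine)

  # smooth baseline: radially decaying GM probability, ~0.75 centrally
  r2 <- w[[1]]^2 + w[[2]]^2 + w[[3]]^2
  template <- 0.75 * exp(-r2 / (2 * 55^2))

  d2 <- (w[[1]] - cfg$atrophy_center[1])^2 +
        (w[[2]] - cfg$atrophy_center[2])^2 +
        (w[[3]] - cfg$atrophy_center[3])^2
  ball <- d2 <= cfg$atrophy_radius^2

  roi_l <- roi_box_mask(gs, affine, "LEFT")
  roi_r <- roi_box_mask(gs, affine, "RIGHT")
  if (cfg$focus_side != "NONE" && cfg$atrophy_depth > 0) {
    if (any(ball & roi_l) && any(ball & roi_r)) {
      stop("atrophy ball intersects both hemisphere ROIs; move the center")
    }
  }

  clip01 <- function(v) { v[v < 0] <- 0; v[v > 1] <- 1; v }
  noise <- function() array(rnorm(prod(gs), sd = cfg$control_noise_sd), gs)
  controls <- lapply(seq_len(cfg$n_controls), function(i) clip01(template + noise()))
  patient <- template + noise()
  if (cfg$focus_side != "NONE") patient[ball] <- patient[ball] - cfg$atrophy_depth
  patient <- clip01(patient)

  structure(list(patient_gm = patient, controls_gm = controls,
                 voxel_size = rep_len(cfg$voxel_size, 3), affine = affine,
                 roi_left = roi_l, roi_right = roi_r,
                 truth = list(focus_side = cfg$focus_side,
                              atrophy_center = cfg$atrophy_center,
                              atrophy_radius = cfg$atrophy_radius,
                              atrophy_depth = cfg$atrophy_depth,
                              blob_voxels = sum(ball))),
            class = "gm_cohort")
}

#' @export
print.gm_cohort <- function(x, ...) {
  cat(sprintf("<gm_cohort> %s grid, %d controls, voxel %g mm\n",
              paste(dim(x$patient_gm), collapse = "x"),
              length(x$controls_gm), x$voxel_size[1]))
  invisible(x)
}

#' Configuration for the synthetic tissue-intensity volume
#'
#' A K-class Gaussian mixture over voxel intensities, emulating the
#' input to GMM-based tissue segmentation (e.g. CSF / gray matter / white
#' matter on T1).
#'
#' @param class_means Numeric vector of K component means (gray levels).
#' @param class_sds Component standard deviations (length K or scalar).
#' @param class_fractions Mixing fractions (nonnegative, sum 1).
#' @param grid_shape Volume dimensions in voxels.
#' @param seed Integer seed.
#' @return An object of class `synth_tissue_config`.
#' @export
synth_tissue_config <- function(class_means = c(0.2, 0.5, 0.8),
                                class_sds = 0.03,
                                class_fractions = NULL,
                                grid_shape = c(24, 24, 24), seed = 1L) {
  k <- length(class_means)
  if (k < 1) stop("at least one tissue class is required")
  class_sds <- rep_len(class_sds, k)
  if (is.null(class_fractions)) class_fractions <- rep(1 / k, k)
  stopifnot(length(class_fractions) == k, all(class_fractions >= 0),
            all(class_sds > 0))
  if (abs(sum(class_fractions) - 1) > 1e-8) stop("class_fractions must sum to 1")
  structure(list(class_means = class_means, class_sds = class_sds,
                 class_fractions = class_fractions,
                 grid_shape = as.integer(grid_shape), seed = as.integer(seed)),
            class = "synth_tissue_config")
}

#' Generate a synthetic tissue-intensity volume with known class labels
#'
#' @param cfg A [synth_tissue_config()].
#' @return List with `volume` (3D array of intensities), `labels` (3D
#'   integer array of true component indices, ordered by `class_means` as
#'   given) and the config.
#' @export
gen_tissue_volume <- function(cfg) {
  stopifnot(inherits(cfg, "synth_tissue_config"))
  set.seed(cfg$seed)
  n <- prod(cfg$grid_shape)
  lab <- sample.int(length(cfg$class_means), n, replace = TRUE,
                    prob = cfg$class_fractions)
  x <- rnorm(n, mean = cfg$class_means[lab], sd = cfg$class_sds[lab])
  list(volume = array(x, cfg$grid_shape),
       labels = array(lab, cfg$grid_shape),
       config = cfg)
}
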