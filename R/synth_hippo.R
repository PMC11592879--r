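#' Configuration for the synthetic hippocampus slice study
#'
#' Emulates a T2-weighted coronal slice stack with expert-drawn left and
#' right hippocampus masks. Each hippocampus is an elliptical cross-section
#' (in-plane radii `radius` x `0.6 * radius`, in mm) repeated across
#' slices. Hippocampal sclerosis is emulated by a smaller mask and an
#' elevated mean intensity on the sclerotic side: gliosis raises the T2
#' signal while atrophy shrinks the structure.
#'
#' @param n_slices Number of coronal slices (>= 1).
#' @param slice_thickness Slice thickness in mm.
#' @param pixel_area In-plane pixel area in mm^2 (pixels are assumed
#'   square, spacing `sqrt(pixel_area)`).
#' @param left_radius,right_radius Major in-plane radius of each
#'   hippocampus in mm. Defaults give the sclerotic side (if any) an 18%
#'   smaller radius.
#' @param sclerotic_side `"LEFT"`, `"RIGHT"` or `"NONE"`.
#' @param intensity_boost Added mean gray level on the sclerotic side.
#' @param tissue_mean,background_mean Baseline gray levels.
#' @param noise_sd Additive Gaussian pixel noise.
#' @param img_dim Image size in pixels `(rows, cols)`.
#' @param seed Integer seed.
#' @return An object of class `synth_hippo_config`.
#' @export
synth_hippo_config <- function(n_slices = 10, slice_thickness = 2,
                               pixel_area = 0.25,
                               sclerotic_side = c("NONE", "LEFT", "RIGHT"),
                               left_radius = NULL, right_radius = NULL,
                               intensity_boost = 20,
                               tissue_mean = 100, background_mean = 40,
                               noise_sd = 5, img_dim = c(64, 96), seed = 1L) {
  sclerotic_side <- match.arg(sclerotic_side)
  base_r <- 8
  shrink <- 0.82
  if (is.null(left_radius))
    left_radius <- if (sclerotic_side == "LEFT") base_r * shrink else base_r
  if (is.null(right_radius))
    right_radius <- if (sclerotic_side == "RIGHT") base_r * shrink else base_r
  if (n_slices < 1 || slice_thickness <= 0 || pixel_area <= 0 ||
      left_radius <= 0 || right_radius <= 0) {
    stop("geometry must be positive: n_slices >= 1, slice_thickness, ",
         "pixel_area and radii > 0")
  }
  structure(list(n_slices = as.integer(n_slices),
                 slice_thickness = slice_thickness, pixel_area = pixel_area,
                 left_radius = left_radius, right_radius = right_radius,
                 sclerotic_side = sclerotic_side,
                 intensity_boost = intensity_boost,
                 tissue_mean = tissue_mean, background_mean = background_mean,
                 noise_sd = noise_sd, img_dim = as.integer(img_dim),
                 seed = as.integer(seed)),
            class = "synth_hippo_config")
}

# filled ellipse mask: rows x cols, center (r0, c0) and semi-axes in pixels
ellipse_mask <- function(dim, center, a, b) {
  r <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cc <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  ((cc - center[2]) / a)^2 + ((r - center[1]) / b)^2 <= 1
}

#' Generate a synthetic hippocampus slice study with known true volumes
#'
#' @param cfg A [synth_hippo_config()].
#' @return A `hippo_study`: list with `slices` (each a list of `image`,
#'   `left_mask`, `right_mask` matrices), `pixel_area`, `slice_thickness`,
#'   and `truth` (`vol_left`, `vol_right` in mm^3 computed as
#'   mask-pixel-count x pixel area x slice thickness, and the planted
#'   `sclerotic_side`). In radiological display convention the image
#'   columns run right-to-left, so the *left* hippocampus sits in the
#'   right half of the image; masks are returned explicitly so no
#'   laterality convention needs to be inferred downstream.
#' @export
#' @examples
#' st <- gen_hippo_study(synth_hippo_config(sclerotic_side = "RIGHT", seed = 3))
#' st$truth$vol_right < st$truth$vol_left
gen_hippo_study <- function(cfg) {
  stopifnot(inherits(cfg, "synth_hippo_config"))
  set.seed(cfg$seed)
  px <- sqrt(cfg$pixel_area)          # pixel spacing, mm
  dm <- cfg$img_dim
  ctr_row <- dm[1] / 2
  left_center <- c(ctr_row, dm[2] * 0.70)   # radiological: subject left on image right
  right_center <- c(ctr_row, dm[2] * 0.30)

  mk <- function(center, radius_mm) {
    ellipse_mask(dm, center, a = radius_mm / px, b = 0.6 * radius_mm / px)
  }
  lmask <- mk(left_center, cfg$left_radius)
  rmask <- mk(right_center, cfg$right_radius)

  boost_l <- if (cfg$sclerotic_side == "LEFT") cfg$intensity_boost else 0
  boost_r <- if (cfg$sclerotic_side == "RIGHT") cfg$intensity_boost else 0

  slices <- lapply(seq_len(cfg$n_slices), function(i) {
    img <- matrix(cfg$background_mean, dm[1], dm[2])
    img[lmask] <- cfg$tissue_mean + boost_l
    img[rmask] <- cfg$tissue_mean + boost_r
    img <- img + matrix(rnorm(prod(dm), sd = cfg$noise_sd), dm[1], dm[2])
    list(image = img, left_mask = lmask, right_mask = rmask)
  })

  vol <- function(mask) sum(mask) * cfg$pixel_area * cfg$n_slices * cfg$slice_thickness
  structure(list(slices = slices, pixel_area = cfg$pixel_area,
                 slice_thickness = cfg$slice_thickness,
                 truth = list(vol_left = vol(lmask), vol_right = vol(rmask),
                              sclerotic_side = cfg$sclerotic_side)),
            class = "hippo_study")
}

#' @export
print.hippo_study <- function(x, ...) {
  cat(sprintf("<hippo_study> %d slices, pixel area %g mm^2, thickness %g mm\n",
              length(x$slices), x$pixel_area, x$slice_thickness))
  invisible(x)
}
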