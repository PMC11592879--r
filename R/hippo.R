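#' Threshold a labeled image into a binary mask
#'
#' Expert hippocampus delineations arrive as gray-level overlay images;
#' thresholding recovers the binary mask. When no threshold is given,
#' Otsu's method on the image histogram picks one.
#'
#' @param labeled_image Numeric matrix.
#' @param threshold Scalar; pixels strictly above it are foreground.
#'   Default `NULL` uses Otsu's threshold.
#' @return Logical matrix of the same shape.
#' @export
binarize_mask <- function(labeled_image, threshold = NULL) {
  if (is.null(threshold)) threshold <- otsu_threshold(labeled_image)
  labeled_image > threshold
}

# Otsu's threshold: maximize between-class variance over a 256-bin histogram
otsu_threshold <- function(img, n_bins = 256) {
  v <- as.numeric(img)
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

#' Area of a binary region
#'
#' `Area = (number of foreground pixels) x (pixel area)`.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param pixel_area Pixel area in mm^2.
#' @return Area in mm^2.
#' @export
#' @examples
#' region_area(matrix(TRUE, 10, 10), 0.25)  # 25
region_area <- function(mask, pixel_area) {
  stopifnot(pixel_area > 0)
  sum(mask != 0) * pixel_area
}

#' Volume from per-slice areas
#'
#' `Volume = sum_i Area_i x slice thickness`.
#'
#' @param areas Numeric vector of per-slice areas in mm^2.
#' @param slice_thickness Slice thickness in mm.
#' @return Volume in mm^3.
#' @export
#' @examples
#' region_volume(c(25, 25, 0), 2)  # 100
region_volume <- function(areas, slice_thickness) {
  if (length(areas) < 1) stop("at least one slice is required")
  if (slice_thickness <= 0) stop("slice_thickness must be positive")
  sum(areas) * slice_thickness
}

#' Mean and standard deviation of masked pixel intensities
#'
#' `mu = (1/N) sum(x_n)` and `sigma = sqrt( (1/(N-1)) sum((x_n - mu)^2) )`
#' over the N foreground pixels.
#'
#' @param image Numeric matrix.
#' @param mask Logical matrix of the same shape.
#' @return List with `mu` and `sigma`. With a single foreground pixel,
#'   `sigma` is `NA_real_` (undefined) with a warning; an empty mask is an
#'   error.
#' @export
#' @examples
#' region_stats(matrix(c(2, 4, 6, 0), 2), matrix(c(TRUE, TRUE, TRUE, FALSE), 2))
region_stats <- function(image, mask) {
  stopifnot(all(dim(image) == dim(mask)))
  x <- image[mask != 0]
  n <- length(x)
  if (n == 0) stop("empty mask: no pixels to summarize")
  mu <- sum(x) / n
  if (n == 1) {
    warning("single-pixel region: sigma undefined")
    return(list(mu = mu, sigma = NA_real_))
  }
  list(mu = mu, sigma = sqrt(sum((x - mu)^2) / (n - 1)))
}

#' Extract morphometric features from a hippocampus study (Analysis-1)
#'
#' Left and right hippocampus volumes accumulate over all slices; the
#' per-slice intensity mean and standard deviation are averaged across
#' slices with equal slice weights.
#'
#' @param study A `hippo_study` (see [gen_hippo_study()]).
#' @return A `morph_features` list: `vol_left`, `vol_right` (mm^3),
#'   `mean_left`, `mean_right`, `sd_left`, `sd_right` (gray levels).
#' @export
extract_features <- function(study) {
  stopifnot(inherits(study, "hippo_study") || is.list(study))
  sl <- study$slices
  if (length(sl) < 1) stop("study has no slices")
  per_side <- function(side_mask, side) {
    keep <- vapply(sl, function(s) sum(s[[side_mask]]) > 0, logical(1))
    if (!any(keep)) stop("no slice has a nonempty ", side, " mask")
    areas <- vapply(sl, function(s) region_area(s[[side_mask]], study$pixel_area),
                    numeric(1))
    st <- lapply(sl[keep], function(s) region_stats(s$image, s[[side_mask]]))
    list(vol = region_volume(areas, study$slice_thickness),
         mu = mean(vapply(st, `[[`, numeric(1), "mu")),
         sigma = mean(vapply(st, `[[`, numeric(1), "sigma")))
  }
  L <- per_side("left_mask", "left")
  R <- per_side("right_mask", "right")
  structure(list(vol_left = L$vol, vol_right = R$vol,
                 mean_left = L$mu, mean_right = R$mu,
                 sd_left = L$sigma, sd_right = R$sigma),
            class = "morph_features")
}

#' @export
print.morph_features <- function(x, ...) {
  cat(sprintf("<morph_features> vol L/R: %.1f/%.1f mm^3, mean L/R: %.2f/%.2f, sd L/R: %.2f/%.2f\n",
              x$vol_left, x$vol_right, x$mean_left, x$mean_right,
              x$sd_left, x$sd_right))
  invisible(x)
}
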