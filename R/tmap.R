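#' Single-subject versus control-group voxel t-map
#'
#' Crawford-Howell single-case t at every voxel:
#' `t = (mean_controls - patient) / (sd_controls * sqrt(1 + 1/n))`,
#' with `df = n - 1` degrees of freedom — the two-sample t-test with one
#' group of size 1. The map is oriented so that larger t means greater
#' gray-matter reduction in the patient. Voxels where the controls have
#' zero variance are set to t = 0 and counted in `n_flagged`.
#'
#' @param patient_gm 3D array, the patient's (smoothed) GM map.
#' @param controls_gm List of >= 3 control arrays of the same shape.
#' @return A `stat_map`: list with `t` (3D array), `df`, `n_controls`,
#'   `n_flagged`, `tail = "reduction"`.
#' @export
#' @examples
#' p <- array(0.4, c(4, 4, 4))
#' ctl <- replicate(5, array(rnorm(64, 0.5, 0.05), c(4, 4, 4)), simplify = FALSE)
#' sm <- single_subject_tmap(p, ctl)
#' sm$df
single_subject_tmap <- function(patient_gm, controls_gm) {
  n <- length(controls_gm)
  if (n < 3) stop("at least 3 controls are required")
  d <- dim(patient_gm)
  ok <- vapply(controls_gm, function(v) identical(dim(v), d), logical(1))
  if (!all(ok)) stop("control volumes must match the patient's shape")

  cs <- Reduce(`+`, controls_gm)
  cs2 <- Reduce(`+`, lapply(controls_gm, function(v) v^2))
  mean_c <- cs / n
  var_c <- (cs2 - n * mean_c^2) / (n - 1)
  var_c[var_c < 0] <- 0           # guard tiny negative rounding
  sd_c <- sqrt(var_c)

  denom <- sd_c * sqrt(1 + 1 / n)
  t <- (mean_c - patient_gm) / denom
  flagged <- denom == 0
  t[flagged] <- 0

  structure(list(t = t, df = n - 1L, n_controls = n,
                 n_flagged = sum(flagged), tail = "reduction"),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s grid, df = %d, t range [%.2f, %.2f]\n",
              paste(dim(x$t), collapse = "x"), x$df, min(x$t), max(x$t)))
  invisible(x)
}
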