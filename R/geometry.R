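#' Voxel/world geometry helpers
#'
#' Volumes carry a 4x4 affine mapping 0-based voxel indices to world
#' coordinates in mm, with the convention that world +x is the subject's
#' right (as in MNI space). All hemisphere logic in the package operates
#' in world space through the affine, never on raw storage indices.
#'
#' @param grid_shape Integer length-3 volume dimensions.
#' @param voxel_size Voxel edge length(s) in mm (scalar or length 3).
#' @return `default_affine()`: a 4x4 matrix placing the world origin at
#'   the grid center.
#' @export
default_affine <- function(grid_shape, voxel_size) {
  voxel_size <- rep_len(voxel_size, 3)
  a <- diag(c(voxel_size, 1))
  a[1:3, 4] <- -voxel_size * (grid_shape - 1) / 2
  a
}

#' @rdname default_affine
#' @param affine 4x4 voxel-to-world matrix.
#' @param ijk Matrix (n x 3) or length-3 vector of 1-based voxel indices.
#' @return `voxel_to_world()`: n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(affine, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  h <- cbind(ijk - 1, 1)          # affine is 0-based
  out <- h %*% t(affine)
  out[, 1:3, drop = FALSE]
}

# world-x coordinate of every voxel, as an array matching the grid
world_x_grid <- function(grid_shape, affine) {
  i <- (seq_len(grid_shape[1]) - 1)
  # x may depend on all three indices for a general affine; the package's
  # volumes use axis-aligned affines so only i contributes beyond a constant
  j <- (seq_len(grid_shape[2]) - 1)
  k <- (seq_len(grid_shape[3]) - 1)
  xi <- affine[1, 1] * i
  xj <- affine[1, 2] * j
  xk <- affine[1, 3] * k
  outer(outer(xi, xj, "+"), xk, "+") + affine[1, 4]
}

# world coordinate arrays for all three axes (axis-aligned affines)
world_coord_grids <- function(grid_shape, affine) {
  lapply(1:3, function(ax) {
    i <- (seq_len(grid_shape[1]) - 1)
    j <- (seq_len(grid_shape[2]) - 1)
    k <- (seq_len(grid_shape[3]) - 1)
    outer(outer(affine[ax, 1] * i, affine[ax, 2] * j, "+"),
          affine[ax, 3] * k, "+") + affine[ax, 4]
  })
}
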