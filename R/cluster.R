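#' Label connected components of a 3D binary map
#'
#' @param mask Logical 3D array.
#' @param connectivity 6 (faces), 18 (faces+edges) or 26
#'   (faces+edges+corners, the default and most inclusive).
#' @return Integer array of component labels (0 = background), with
#'   attribute `n_components`.
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(length(dim(mask)) == 3, connectivity %in% c(6, 18, 26))
  d <- dim(mask)
  v <- which(mask)
  lab <- array(0L, d)
  if (length(v) == 0) {
    attr(lab, "n_components") <- 0L
    return(lab)
  }
  lookup <- integer(prod(d))
  lookup[v] <- seq_along(v)

  offs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  ord <- abs(offs$di) + abs(offs$dj) + abs(offs$dk)
  offs <- offs[ord > 0 & ord <= switch(as.character(connectivity),
                                       "6" = 1, "18" = 2, "26" = 3), ]
  # half the offsets suffice: each undirected edge found once
  offs <- offs[offs$dk > 0 | (offs$dk == 0 & (offs$dj > 0 |
            (offs$dj == 0 & offs$di > 0))), ]

  ijk <- arrayInd(v, d)
  edges <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    ni <- ijk[, 1] + offs$di[r]
    nj <- ijk[, 2] + offs$dj[r]
    nk <- ijk[, 3] + offs$dk[r]
    inb <- ni >= 1 & ni <= d[1] & nj >= 1 & nj <= d[2] & nk >= 1 & nk <= d[3]
    nl <- (nk[inb] - 1L) * d[1] * d[2] + (nj[inb] - 1L) * d[1] + ni[inb]
    nb <- lookup[nl]
    src <- which(inb)[nb > 0]
    edges[[r]] <- rbind(src, nb[nb > 0])
  }
  em <- do.call(cbind, edges)
  g <- igraph::make_graph(edges = as.vector(em), n = length(v), directed = FALSE)
  comp <- igraph::components(g)
  lab[v] <- as.integer(comp$membership)
  attr(lab, "n_components") <- as.integer(comp$no)
  lab
}

#' Threshold a t-map and extract suprathreshold clusters
#'
#' Voxels whose one-tailed p-value (Student t with the map's degrees of
#' freedom) falls below `p_thresh` form a binary map; connected
#' components are labeled and only components with strictly more than
#' `min_cluster_voxels` voxels are retained, sorted by peak t descending.
#'
#' @param stat A `stat_map` from [single_subject_tmap()].
#' @param p_thresh Voxel-level one-tailed p threshold in (0, 1)
#'   (default 0.001; 0.003 is the laxer alternative).
#' @param min_cluster_voxels Cluster-extent threshold; clusters must
#'   exceed this voxel count (default 50).
#' @param affine Optional 4x4 voxel-to-world matrix for peak coordinates.
#' @param connectivity Passed to [label_components()].
#' @return List of `cluster` objects: each has `voxel_ids` (linear
#'   indices), `size`, `peak_voxel` (linear index), `peak_ijk`, `peak_t`,
#'   and `peak_world` (mm, if `affine` given). An empty list is a valid
#'   result.
#' @export
threshold_and_cluster <- function(stat, p_thresh = 0.001,
                                  min_cluster_voxels = 50,
                                  affine = NULL, connectivity = 26) {
  stopifnot(inherits(stat, "stat_map"), p_thresh > 0, p_thresh < 1,
            min_cluster_voxels >= 1)
  t_crit <- qt(1 - p_thresh, df = stat$df)
  supra <- stat$t > t_crit
  lab <- label_components(supra, connectivity)
  n <- attr(lab, "n_components")
  if (n == 0) return(list())

  out <- list()
  for (cl in seq_len(n)) {
    ids <- which(lab == cl)
    if (length(ids) <= min_cluster_voxels) next
    pk <- ids[which.max(stat$t[ids])]
    ijk <- arrayInd(pk, dim(stat$t))[1, ]
    cluster <- structure(list(
      voxel_ids = ids, size = length(ids), peak_voxel = pk,
      peak_ijk = ijk, peak_t = stat$t[pk],
      peak_world = if (!is.null(affine)) as.numeric(voxel_to_world(affine, ijk)) else NULL
    ), class = "tle_cluster")
    out[[length(out) + 1L]] <- cluster
  }
  out[order(-vapply(out, `[[`, numeric(1), "peak_t"))]
}

#' @export
print.tle_cluster <- function(x, ...) {
  cat(sprintf("<cluster> %d voxels, peak t = %.3f at (%s)%s\n",
              x$size, x$peak_t, paste(x$peak_ijk, collapse = ", "),
              if (!is.null(x$peak_world))
                sprintf(" = %s mm", paste(round(x$peak_world, 1), collapse = ", "))
              else ""))
  invisible(x)
}

#' Hemisphere of a world x-coordinate
#'
#' World +x is the subject's right (MNI convention): `x > 0` is RIGHT,
#' `x < 0` LEFT, `x == 0` MIDLINE (resolution deferred to the caller).
#'
#' @param x_mm World x-coordinate(s) in mm.
#' @return Character vector of `"LEFT"`, `"RIGHT"`, `"MIDLINE"`.
#' @export
#' @examples
#' hemisphere_from_world(c(30, -38, 0))
hemisphere_from_world <- function(x_mm) {
  stopifnot(all(is.finite(x_mm)))
  ifelse(x_mm > 0, "RIGHT", ifelse(x_mm < 0, "LEFT", "MIDLINE"))
}
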