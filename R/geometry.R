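#' Region centroids, areas and centroid distances
#'
#' Each triangle is assigned to one region by majority vote of its three
#' vertex labels (tie broken toward the lowest region id), so region areas
#' partition the total mesh area exactly. Region centroids are the
#' area-weighted means of the barycenters of the assigned triangles, and
#' region-pair distances are straight-line Euclidean distances between
#' centroids in 3-space -- the same proxy for travelled distance used when
#' correlating activation times with distance (geodesics are deliberately
#' not computed).
#'
#' @param mesh a [surface_mesh()].
#' @param atlas a [region_atlas()] on the same mesh.
#' @return an object of class `region_geometry`: list with `centroid`
#'   (k x 3 matrix, mm), `area` (named vector, mm^2), `centroid_distance`
#'   (k x k symmetric matrix, mm), `region_ids`.
#' @export
region_geometry <- function(mesh, atlas) {
  validate_atlas(atlas, mesh)
  tr <- mesh$triangles
  lab <- atlas$labels
  l1 <- lab[tr[, 1L]]; l2 <- lab[tr[, 2L]]; l3 <- lab[tr[, 3L]]
  # majority vertex label; full tie (all distinct) -> lowest region id
  tlab <- ifelse(l2 == l3, l2, l1)
  tie <- l1 != l2 & l2 != l3 & l1 != l3
  tlab[tie] <- pmin(l1, l2, l3)[tie]
  areas <- triangle_areas(mesh)
  bary <- (mesh$vertices[tr[, 1L], , drop = FALSE] +
           mesh$vertices[tr[, 2L], , drop = FALSE] +
           mesh$vertices[tr[, 3L], , drop = FALSE]) / 3
  ids <- atlas$region_ids
  k <- length(ids)
  area <- stats::setNames(numeric(k), ids)
  cen <- matrix(NA_real_, k, 3, dimnames = list(ids, c("x", "y", "z")))
  for (r in seq_len(k)) {
    sel <- tlab == ids[r]
    if (!any(sel))
      stop("region ", ids[r], " owns no triangle (all its triangles ",
           "were claimed by neighbouring majorities)")
    a <- areas[sel]
    area[r] <- sum(a)
    cen[r, ] <- colSums(bary[sel, , drop = FALSE] * a) / sum(a)
  }
  d <- as.matrix(stats::dist(cen))
  dimnames(d) <- list(ids, ids)
  structure(list(centroid = cen, area = area, centroid_distance = d,
                 region_ids = ids),
            class = "region_geometry")
}

#' @export
print.region_geometry <- function(x, ...) {
  cat(sprintf("region_geometry: %d regions, total area %.6g mm^2\n",
              length(x$region_ids), sum(x$area)))
  invisible(x)
}
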