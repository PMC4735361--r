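#' Protocol ordering of regions
#'
#' Regions are grouped by lobe (in a fixed, configurable lobe order) and,
#' within each lobe, chained by a deterministic greedy nearest-centroid
#' walk starting from the region closest to the lobe centroid; ties break
#' toward the lower region id. This keeps spatially adjacent regions
#' adjacent in the activation matrices. Source-excluded regions are left
#' out.
#'
#' @param atlas a [region_atlas()].
#' @param rgeom the [region_geometry()] of the same mesh/atlas.
#' @param lobe_order character vector of lobe names; defaults to first
#'   appearance order among non-excluded regions.
#' @return integer vector: non-excluded region ids in display order.
#' @export
order_regions <- function(atlas, rgeom, lobe_order = NULL) {
  incl <- included_regions(atlas)
  lob <- atlas$lobes[match(incl, atlas$region_ids)]
  if (is.null(lobe_order)) lobe_order <- unique(lob)
  if (!all(lob %in% lobe_order))
    stop("lobe_order is missing lobe(s): ",
         paste(setdiff(lob, lobe_order), collapse = ", "))
  out <- integer(0)
  for (L in lobe_order) {
    ids <- incl[lob == L]
    if (length(ids) == 0L) next
    cen <- rgeom$centroid[match(ids, rgeom$region_ids), , drop = FALSE]
    ar <- rgeom$area[match(ids, rgeom$region_ids)]
    lc <- colSums(cen * ar) / sum(ar)          # area-weighted lobe centroid
    d0 <- sqrt(colSums((t(cen) - lc)^2))
    chain <- ids[order(d0, ids)[1L]]
    left <- setdiff(ids, chain)
    while (length(left) > 0L) {
      last <- chain[length(chain)]
      dd <- sqrt(colSums((t(cen[match(left, ids), , drop = FALSE]) -
                            cen[match(last, ids), ])^2))
      nxt <- left[order(dd, left)[1L]]
      chain <- c(chain, nxt)
      left <- setdiff(left, nxt)
    }
    out <- c(out, chain)
  }
  out
}

check_square_zero_diag <- function(T_min, what = "T_min") {
  if (!is.matrix(T_min) || nrow(T_min) != ncol(T_min))
    stop(what, " must be a square matrix")
  if (any(abs(diag(T_min)) > 0))
    stop(what, " must have a zero diagonal")
  invisible(TRUE)
}

#' Back-and-forth asymmetry matrix
#'
#' `Asym = T_min - t(T_min)`: entry (i, j) is the difference in arrival
#' time between a wave travelling i -> j and one travelling j -> i.
#' Exactly skew-symmetric; it vanishes when propagation is symmetric.
#'
#' @param T_min square minimum-activation-time matrix (s), zero diagonal.
#' @return skew-symmetric matrix (s).
#' @export
asymmetry_matrix <- function(T_min) {
  check_square_zero_diag(T_min)
  T_min - t(T_min)
}

#' Normalised asymmetry matrix
#'
#' Divides each off-diagonal asymmetry entry by the corresponding minimum
#' activation time, making the measure dimensionless and scale-invariant;
#' the (zero) diagonal passes through unchanged.
#'
#' @param Asym output of [asymmetry_matrix()].
#' @param T_min the matrix it was computed from.
#' @return dimensionless matrix.
#' @export
normalized_asymmetry <- function(Asym, T_min) {
  check_square_zero_diag(T_min)
  if (!all(dim(Asym) == dim(T_min))) stop("shape mismatch")
  off <- !diag(nrow(T_min))
  bad <- which(off & T_min <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("cannot normalise: T_min[%d, %d] = %g is not positive",
                 bad[1, 1], bad[1, 2], T_min[bad[1, 1], bad[1, 2]]))
  out <- Asym
  out[off] <- Asym[off] / T_min[off]
  out
}

#' Global asymmetry index
#'
#' Column means of the normalised asymmetry matrix (over off-diagonal
#' entries by default; the diagonal is structurally zero and including it
#' only dilutes every mean by the same factor) and their signs. A
#' positive sign marks a region from which waves leave faster than they
#' arrive (a "source"/facilitator); negative marks a "sink".
#'
#' @param AsymNorm output of [normalized_asymmetry()].
#' @param include_diagonal include the structural zeros in the means.
#' @return list with `col_means` and `signs` (-1, 0, +1 per region).
#' @export
global_asymmetry_index <- function(AsymNorm, include_diagonal = FALSE) {
  k <- nrow(AsymNorm)
  cm <- if (include_diagonal) colMeans(AsymNorm)
        else (colSums(AsymNorm) - diag(AsymNorm)) / (k - 1)
  list(col_means = cm, signs = sign(cm))
}

#' Combine two skew-symmetric asymmetry matrices into one display matrix
#'
#' Lower triangle takes |left|, upper triangle |right|, zero diagonal --
#' no information is lost because each input is skew-symmetric. The two
#' matrices must describe the same regions in the same order.
#'
#' @param AsymLeft,AsymRight skew-symmetric matrices of equal shape.
#' @return non-negative matrix `G`.
#' @export
combine_hemispheres <- function(AsymLeft, AsymRight) {
  if (!all(dim(AsymLeft) == dim(AsymRight))) stop("shape mismatch")
  for (m in list(AsymLeft, AsymRight))
    if (max(abs(m + t(m))) > 1e-9 * max(1, max(abs(m))))
      stop("inputs must be skew-symmetric")
  G <- matrix(0, nrow(AsymLeft), ncol(AsymLeft),
              dimnames = dimnames(AsymLeft))
  G[lower.tri(G)] <- abs(AsymLeft[lower.tri(AsymLeft)])
  G[upper.tri(G)] <- abs(AsymRight[upper.tri(AsymRight)])
  G
}

#' Residence matrix and retention index
#'
#' `D = T_max - T_min` holds the time the wavefront needs to sweep each
#' arrival region (column) from each source (row); the retention index of
#' region j is the column sum of D, an initial-condition-independent
#' measure of how long waves stay in the region.
#'
#' @param T_min,T_max activation-time matrices (s), `T_max >= T_min`.
#' @return list with `D` (s) and `retention` (named column sums, s).
#' @export
residence_and_retention <- function(T_min, T_max) {
  if (!all(dim(T_min) == dim(T_max))) stop("shape mismatch")
  bad <- which(T_max - T_min < -1e-9, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("T_max < T_min at entry [%d, %d]", bad[1, 1], bad[1, 2]))
  D <- pmax(T_max - T_min, 0)
  list(D = D, retention = colSums(D))
}

#' Pearson product-moment correlation
#'
#' Two-pass evaluation of the textbook formula
#' `r = sum((x - xbar)(y - ybar)) / sqrt(sum((x - xbar)^2) sum((y - ybar)^2))`.
#'
#' @param x,y equal-length numeric vectors (n >= 3), neither constant.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  dx <- x - mean(x); dy <- y - mean(y)
  sx <- sum(dx^2); sy <- sum(dy^2)
  if (sx == 0 || sy == 0) stop("correlation undefined for constant input")
  sum(dx * dy) / sqrt(sx * sy)
}

#' Distance-time pair dataset
#'
#' All ordered off-diagonal (start, arrival) region pairs with the
#' Euclidean centroid distance as x and the activation time as y --
#' `k * (k - 1)` rows for k regions (1122 for the 34-region atlas).
#'
#' @param mat square activation-time matrix with region-name dimnames, in
#'   protocol order.
#' @param rgeom the [region_geometry()].
#' @param region_order integer region ids giving the row/column order of
#'   `mat` (as in `activation_matrices$region_order`).
#' @return data.frame with columns `start`, `arrival`, `distance_mm`,
#'   `time_s`.
#' @export
pair_dataset <- function(mat, rgeom, region_order) {
  k <- nrow(mat)
  if (length(region_order) != k) stop("region_order length mismatch")
  dmat <- rgeom$centroid_distance[as.character(region_order),
                                  as.character(region_order)]
  idx <- which(!diag(k), arr.ind = TRUE)   # column-major off-diagonal order
  data.frame(start = rownames(mat)[idx[, 1]],
             arrival = colnames(mat)[idx[, 2]],
             distance_mm = dmat[idx],
             time_s = mat[idx],
             stringsAsFactors = FALSE)
}

#' All quantities of interest from one protocol run
#'
#' Convenience wrapper collecting the asymmetry matrix, its normalised
#' form, the per-region column means and global asymmetry signs, the
#' residence matrix and retention index, the distance-time pair datasets
#' for both matrices and their Pearson correlations, plus the
#' retention-vs-area dataset and correlation.
#'
#' @param matrices an `activation_matrices` from [run_protocol()].
#' @param rgeom the [region_geometry()] of the same mesh/atlas.
#' @return list of class `qoi_bundle`.
#' @export
qoi_bundle <- function(matrices, rgeom) {
  Asym <- asymmetry_matrix(matrices$T_min)
  AsymNorm <- normalized_asymmetry(Asym, matrices$T_min)
  gai <- global_asymmetry_index(AsymNorm)
  rr <- residence_and_retention(matrices$T_min, matrices$T_max)
  pd_min <- pair_dataset(matrices$T_min, rgeom, matrices$region_order)
  pd_max <- pair_dataset(matrices$T_max, rgeom, matrices$region_order)
  areas <- rgeom$area[as.character(matrices$region_order)]
  structure(list(
    Asym = Asym, AsymNorm = AsymNorm,
    col_means = gai$col_means, asym_index = gai$signs,
    D = rr$D, retention = rr$retention,
    pair_min = pd_min, pair_max = pd_max,
    pearson_min = pearson(pd_min$distance_mm, pd_min$time_s),
    pearson_max = pearson(pd_max$distance_mm, pd_max$time_s),
    area = stats::setNames(areas, matrices$region_names),
    pearson_area_retention = pearson(areas, rr$retention)),
    class = "qoi_bundle")
}

#' @export
print.qoi_bundle <- function(x, ...) {
  cat(sprintf(paste0("qoi_bundle: %d regions\n",
                     "  r(distance, T_min) = %.4f   r(distance, T_max) = %.4f\n",
                     "  r(area, retention) = %.4f   max |asymmetry| = %.3g s\n"),
              nrow(x$Asym), x$pearson_min, x$pearson_max,
              x$pearson_area_retention, max(abs(x$Asym))))
  invisible(x)
}

#' Write a pair dataset to CSV
#' @param pd data.frame from [pair_dataset()].
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_pair_dataset <- function(pd, path) {
  write_lines_lf(c("start,arrival,distance_mm,time_s",
                   sprintf("%s,%s,%.17g,%.17g", pd$start, pd$arrival,
                           pd$distance_mm, pd$time_s)), path)
  invisible(path)
}
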