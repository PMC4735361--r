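#' Construct a triangulated surface mesh
#'
#' A `surface_mesh` is the spatial domain of the simulation: a triangulated
#' surface in 3-space with coordinates in millimetres. Triangle vertex
#' indices are 1-based inside R; exchange formats (OFF, PLY, atlas CSV) use
#' 0-based indices and are converted at the file boundary.
#'
#' @param vertices numeric matrix, one row per vertex, 3 columns (x, y, z) in mm.
#' @param triangles integer matrix, one row per triangle, 3 columns of
#'   1-based vertex indices.
#' @param validate validate indices, degeneracy and (if `closed = TRUE`)
#'   manifold-closedness; set `FALSE` only to inspect a broken file.
#' @param closed require every edge to be shared by exactly two triangles
#'   with consistent orientation (needed for simulation, where the closed
#'   surface makes boundary conditions unnecessary).
#' @return an object of class `surface_mesh` with elements `vertices`
#'   (n x 3 matrix) and `triangles` (m x 3 integer matrix).
#' @export
surface_mesh <- function(vertices, triangles, validate = TRUE, closed = FALSE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop("'vertices' must have 3 columns (x, y, z)")
  if (ncol(triangles) != 3L) stop("'triangles' must have 3 columns")
  dimnames(vertices) <- NULL
  dimnames(triangles) <- NULL
  mesh <- structure(list(vertices = vertices, triangles = triangles),
                    class = "surface_mesh")
  if (validate) validate_mesh(mesh, closed = closed)
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles, total area %.6g mm^2\n",
              n_vertices(x), n_triangles(x), sum(triangle_areas(x))))
  invisible(x)
}

#' Number of vertices / triangles of a mesh
#' @param mesh a `surface_mesh`.
#' @return integer count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_triangles <- function(mesh) nrow(mesh$triangles)

#' Per-triangle areas (mm^2)
#' @param mesh a `surface_mesh`.
#' @return numeric vector of length `n_triangles(mesh)`.
#' @export
triangle_areas <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 2L], , drop = FALSE] - v[tr[, 1L], , drop = FALSE]
  b <- v[tr[, 3L], , drop = FALSE] - v[tr[, 1L], , drop = FALSE]
  cx <- a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L]
  cy <- a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L]
  cz <- a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total surface area (mm^2)
#' @param mesh a `surface_mesh`.
#' @export
mesh_area <- function(mesh) sum(triangle_areas(mesh))

# Edge table: one row per directed half-edge (lo, hi, direction)
directed_edges <- function(triangles) {
  e <- rbind(triangles[, c(1L, 2L)], triangles[, c(2L, 3L)], triangles[, c(3L, 1L)])
  e
}

#' Validate a surface mesh
#'
#' Checks vertex-index bounds, strictly positive triangle areas (degeneracy
#' threshold 1e-12 mm^2) and, when `closed = TRUE`, that every undirected
#' edge is shared by exactly two triangles which traverse it in opposite
#' directions (closed, consistently oriented 2-manifold).
#'
#' @param mesh a `surface_mesh`.
#' @param closed also require manifold-closedness and consistent orientation.
#' @return invisibly `TRUE`; otherwise an error naming the offending
#'   triangle or edge.
#' @export
validate_mesh <- function(mesh, closed = FALSE) {
  tr <- mesh$triangles
  nv <- n_vertices(mesh)
  bad <- which(tr < 1L | tr > nv, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("triangle %d references vertex index %d outside [1, %d]",
                 bad[1L, 1L], tr[bad[1L, 1L], bad[1L, 2L]], nv))
  dup <- which(tr[, 1L] == tr[, 2L] | tr[, 2L] == tr[, 3L] | tr[, 1L] == tr[, 3L])
  if (length(dup) > 0L)
    stop(sprintf("triangle %d has a repeated vertex index", dup[1L]))
  ar <- triangle_areas(mesh)
  if (any(ar <= 1e-12))
    stop(sprintf("triangle %d is degenerate (area %.3g mm^2 <= 1e-12)",
                 which(ar <= 1e-12)[1L], min(ar)))
  if (closed && !is_closed_manifold(mesh))
    stop("mesh is not a closed, consistently oriented 2-manifold")
  invisible(TRUE)
}

#' Is the mesh a closed, consistently oriented 2-manifold?
#'
#' TRUE when every undirected edge is shared by exactly two triangles and
#' the two traverse it in opposite directions.
#'
#' @param mesh a `surface_mesh`.
#' @return logical scalar.
#' @export
is_closed_manifold <- function(mesh) {
  de <- directed_edges(mesh$triangles)
  key_dir <- paste(de[, 1L], de[, 2L])
  key_und <- paste(pmin(de[, 1L], de[, 2L]), pmax(de[, 1L], de[, 2L]))
  cnt <- table(key_und)
  if (any(cnt != 2L)) return(FALSE)
  # opposite traversal <=> each directed edge appears exactly once
  !anyDuplicated(key_dir) > 0L
}

#' Construct a per-vertex region atlas
#'
#' Assigns every mesh vertex to exactly one region; regions carry display
#' names and a lobe membership (the coarser anatomical grouping), and a set
#' of regions may be excluded as wave sources (e.g. the corpus callosum,
#' which is never initially depolarised and never appears as a row or
#' column of activation matrices).
#'
#' @param labels integer vector, one region id per vertex.
#' @param region_names named character vector mapping region id to name;
#'   defaults to `"region_<id>"`.
#' @param lobes named character vector mapping region id to lobe name.
#' @param source_excluded integer vector of region ids excluded as sources.
#' @return an object of class `region_atlas`.
#' @export
region_atlas <- function(labels, region_names = NULL, lobes, source_excluded = integer(0)) {
  labels <- as.integer(labels)
  ids <- sort(unique(labels))
  if (is.null(region_names)) {
    region_names <- stats::setNames(paste0("region_", ids), ids)
  }
  if (!all(as.character(ids) %in% names(region_names)))
    stop("region_names missing an entry for region ",
         ids[!as.character(ids) %in% names(region_names)][1L])
  if (!all(as.character(ids) %in% names(lobes)))
    stop("lobe assignment missing for region ",
         ids[!as.character(ids) %in% names(lobes)][1L])
  source_excluded <- as.integer(source_excluded)
  if (!all(source_excluded %in% ids))
    stop("source_excluded region ", setdiff(source_excluded, ids)[1L],
         " has no vertices")
  structure(list(labels = labels,
                 region_ids = ids,
                 region_names = region_names[as.character(ids)],
                 lobes = lobes[as.character(ids)],
                 source_excluded = source_excluded),
            class = "region_atlas")
}

#' @export
print.region_atlas <- function(x, ...) {
  cat(sprintf("region_atlas: %d vertices, %d regions, %d lobes, %d source-excluded\n",
              length(x$labels), length(x$region_ids),
              length(unique(x$lobes)), length(x$source_excluded)))
  invisible(x)
}

#' Region ids usable as wave sources / matrix rows
#' @param atlas a `region_atlas`.
#' @return integer vector of non-excluded region ids, ascending.
#' @export
included_regions <- function(atlas) setdiff(atlas$region_ids, atlas$source_excluded)

#' Check atlas consistency against a mesh
#' @param atlas a `region_atlas`.
#' @param mesh a `surface_mesh`.
#' @return invisibly `TRUE` or an error.
#' @export
validate_atlas <- function(atlas, mesh) {
  if (length(atlas$labels) != n_vertices(mesh))
    stop(sprintf("atlas has %d labels but mesh has %d vertices",
                 length(atlas$labels), n_vertices(mesh)))
  invisible(TRUE)
}
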