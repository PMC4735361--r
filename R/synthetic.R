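#' Flat rectangular sheet mesh
#'
#' Regular nx-by-ny vertex grid on `[0, lx] x [0, ly]` in the z = 0 plane,
#' each grid cell split into two triangles. The sheet is an open mesh
#' (it has a boundary); under the surface FEM discretisation the boundary
#' behaves as zero-flux, which is what the plane-wave speed and collision
#' fixtures rely on.
#'
#' @param nx,ny number of vertices per side (>= 2).
#' @param lx,ly side lengths (mm).
#' @return a [surface_mesh()].
#' @export
make_sheet <- function(nx, ny, lx, ly) {
  if (nx < 2L || ny < 2L) stop("nx and ny must be >= 2")
  if (lx <= 0 || ly <= 0) stop("lx and ly must be positive")
  xs <- seq(0, lx, length.out = nx)
  ys <- seq(0, ly, length.out = ny)
  v <- cbind(rep(xs, times = ny), rep(ys, each = nx), 0)
  idx <- function(i, j) (j - 1L) * nx + i       # i along x, j along y
  i <- rep(seq_len(nx - 1L), times = ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  a <- idx(i, j); b <- idx(i + 1L, j); c <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
  tr <- rbind(cbind(a, b, c), cbind(a, c, d))
  surface_mesh(v, tr)
}

#' Icosphere mesh
#'
#' Icosahedron subdivided `subdivisions` times (each level splits every
#' triangle in four), vertices projected to the sphere of the given
#' radius. The result is a closed, consistently oriented manifold with
#' `20 * 4^subdivisions` faces; it is the stand-in for a smooth cortex,
#' on which isotropic propagation must be (near-)symmetric between
#' regions.
#'
#' @param subdivisions non-negative integer.
#' @param radius sphere radius (mm).
#' @return a [surface_mesh()].
#' @export
make_icosphere <- function(subdivisions = 3L, radius = 1) {
  if (subdivisions < 0L) stop("subdivisions must be >= 0")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  tr <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    edges <- unique(rbind(cbind(pmin(tr[, 1], tr[, 2]), pmax(tr[, 1], tr[, 2])),
                          cbind(pmin(tr[, 2], tr[, 3]), pmax(tr[, 2], tr[, 3])),
                          cbind(pmin(tr[, 1], tr[, 3]), pmax(tr[, 1], tr[, 3]))))
    mid <- (v[edges[, 1], , drop = FALSE] + v[edges[, 2], , drop = FALSE]) / 2
    key <- paste(edges[, 1], edges[, 2])
    midx <- stats::setNames(nv + seq_len(nrow(edges)), key)
    v <- rbind(v, mid)
    ek <- function(a, b) midx[paste(pmin(a, b), pmax(a, b))]
    m12 <- ek(tr[, 1], tr[, 2]); m23 <- ek(tr[, 2], tr[, 3]); m13 <- ek(tr[, 1], tr[, 3])
    tr <- rbind(cbind(tr[, 1], m12, m13),
                cbind(tr[, 2], m23, m12),
                cbind(tr[, 3], m13, m23),
                cbind(m12, m23, m13))
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  surface_mesh(v, tr, closed = TRUE)
}

#' Planar duct with a bend
#'
#' Two rectangular legs of the given width and length joined by a circular
#' sector that pivots around the inner corner; `bend_angle` is the angle
#' between the axes of the two legs (180 degrees gives a straight duct).
#' Sharp bends (small angles) are the classical geometry on which
#' excitation waves fail to turn the corner when the duct width is below
#' the critical pivot radius of the medium, while gentle bends transmit.
#'
#' @param width duct width (mm).
#' @param leg_length length of each straight leg (mm).
#' @param bend_angle angle between leg axes in degrees, in (0, 180].
#' @param h target edge length (mm).
#' @return a [surface_mesh()] (open, z = 0 plane).
#' @export
make_duct <- function(width, leg_length, bend_angle, h = width / 4) {
  if (width <= 0 || leg_length <= 0) stop("width and leg_length must be positive")
  if (bend_angle <= 0 || bend_angle > 180) stop("bend_angle must be in (0, 180]")
  kink <- (180 - bend_angle) * pi / 180   # turn of the axis at the joint
  nxa <- max(2L, ceiling(leg_length / h) + 1L)
  nw  <- max(2L, ceiling(width / h) + 1L)
  rr  <- seq(0, width, length.out = nw)   # radial stations from inner corner

  grid_patch <- function(origin, ex, ey, lx, ly, nx, ny) {
    s <- seq(0, lx, length.out = nx); t <- seq(0, ly, length.out = ny)
    V <- matrix(0, nx * ny, 3)
    for (j in seq_len(ny)) for (i in seq_len(nx))
      V[(j - 1L) * nx + i, ] <- origin + s[i] * ex + t[j] * ey
    idx <- function(i, j) (j - 1L) * nx + i
    i <- rep(seq_len(nx - 1L), times = ny - 1L)
    j <- rep(seq_len(ny - 1L), each = nx - 1L)
    a <- idx(i, j); b <- idx(i + 1L, j); c <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
    list(v = V, tr = rbind(cbind(a, b, c), cbind(a, c, d)))
  }

  rot <- function(u, a) c(cos(a) * u[1] - sin(a) * u[2],
                          sin(a) * u[1] + cos(a) * u[2], 0)
  # leg A along +x, width along +y; inner corner (pivot) at (L, width)
  pA <- grid_patch(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), leg_length, width, nxa, nw)
  pieces <- list(pA)
  pivot <- c(leg_length, width, 0)
  u0 <- c(0, -1, 0)                        # end cross-section direction (inner -> outer)
  if (kink > 1e-12) {
    na <- max(2L, ceiling(kink * width / h) + 1L)
    alphas <- seq(0, kink, length.out = na)
    nvtx <- na * (nw - 1L) + 1L
    V <- matrix(0, nvtx, 3)
    V[1L, ] <- pivot
    id <- function(ia, jr) 1L + (ia - 1L) * (nw - 1L) + jr  # jr in 1..nw-1 (r > 0)
    for (ia in seq_len(na)) {
      u <- rot(u0, alphas[ia])            # counterclockwise: pivot is the inner wall
      for (jr in seq_len(nw - 1L)) V[id(ia, jr), ] <- pivot + rr[jr + 1L] * u
    }
    tr <- NULL
    for (ia in seq_len(na - 1L)) {
      tr <- rbind(tr, cbind(1L, id(ia + 1L, 1L), id(ia, 1L)))
      for (jr in seq_len(nw - 2L))
        tr <- rbind(tr,
                    cbind(id(ia, jr), id(ia + 1L, jr), id(ia + 1L, jr + 1L)),
                    cbind(id(ia, jr), id(ia + 1L, jr + 1L), id(ia, jr + 1L)))
    }
    pieces <- c(pieces, list(list(v = V, tr = tr)))
    uend <- rot(u0, kink)
    d2 <- rot(c(1, 0, 0), kink)
    pB <- grid_patch(pivot + width * uend, d2, -uend, leg_length, width, nxa, nw)
    pieces <- c(pieces, list(pB))
  } else {
    pB <- grid_patch(c(leg_length, 0, 0), c(1, 0, 0), c(0, 1, 0),
                     leg_length, width, nxa, nw)
    pieces <- c(pieces, list(pB))
  }
  # reject parameter combinations where the far leg folds back onto the first
  inside_legA <- pB$v[, 1] > h / 4 & pB$v[, 1] < leg_length - h / 4 &
    pB$v[, 2] > h / 4 & pB$v[, 2] < width - h / 4
  if (kink > 1e-12 && any(inside_legA))
    stop("self-intersecting duct: legs overlap for these parameters")
  merged <- merge_patches(pieces)
  m <- surface_mesh(merged$v, merged$tr)
  fix_planar_orientation(m)
}

# merge triangle patches, welding vertices that coincide to 1e-9 mm
merge_patches <- function(pieces) {
  V <- do.call(rbind, lapply(pieces, `[[`, "v"))
  off <- cumsum(c(0L, vapply(pieces, function(p) nrow(p$v), integer(1))))
  TR <- do.call(rbind, lapply(seq_along(pieces),
                              function(k) pieces[[k]]$tr + off[k]))
  key <- paste(round(V[, 1] / 1e-9) * 1e-9,
               round(V[, 2] / 1e-9) * 1e-9,
               round(V[, 3] / 1e-9) * 1e-9)
  first <- !duplicated(key)
  newid <- match(key, key[first])
  list(v = V[first, , drop = FALSE],
       tr = matrix(newid[TR], ncol = 3L))
}

# make every triangle of a z-plane mesh counterclockwise (+z normal)
fix_planar_orientation <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 2], 1:2, drop = FALSE] - v[tr[, 1], 1:2, drop = FALSE]
  b <- v[tr[, 3], 1:2, drop = FALSE] - v[tr[, 1], 1:2, drop = FALSE]
  cw <- (a[, 1] * b[, 2] - a[, 2] * b[, 1]) < 0
  tr[cw, c(2, 3)] <- tr[cw, c(3, 2)]
  surface_mesh(v, tr)
}

#' Six-region cube-face atlas for an icosphere
#'
#' Labels every vertex by its dominant coordinate axis and sign (the
#' projection of the cube's six faces onto the sphere), grouping the six
#' regions into three synthetic "lobes" by axis. Ties are broken by the
#' fixed priority x > y > z, positive > negative. On a centred icosphere
#' the six regions have equal area up to the discreteness of the
#' triangulation, which makes this the reference fixture for propagation
#' symmetry.
#'
#' @param mesh an icosphere (any mesh centred on the origin works).
#' @return a [region_atlas()] with regions `+x, -x, +y, -y, +z, -z`.
#' @export
make_face_atlas <- function(mesh) {
  v <- mesh$vertices
  ax <- max.col(abs(v), ties.method = "first")
  coord <- v[cbind(seq_len(nrow(v)), ax)]
  pos <- coord >= 0
  lab <- (ax - 1L) * 2L + ifelse(pos, 1L, 2L)
  nm <- c("+x", "-x", "+y", "-y", "+z", "-z")
  lb <- c("lobe_x", "lobe_x", "lobe_y", "lobe_y", "lobe_z", "lobe_z")
  ids <- sort(unique(lab))
  region_atlas(lab,
               region_names = stats::setNames(nm, 1:6)[as.character(ids)],
               lobes = stats::setNames(lb, 1:6)[as.character(ids)])
}

#' Deterministic k-region nearest-seed atlas
#'
#' Partitions a closed origin-centred mesh into `k` regions by assigning
#' each vertex to the nearest of `k` Fibonacci-lattice directions on the
#' sphere; empty regions claim their closest vertex. This is a synthetic
#' stand-in for an anatomical parcellation (e.g. a 34-region atlas) on a
#' geometry where none exists; lobes are assigned by the dominant-axis rule
#' applied to each seed direction, giving up to six synthetic lobes.
#'
#' @param mesh a closed, origin-centred [surface_mesh()].
#' @param k number of regions (>= 2).
#' @return a [region_atlas()].
#' @export
make_seed_atlas <- function(mesh, k) {
  if (k < 2L) stop("k must be >= 2")
  if (k > n_vertices(mesh)) stop("k exceeds the number of vertices")
  i <- seq_len(k) - 0.5
  ga <- pi * (3 - sqrt(5))
  z <- 1 - 2 * i / k
  r <- sqrt(pmax(0, 1 - z^2))
  seeds <- cbind(r * cos(ga * i), r * sin(ga * i), z)
  dirs <- mesh$vertices / sqrt(rowSums(mesh$vertices^2))
  sim <- dirs %*% t(seeds)
  lab <- max.col(sim, ties.method = "first")
  for (id in seq_len(k)) {           # repair empty regions deterministically
    if (!any(lab == id)) {
      tab <- tabulate(lab, nbins = k)
      cand <- which(tab[lab] >= 2L)
      pick <- cand[which.max(sim[cand, id])]
      lab[pick] <- id
    }
  }
  ax <- max.col(abs(seeds), ties.method = "first")
  sgn <- ifelse(seeds[cbind(seq_len(k), ax)] >= 0, "+", "-")
  lobes <- paste0("lobe_", sgn, c("x", "y", "z")[ax])
  region_atlas(lab,
               region_names = stats::setNames(sprintf("seed_%02d", 1:k), 1:k),
               lobes = stats::setNames(lobes, 1:k))
}

#' Atlas of equal-width strips along a coordinate axis
#'
#' Splits a sheet (or any mesh) into `n_strips` regions by binning one
#' coordinate of each vertex; used for plane-wave fixtures where the first
#' strip is the stimulated source and later strips are measurement
#' stations. All strips share one synthetic lobe.
#'
#' @param mesh a [surface_mesh()].
#' @param n_strips number of regions (>= 2).
#' @param axis coordinate to bin (1 = x, 2 = y, 3 = z).
#' @return a [region_atlas()].
#' @export
make_strip_atlas <- function(mesh, n_strips, axis = 1L) {
  x <- mesh$vertices[, axis]
  w <- (max(x) - min(x)) / n_strips
  lab <- pmin(n_strips - 1L, floor((x - min(x)) / w)) + 1L
  region_atlas(lab,
               region_names = stats::setNames(sprintf("strip_%02d", 1:n_strips), 1:n_strips),
               lobes = stats::setNames(rep("sheet", n_strips), 1:n_strips))
}
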