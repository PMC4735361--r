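#' P1 mass matrix on a triangulated surface
#'
#' Consistent mode sums the exact element integrals of products of linear
#' basis functions, `(area/12) * [[2,1,1],[1,2,1],[1,1,2]]` per triangle;
#' lumped mode places the row sums on the diagonal. Entries have units
#' mm^2 and the grand sum equals the total surface area (partition of
#' unity).
#'
#' @param mesh a [surface_mesh()].
#' @param mass_mode `"consistent"` (default) or `"lumped"`.
#' @return sparse symmetric `dgCMatrix`, n_vertices x n_vertices.
#' @export
assemble_mass <- function(mesh, mass_mode = c("consistent", "lumped")) {
  mass_mode <- match.arg(mass_mode)
  tr <- mesh$triangles
  ar <- triangle_areas(mesh)
  if (any(ar <= 1e-12))
    stop("degenerate triangle ", which(ar <= 1e-12)[1L], " (area <= 1e-12 mm^2)")
  n <- n_vertices(mesh)
  if (mass_mode == "lumped") {
    # row sums of the consistent matrix: area/3 to each corner
    d <- numeric(n)
    for (c in 1:3) {
      acc <- tapply(ar / 3, tr[, c], sum)
      d[as.integer(names(acc))] <- d[as.integer(names(acc))] + acc
    }
    return(Matrix::Diagonal(n, d))
  }
  ii <- c(tr[, 1], tr[, 2], tr[, 3], tr[, 1], tr[, 2], tr[, 1], tr[, 2], tr[, 3], tr[, 3])
  jj <- c(tr[, 1], tr[, 2], tr[, 3], tr[, 2], tr[, 1], tr[, 3], tr[, 3], tr[, 1], tr[, 2])
  xx <- c(rep(ar / 6, 3), rep(ar / 12, 6))
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

#' Laplace-Beltrami P1 stiffness matrix (cotangent formula)
#'
#' Assembles the intrinsic surface stiffness triangle by triangle: every
#' triangle contributes the classical cotangent weights `cot(angle)/2` of
#' its own plane, which is exactly the P1 discretisation of the
#' Laplace-Beltrami operator for an isotropic diffusion tensor
#' `D = delta * Id`. The global matrix is scaled by `delta`
#' (mm^2 s^-1), is symmetric positive-semidefinite and annihilates
#' constant vectors (zero-flux / closed-surface null space).
#'
#' @param mesh a [surface_mesh()].
#' @param delta isotropic diffusion coefficient (mm^2/s), > 0.
#' @return sparse symmetric `dgCMatrix`.
#' @export
assemble_stiffness <- function(mesh, delta = 1) {
  if (delta <= 0) stop("delta must be positive")
  v <- mesh$vertices; tr <- mesh$triangles
  ar <- triangle_areas(mesh)
  if (any(ar <= 1e-12))
    stop("degenerate triangle ", which(ar <= 1e-12)[1L], " (area <= 1e-12 mm^2)")
  # cot of the angle at vertex c of each triangle: dot / (2*area)
  cot_at <- function(a, b, c) {
    e1 <- v[a, , drop = FALSE] - v[c, , drop = FALSE]
    e2 <- v[b, , drop = FALSE] - v[c, , drop = FALSE]
    rowSums(e1 * e2) / (2 * ar)
  }
  c1 <- cot_at(tr[, 2], tr[, 3], tr[, 1])  # opposite edge (2,3)
  c2 <- cot_at(tr[, 1], tr[, 3], tr[, 2])  # opposite edge (1,3)
  c3 <- cot_at(tr[, 1], tr[, 2], tr[, 3])  # opposite edge (1,2)
  w1 <- c1 / 2; w2 <- c2 / 2; w3 <- c3 / 2
  ii <- c(tr[, 2], tr[, 3], tr[, 1], tr[, 3], tr[, 1], tr[, 2],
          tr[, 1], tr[, 2], tr[, 3])
  jj <- c(tr[, 3], tr[, 2], tr[, 3], tr[, 1], tr[, 2], tr[, 1],
          tr[, 1], tr[, 2], tr[, 3])
  xx <- c(-w1, -w1, -w2, -w2, -w3, -w3,
          w2 + w3, w1 + w3, w1 + w2)
  n <- n_vertices(mesh)
  delta * Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

#' IMEX system matrix A = M + dt * S
#'
#' @param M mass matrix (mm^2).
#' @param S stiffness matrix already scaled by the diffusion coefficient.
#' @param dt time step in the time unit `S` is expressed in (seconds for
#'   `delta` in mm^2/s).
#' @return sparse symmetric positive-definite matrix.
#' @export
build_system <- function(M, S, dt) {
  if (!all(dim(M) == dim(S))) stop("M and S have mismatched shapes")
  if (dt < 0) stop("dt must be non-negative")
  M + dt * S
}

#' Assemble all FEM matrices for a model run
#'
#' @param mesh a [surface_mesh()].
#' @param params a [model_params()] (uses `delta`, `dt`, `mass_mode`).
#' @return list of class `fem_matrices` with `M`, `S` (delta-scaled), `A`,
#'   `dt` (s), `mass_mode`, and a cached incomplete-Cholesky
#'   preconditioner for `A`.
#' @export
fem_matrices <- function(mesh, params) {
  M <- assemble_mass(mesh, params$mass_mode)
  S <- assemble_stiffness(mesh, params$delta)
  A <- build_system(M, S, params$dt)
  prec <- ic0_factor(A)
  structure(list(M = M, S = S, A = A, dt = params$dt,
                 mass_mode = params$mass_mode, prec = prec),
            class = "fem_matrices")
}

#' Zero-fill incomplete Cholesky factor
#'
#' Computes the IC(0) factor L (lower triangular, sparsity pattern of the
#' lower triangle of A) with `A ~ L L'`, used as the conjugate-gradient
#' preconditioner. If a pivot breaks down (possible for matrices that are
#' not M-matrices) the factorisation is abandoned and `NULL` is returned;
#' the solver then falls back to unpreconditioned CG with a warning.
#'
#' @param A sparse symmetric positive-definite matrix.
#' @return a `dtCMatrix` lower-triangular factor, or `NULL` on breakdown.
#' @export
ic0_factor <- function(A) {
  L <- Matrix::tril(methods::as(methods::as(A, "generalMatrix"), "CsparseMatrix"))
  p <- L@p; ri <- L@i; x <- L@x
  n <- ncol(L)
  col_of <- vector("list", n)
  for (j in seq_len(n)) col_of[[j]] <- (p[j] + 1L):p[j + 1L]
  for (j in seq_len(n)) {
    idx <- col_of[[j]]
    rows <- ri[idx] + 1L
    djj <- x[idx[1L]]           # first entry of each column is the diagonal
    if (djj <= 0) return(NULL)
    x[idx[1L]] <- sqrt(djj)
    if (length(idx) > 1L) x[idx[-1L]] <- x[idx[-1L]] / x[idx[1L]]
    # right-looking update of the remaining columns in this pattern
    if (length(idx) > 1L) {
      sub_rows <- rows[-1L]
      sub_vals <- x[idx[-1L]]
      for (t in seq_along(sub_rows)) {
        k <- sub_rows[t]
        lkj <- sub_vals[t]
        kk <- col_of[[k]]
        krows <- ri[kk] + 1L
        m <- match(krows, sub_rows)
        hit <- !is.na(m) & krows >= k
        if (any(hit))
          x[kk[hit]] <- x[kk[hit]] - lkj * sub_vals[m[hit]]
      }
    }
  }
  L@x <- x
  methods::as(L, "triangularMatrix")
}

#' Preconditioned conjugate-gradient solve
#'
#' Solves `A x = b` for symmetric positive-definite `A` by conjugate
#' gradients with an IC(0) preconditioner (the solver the simulation
#' protocol prescribes). Convergence is declared at relative residual
#' `tol`; non-convergence raises an error carrying the achieved residual.
#'
#' @param A sparse SPD matrix.
#' @param rhs right-hand side vector.
#' @param tol relative residual tolerance.
#' @param max_iter iteration cap; default `10 * sqrt(n)` (min 50).
#' @param prec optional precomputed [ic0_factor()]; `NULL` computes one,
#'   `NA` forces unpreconditioned CG.
#' @param x0 optional starting vector (warm start).
#' @return numeric solution vector with attributes `iterations` and
#'   `residual` (relative).
#' @export
solve_spd <- function(A, rhs, tol = 1e-8, max_iter = NULL, prec = NULL, x0 = NULL) {
  n <- length(rhs)
  if (is.null(max_iter)) max_iter <- max(50L, ceiling(10 * sqrt(n)))
  if (is.null(prec)) {
    prec <- ic0_factor(A)
    if (is.null(prec))
      warning("incomplete Cholesky broke down; using unpreconditioned CG")
  } else if (!methods::is(prec, "Matrix") && is.na(prec[1L])) {
    prec <- NULL
  }
  precT <- if (is.null(prec)) NULL else Matrix::t(prec)
  apply_prec <- if (is.null(prec)) identity else function(r) {
    y <- Matrix::solve(prec, r)
    as.numeric(Matrix::solve(precT, y))
  }
  bnorm <- sqrt(sum(rhs^2))
  if (bnorm == 0) return(structure(numeric(n), iterations = 0L, residual = 0))
  x <- if (is.null(x0)) numeric(n) else x0
  r <- rhs - as.numeric(A %*% x)
  z <- apply_prec(r)
  d <- z
  rz <- sum(r * z)
  for (it in seq_len(max_iter)) {
    if (sqrt(sum(r^2)) / bnorm <= tol)
      return(structure(x, iterations = it - 1L, residual = sqrt(sum(r^2)) / bnorm))
    Ad <- as.numeric(A %*% d)
    alpha <- rz / sum(d * Ad)
    x <- x + alpha * d
    r <- r - alpha * Ad
    z <- apply_prec(r)
    rz_new <- sum(r * z)
    d <- z + (rz_new / rz) * d
    rz <- rz_new
  }
  res <- sqrt(sum(r^2)) / bnorm
  if (res > tol)
    stop(sprintf("CG failed to converge in %d iterations (relative residual %.3g)",
                 max_iter, res))
  structure(x, iterations = max_iter, residual = res)
}

#' Export a sparse matrix to MatrixMarket format
#'
#' @param mat sparse matrix (e.g. from [assemble_mass()]).
#' @param path output `.mtx` path.
#' @return invisibly `path`.
#' @export
write_mtx <- function(mat, path) {
  Matrix::writeMM(methods::as(methods::as(mat, "generalMatrix"), "CsparseMatrix"), path)
  invisible(path)
}
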