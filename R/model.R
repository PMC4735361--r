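#' Model parameters for the firing-rate CSD model
#'
#' Defaults are the published calibration of the modified Rogers-McCulloch
#' model: rest 4 Hz, threshold 11.8 Hz, peak 64 Hz, excitation gain 1.6,
#' recovery parameters eta1 = 2.9227, eta2 = 2e-4, eta3 = 60, isotropic
#' diffusion delta = 0.7174 mm^2/s and time step 0.01 min.
#'
#' Unit convention (stated once, used everywhere): the rate constants
#' `G`, `eta1`, `eta2` are per *minute* -- the calibration under which the
#' published time step is stable, the space-clamped excursion plateaus at
#' the 64 Hz peak and plane waves run at ~9 mm/min (a cortex-scale
#' traversal of ~20 min). Times exposed to the user (`dt`, `t_max`,
#' activation times) are in seconds, and `delta` is in mm^2/s; the stepper
#' converts internally.
#'
#' @param G excitation gain (min^-1).
#' @param u0 resting firing rate (Hz).
#' @param u_th threshold parameter (Hz).
#' @param u_p peak firing rate (Hz).
#' @param eta1 recovery coupling gain (min^-1).
#' @param eta2 recovery rate (min^-1).
#' @param eta3 recovery saturation (dimensionless).
#' @param delta isotropic diffusion coefficient (mm^2/s).
#' @param dt time step (s); 0.6 s = 0.01 min.
#' @param t_max simulation cap (s).
#' @param activation_threshold firing rate whose upward crossing defines
#'   "activated"; defaults to `u_th`.
#' @param variant cubic reading: `"peak"` (default; `u0`, `u_th`, `u_p` are
#'   the literal rest/threshold/peak fixed points) or `"shifted"`
#'   (`(1-(u-u0)/u_th)(1-(u-u0)/u_p)`).
#' @param mass_mode `"consistent"` or `"lumped"` mass matrix.
#' @param cg_tol relative residual tolerance of the CG solver.
#' @return a `model_params` list.
#' @export
model_params <- function(G = 1.6, u0 = 4, u_th = 11.8, u_p = 64,
                         eta1 = 2.9227, eta2 = 2e-4, eta3 = 60,
                         delta = 0.7174, dt = 0.6, t_max = 3600,
                         activation_threshold = u_th,
                         variant = c("peak", "shifted"),
                         mass_mode = c("consistent", "lumped"),
                         cg_tol = 1e-8) {
  variant <- match.arg(variant)
  mass_mode <- match.arg(mass_mode)
  if (!(u0 < u_th && u_th < u_p)) stop("need u0 < u_th < u_p")
  if (any(c(G, eta1, eta2, eta3, delta, dt) <= 0))
    stop("G, eta1, eta2, eta3, delta and dt must be positive")
  if (activation_threshold <= u0 || activation_threshold >= u_p)
    stop("activation_threshold must lie in (u0, u_p)")
  structure(list(G = G, u0 = u0, u_th = u_th, u_p = u_p,
                 eta1 = eta1, eta2 = eta2, eta3 = eta3,
                 delta = delta, dt = dt, t_max = t_max,
                 activation_threshold = activation_threshold,
                 variant = variant, mass_mode = mass_mode, cg_tol = cg_tol),
            class = "model_params")
}

# time step expressed in the unit of the rate constants (minutes)
dt_rate <- function(params) params$dt / 60

#' Reaction current I(u, w)
#'
#' `I = G (u - u0)(1 - u/u_th)(1 - u/u_p) + eta1 (u - u0) w` (default
#' variant), vectorised over vertices. The cubic vanishes at rest,
#' threshold and peak; the recovery coupling pulls excited tissue back to
#' rest as `w` builds up. Units: Hz per minute (rate constants are per
#' minute).
#'
#' @param u firing rate (Hz), scalar or vector.
#' @param w recovery variable, same length.
#' @param params a [model_params()].
#' @return numeric vector, the current.
#' @export
reaction_current <- function(u, w, params) {
  d <- u - params$u0
  cubic <- switch(params$variant,
    peak    = (1 - u / params$u_th) * (1 - u / params$u_p),
    shifted = (1 - d / params$u_th) * (1 - d / params$u_p))
  params$G * d * cubic + params$eta1 * d * w
}

#' Closed-form recovery update
#'
#' Advances `w` over one step with `u` frozen at its start-of-step value:
#' `w' = (u - u0)/eta3 + (w - (u - u0)/eta3) exp(-eta2 eta3 dt)`, the
#' exact solution of the linear recovery ODE for frozen u.
#'
#' @param u_n,w_n state at the start of the step.
#' @param dt step length in seconds.
#' @param params a [model_params()].
#' @return updated recovery variable.
#' @export
update_recovery <- function(u_n, w_n, dt, params) {
  winf <- (u_n - params$u0) / params$eta3
  winf + (w_n - winf) * exp(-params$eta2 * params$eta3 * dt / 60)
}

#' Simulation state
#' @param u per-vertex firing rate (Hz).
#' @param w per-vertex recovery variable.
#' @param t current time (s).
#' @return a `sim_state` list.
#' @export
sim_state <- function(u, w = numeric(length(u)), t = 0) {
  stopifnot(length(u) == length(w), all(is.finite(u)), all(is.finite(w)))
  structure(list(u = u, w = w, t = t), class = "sim_state")
}

#' One IMEX step
#'
#' The recovery variable is advanced first by its closed-form update, the
#' reaction current is evaluated as `I(u^n, w^{n+1})`, and the firing rate
#' is advanced by one linearly implicit diffusion solve
#' `A u^{n+1} = M u^n - dt M I^{n+1}` with `A = M + dt S`.
#'
#' @param state a [sim_state()].
#' @param fem a [fem_matrices()] assembled with the same `params`.
#' @param params a [model_params()].
#' @return the advanced `sim_state`.
#' @export
imex_step <- function(state, fem, params) {
  w1 <- update_recovery(state$u, state$w, params$dt, params)
  I1 <- reaction_current(state$u, w1, params)
  rhs <- as.numeric(fem$M %*% (state$u - dt_rate(params) * I1))
  u1 <- solve_spd(fem$A, rhs, tol = params$cg_tol, prec = fem$prec, x0 = state$u)
  sim_state(as.numeric(u1), w1, state$t + params$dt)
}

#' Single-source CSD simulation with activation recording
#'
#' Initialises the source region fully depolarised (`u = u_p`), everything
#' else at rest (`u = u0`, `w = 0`), and steps the IMEX scheme until every
#' non-excluded region is fully activated (all of its vertices have
#' crossed the activation threshold) or `t_max` is reached. The first
#' upward crossing of each vertex is recorded, refined by linear
#' interpolation inside the step.
#'
#' @param mesh a closed [surface_mesh()].
#' @param atlas a [region_atlas()] on the mesh.
#' @param source_region region id to depolarise initially, or `NA` for an
#'   unstimulated (resting) run.
#' @param params a [model_params()].
#' @param fem optional pre-assembled [fem_matrices()] (reused across the
#'   all-sources protocol).
#' @return an `activation_record`: list with `source_region`,
#'   `first_activation` (per-vertex seconds, `NA` if never),
#'   `region_min`/`region_max` (named by region id, seconds), `complete`,
#'   `not_activated` (ids of regions not fully activated), `u_peak` (max of
#'   u over space and time, Hz), `t_end`, `steps`.
#' @export
run_simulation <- function(mesh, atlas, source_region, params = model_params(),
                           fem = NULL) {
  validate_atlas(atlas, mesh)
  if (!is.na(source_region)) {
    if (!source_region %in% atlas$region_ids)
      stop("unknown source region ", source_region)
    if (source_region %in% atlas$source_excluded)
      stop("region ", source_region, " is excluded as a source")
  }
  if (is.null(fem)) fem <- fem_matrices(mesh, params)
  n <- n_vertices(mesh)
  lab <- atlas$labels
  th <- params$activation_threshold
  u <- rep(params$u0, n)
  if (!is.na(source_region)) u[lab == source_region] <- params$u_p
  w <- numeric(n)
  act <- rep(NA_real_, n)
  act[u > th] <- 0
  incl <- included_regions(atlas)
  remaining <- vapply(incl, function(r) sum(lab == r & is.na(act)), integer(1))
  names(remaining) <- incl
  t <- 0; step <- 0L; u_peak <- max(u)
  n_steps_max <- ceiling(params$t_max / params$dt)
  while (any(remaining > 0L) && step < n_steps_max) {
    w1 <- update_recovery(u, w, params$dt, params)
    I1 <- reaction_current(u, w1, params)
    rhs <- as.numeric(fem$M %*% (u - dt_rate(params) * I1))
    u1 <- as.numeric(solve_spd(fem$A, rhs, tol = params$cg_tol,
                               prec = fem$prec, x0 = u))
    newly <- which(is.na(act) & u1 > th)
    if (length(newly) > 0L) {
      frac <- (th - u[newly]) / (u1[newly] - u[newly])
      frac[!is.finite(frac)] <- 1
      act[newly] <- t + params$dt * pmin(pmax(frac, 0), 1)
      hit <- lab[newly]
      hit <- hit[hit %in% incl]
      if (length(hit) > 0L) {
        cnt <- table(hit)
        remaining[names(cnt)] <- remaining[names(cnt)] - as.integer(cnt)
      }
    }
    u <- u1; w <- w1; t <- t + params$dt; step <- step + 1L
    if (max(u) > u_peak) u_peak <- max(u)
  }
  ids <- atlas$region_ids
  region_min <- stats::setNames(rep(NA_real_, length(ids)), ids)
  region_max <- region_min
  for (r in seq_along(ids)) {
    a <- act[lab == ids[r]]
    if (!anyNA(a)) {
      region_min[r] <- min(a); region_max[r] <- max(a)
    } else if (any(!is.na(a))) {
      region_min[r] <- min(a, na.rm = TRUE)
    }
  }
  complete <- all(remaining == 0L)
  structure(list(source_region = source_region,
                 first_activation = act,
                 region_min = region_min,
                 region_max = region_max,
                 complete = complete,
                 not_activated = as.integer(names(remaining)[remaining > 0L]),
                 u_peak = u_peak,
                 t_end = t, steps = step, params = params),
            class = "activation_record")
}

#' @export
print.activation_record <- function(x, ...) {
  cat(sprintf("activation_record: source %s, %d steps (t = %.1f s), %s\n",
              format(x$source_region), x$steps, x$t_end,
              if (x$complete) "complete" else
                paste0("INCOMPLETE (", length(x$not_activated), " regions unfinished)")))
  invisible(x)
}

#' All-sources simulation protocol
#'
#' Runs one single-source simulation per non-excluded region and collects
#' the per-region minimum and maximum activation times into k x k matrices
#' `T_min` and `T_max` (seconds): row = starting region, column = arrival
#' region. Rows/columns are arranged by [order_regions()] (lobe blocks,
#' centroid-chained within each lobe).
#'
#' @param mesh a closed [surface_mesh()].
#' @param atlas a [region_atlas()] with at least 2 non-excluded regions.
#' @param params a [model_params()].
#' @param allow_partial keep going when a run hits `t_max` (missing
#'   entries become `NA`); otherwise such a run is an error.
#' @param verbose print one line per source.
#' @return an `activation_matrices` object: `T_min`, `T_max` (dimnames =
#'   region names in protocol order), `region_order` (ids), `records`.
#' @export
run_protocol <- function(mesh, atlas, params = model_params(),
                         allow_partial = FALSE, verbose = FALSE) {
  incl <- included_regions(atlas)
  if (length(incl) < 2L) stop("need at least 2 non-excluded regions")
  fem <- fem_matrices(mesh, params)
  rg <- region_geometry(mesh, atlas)
  ord <- order_regions(atlas, rg)
  k <- length(ord)
  nms <- unname(atlas$region_names[match(ord, atlas$region_ids)])
  T_min <- matrix(NA_real_, k, k, dimnames = list(nms, nms))
  T_max <- T_min
  records <- vector("list", k)
  for (i in seq_len(k)) {
    if (verbose) message("source region ", ord[i], " (", nms[i], ")")
    rec <- run_simulation(mesh, atlas, ord[i], params, fem = fem)
    if (!rec$complete && !allow_partial)
      stop("simulation from region ", ord[i], " incomplete at t_max; ",
           "unfinished regions: ", paste(rec$not_activated, collapse = ", "))
    T_min[i, ] <- rec$region_min[as.character(ord)]
    T_max[i, ] <- rec$region_max[as.character(ord)]
    records[[i]] <- rec
  }
  structure(list(T_min = T_min, T_max = T_max, region_order = ord,
                 region_names = nms, records = records, params = params),
            class = "activation_matrices")
}

#' @export
print.activation_matrices <- function(x, ...) {
  cat(sprintf("activation_matrices: %d regions, T_min in [%.3g, %.3g] s\n",
              nrow(x$T_min), min(x$T_min, na.rm = TRUE), max(x$T_min, na.rm = TRUE)))
  invisible(x)
}

#' Space-clamped excitation episode
#'
#' Integrates the diffusion-free single-point dynamics with the same IMEX
#' splitting (closed-form recovery update, explicit reaction) and
#' summarises the excursion: peak firing rate, plateau duration (time
#' above the activation threshold) and the final state. A supra-threshold
#' start rises to the ~`u_p` plateau and returns to rest once the
#' recovery variable builds up; a sub-threshold start decays monotonically.
#'
#' @param params a [model_params()].
#' @param u_start initial firing rate (Hz), in `(u0, u_p]`.
#' @param w_start initial recovery value.
#' @param t_max integration cap (s).
#' @return list with `peak_u` (Hz), `plateau_s` (s above threshold),
#'   `u_final`, `w_final`, `t_final` (s) and the `u` trajectory.
#' @export
excitation_episode <- function(params = model_params(), u_start,
                               w_start = 0, t_max = 18000) {
  u <- u_start; w <- w_start
  n_max <- ceiling(t_max / params$dt)
  traj <- numeric(n_max)
  above <- 0L; peak <- u_start; n_done <- n_max
  for (n in seq_len(n_max)) {
    w <- update_recovery(u, w, params$dt, params)
    u <- u - dt_rate(params) * reaction_current(u, w, params)
    traj[n] <- u
    if (u > params$activation_threshold) above <- above + 1L
    if (u > peak) peak <- u
    if (abs(u - params$u0) < 1e-9 && abs(w) < 1e-9) { n_done <- n; break }
  }
  list(peak_u = peak,
       plateau_s = above * params$dt,
       u_final = u, w_final = w, t_final = n_done * params$dt,
       u = traj[seq_len(n_done)])
}

#' Write a per-vertex activation record to CSV
#'
#' Header `vertex,time_s`, vertex ids 0-based; vertices that never
#' activated get an empty time field. A JSON side-car with the parameters
#' and a mesh hash can be written via [write_run_metadata()].
#'
#' @param record an `activation_record`.
#' @param path output CSV path.
#' @return invisibly `path`.
#' @export
write_activation_record <- function(record, path) {
  tm <- ifelse(is.na(record$first_activation), "",
               sprintf("%.17g", record$first_activation))
  write_lines_lf(c("vertex,time_s",
                   paste(seq_along(tm) - 1L, tm, sep = ",")), path)
  invisible(path)
}

#' Write activation-time matrices to CSV
#'
#' One CSV per matrix, region names as header row and first column, in
#' protocol order; 17-significant-digit values, LF endings.
#'
#' @param matrices an `activation_matrices` object.
#' @param path_min,path_max output paths.
#' @return invisibly `path_min`.
#' @export
write_activation_matrices <- function(matrices, path_min, path_max) {
  write_matrix_csv(matrices$T_min, path_min)
  write_matrix_csv(matrices$T_max, path_max)
  invisible(path_min)
}

#' Write run metadata (parameters + mesh hash) as JSON
#'
#' @param params a [model_params()].
#' @param mesh the mesh the run used.
#' @param path output JSON path.
#' @param extra named list of additional fields (e.g. seed, source).
#' @return invisibly `path`.
#' @export
write_run_metadata <- function(params, mesh, path, extra = list()) {
  tmp <- tempfile(fileext = ".off")
  on.exit(unlink(tmp))
  write_mesh(mesh, tmp)
  meta <- c(list(params = unclass(params),
                 mesh_hash = unname(tools::md5sum(tmp)),
                 n_vertices = n_vertices(mesh),
                 n_triangles = n_triangles(mesh)),
            extra)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
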