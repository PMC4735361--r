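# Shared fixtures, memoised so expensive simulations run once per suite.
.fix <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fix)) assign(name, force(expr), envir = .fix)
  get(name, envir = .fix)
}

unit_triangle <- function() {
  surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
}

# 2-triangle unit square in the z = 0 plane
unit_square <- function() make_sheet(2, 2, 1, 1)

ico6 <- function() memo("ico6", {
  m <- make_icosphere(3, 10)
  list(mesh = m, atlas = make_face_atlas(m))
})

ico6_protocol <- function() memo("ico6_protocol", {
  f <- ico6()
  run_protocol(f$mesh, f$atlas, model_params())
})

ico6_protocol_halfdt <- function() memo("ico6_protocol_halfdt", {
  f <- ico6()
  run_protocol(f$mesh, f$atlas, model_params(dt = 0.3))
})

# radius 20 mm so every 1/34 source patch exceeds the critical nucleation
# radius (~delta/c ~ 4.5 mm) of the medium
ico34_protocol <- function() memo("ico34_protocol", {
  m <- make_icosphere(3, 20)
  a <- make_seed_atlas(m, 34)
  list(mesh = m, atlas = a, mats = run_protocol(m, a, model_params()))
})

# plane-wave front speed (mm/min) on a 40 x 2 mm strip, source = first strip
sheet_speed <- function(delta, h = 0.5, mass_mode = "consistent") {
  key <- sprintf("speed_%g_%g_%s", delta, h, mass_mode)
  memo(key, {
    L <- 40; W <- 2
    sh <- make_sheet(round(L / h) + 1L, round(W / h) + 1L, L, W)
    at <- make_strip_atlas(sh, 8)
    p <- model_params(delta = delta, mass_mode = mass_mode)
    rec <- run_simulation(sh, at, 1, p)
    mid <- abs(sh$vertices[, 2] - W / 2) < 1e-9
    x <- sh$vertices[mid, 1]; tt <- rec$first_activation[mid]
    sel <- x >= 15 & x <= 35
    slope <- stats::coef(stats::lm(tt[sel] ~ x[sel]))[[2]]
    list(speed = 60 / slope, record = rec)
  })
}

# duct transmission fixture: fast-recovery pulse regime, only the bend
# angle differs between arms
duct_transmits <- function(bend_angle) {
  key <- sprintf("duct_%g", bend_angle)
  memo(key, {
    width <- 3; leg <- 15; h <- 0.5
    d <- make_duct(width, leg, bend_angle, h = h)
    v <- d$vertices
    kink <- (180 - bend_angle) * pi / 180
    rot2 <- function(u, a) c(cos(a) * u[1] - sin(a) * u[2],
                             sin(a) * u[1] + cos(a) * u[2])
    pivot <- c(leg, width)
    endc <- pivot + (width / 2) * rot2(c(0, -1), kink) + leg * rot2(c(1, 0), kink)
    lab <- rep(2L, nrow(v))
    lab[v[, 1] < 5 & v[, 2] <= width + 1e-9 & v[, 2] >= -1e-9] <- 1L
    lab[sqrt((v[, 1] - endc[1])^2 + (v[, 2] - endc[2])^2) < 2] <- 3L
    at <- region_atlas(lab, lobes = stats::setNames(rep("duct", 3), 1:3))
    p <- model_params(eta2 = 0.02, t_max = 1500)
    rec <- run_simulation(d, at, 1, p)
    list(transmitted = is.finite(rec$region_min[["3"]]), record = rec)
  })
}

# space-clamped excitation episode from 13 Hz with default parameters
episode13 <- function() memo("episode13", excitation_episode(model_params(), 13))

# two counter-propagating plane waves on a thin strip; returns max u over
# the strip at the end of 2 plateau durations after the collision
annihilation_run <- function() memo("annihilation", {
  sh <- make_sheet(61, 3, 30, 1)
  x <- sh$vertices[, 1]
  lab <- rep(2L, n_vertices(sh)); lab[x < 3 | x > 27] <- 1L
  at <- region_atlas(lab, lobes = stats::setNames(rep("sheet", 2), 1:2))
  p <- model_params()
  fm <- fem_matrices(sh, p)
  u <- rep(p$u0, n_vertices(sh)); u[lab == 1L] <- p$u_p
  st <- sim_state(u)
  plateau <- episode13()$plateau_s
  t_collide <- 200                     # fronts meet mid-strip well before this
  n_total <- ceiling((t_collide + 2 * plateau) / p$dt)
  collided <- FALSE; u_peak <- max(u)
  for (i in seq_len(n_total)) {
    st <- imex_step(st, fm, p)
    if (max(st$u) > u_peak) u_peak <- max(st$u)
    if (!collided && i * p$dt >= t_collide)
      collided <- all(st$u > p$u_th | abs(x - 15) > 10)
  }
  list(final_max_u = max(st$u), u_peak = u_peak, params = p)
})
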