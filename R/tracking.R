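#' Particle parameters for algal-cell surrogates
#'
#' Neutrally buoyant spherical particles standing in for algal cells:
#' 20 particles of 10 micron diameter and density 1000 kg/m^3 by default,
#' tracked for 60 s with positions recorded every 0.1 s. The drag
#' coefficient defaults to the Newton-regime constant 0.44.
#'
#' @param n_particles Number of particles (default 20).
#' @param diameter Particle diameter in m (default 1e-5).
#' @param density Particle density in kg/m^3 (default 1000).
#' @param drag_coefficient Drag coefficient C_D (default 0.44).
#' @param fluid_density Liquid density in kg/m^3 (default 1000).
#' @param record_interval Recording interval in s (default 0.1).
#' @param max_time Total tracking time in s (default 60).
#' @param integrator_step Outer integrator step in s (default 0.01; the
#'   integrator subdivides further when the drag dynamics demand it).
#' @param seed Integer RNG seed, or `NULL` to use the current RNG state.
#' @param use_drw Apply discrete-random-walk turbulent dispersion
#'   (default `TRUE`; automatically inert where `k = 0`).
#' @return A `pbr_particle_params` list.
#' @export
particle_params <- function(n_particles = 20, diameter = 1e-5,
                            density = 1000, drag_coefficient = 0.44,
                            fluid_density = 1000, record_interval = 0.1,
                            max_time = 60, integrator_step = 0.01,
                            seed = NULL, use_drw = TRUE) {
  stopifnot(diameter > 0, density > 0, fluid_density > 0,
            drag_coefficient >= 0, record_interval > 0,
            integrator_step > 0, integrator_step <= record_interval,
            max_time >= record_interval, n_particles >= 1)
  structure(list(n_particles = as.integer(n_particles), diameter = diameter,
                 density = density, drag_coefficient = drag_coefficient,
                 fluid_density = fluid_density,
                 record_interval = record_interval, max_time = max_time,
                 integrator_step = integrator_step, seed = seed,
                 use_drw = isTRUE(use_drw)),
            class = "pbr_particle_params")
}

# quadratic-drag coefficient per unit mass, 1/m
drag_coefficient_per_m <- function(params) {
  3 * params$drag_coefficient * params$fluid_density /
    (4 * params$diameter * params$density)
}

#' Drag acceleration on a particle
#'
#' Quadratic (Newton-regime) drag per unit particle mass:
#' `(3 C_D rho_f) / (4 d rho_p) * |v_f - v_p| (v_f - v_p)`.
#'
#' @param v_fluid,v_particle Length-2 velocity vectors in m/s.
#' @param params A [particle_params()] object.
#' @return Length-2 acceleration in m/s^2.
#' @export
drag_accel <- function(v_fluid, v_particle, params) {
  dv <- v_fluid - v_particle
  drag_coefficient_per_m(params) * sqrt(sum(dv^2)) * dv
}

#' Material acceleration of the carrier fluid
#'
#' Convective acceleration `(u . grad) u` of the steady field, from
#' bilinear interpolation of centred-difference velocity gradients.
#'
#' @param field A [pbr_flow_field] object.
#' @param depth,lateral Point coordinates in mm (inside the culture
#'   region).
#' @return Matrix with columns `a_depth`, `a_lateral` in m/s^2.
#' @export
fluid_accel <- function(field, depth, lateral) {
  stopifnot(inherits(field, "pbr_flow_field"))
  if (!all(in_culture(field$geom, depth, lateral)))
    stop("fluid_accel() cannot extrapolate outside the culture region",
         call. = FALSE)
  g <- field_gradients(field)
  v <- interp_field(field, depth, lateral)
  gv <- interp_grad(g, field, depth, lateral)
  cbind(a_depth   = v[, 1] * gv$dud_dd + v[, 2] * gv$dud_dl,
        a_lateral = v[, 1] * gv$dul_dd + v[, 2] * gv$dul_dl)
}

# centred-difference gradients of the velocity matrices, per metre
field_gradients <- function(field) {
  h_m <- field$spacing / 1000
  grad <- function(m) {
    nd <- nrow(m); nl <- ncol(m)
    gd <- gl <- matrix(0, nd, nl)
    gd[2:(nd - 1), ] <- (m[3:nd, ] - m[1:(nd - 2), ]) / (2 * h_m)
    gl[, 2:(nl - 1)] <- (m[, 3:nl] - m[, 1:(nl - 2)]) / (2 * h_m)
    list(d = gd, l = gl)
  }
  gd_ud <- grad(field$u_depth); gd_ul <- grad(field$u_lateral)
  list(dud_dd = gd_ud$d, dud_dl = gd_ud$l,
       dul_dd = gd_ul$d, dul_dl = gd_ul$l)
}

interp_grad <- function(g, field, depth, lateral) {
  tmp <- field
  tmp$gdudd <- g$dud_dd; tmp$gdudl <- g$dud_dl
  tmp$gduld <- g$dul_dd; tmp$gduldl <- g$dul_dl
  m <- interp_field(tmp, depth, lateral,
                    what = c("gdudd", "gdudl", "gduld", "gduldl"))
  list(dud_dd = m[, 1], dud_dl = m[, 2], dul_dd = m[, 3], dul_dl = m[, 4])
}

#' Pressure-gradient acceleration on a particle
#'
#' Per unit particle mass, `(rho_f / rho_p)` times the fluid material
#' acceleration at the particle position.
#'
#' @inheritParams fluid_accel
#' @param params A [particle_params()] object.
#' @return Matrix with columns `a_depth`, `a_lateral` in m/s^2.
#' @export
pressure_gradient_accel <- function(field, depth, lateral, params) {
  (params$fluid_density / params$density) * fluid_accel(field, depth, lateral)
}

#' Discrete-random-walk velocity fluctuation
#'
#' Draws one eddy interaction of the discrete random walk: each velocity
#' component is an independent Gaussian with standard deviation
#' `sqrt(2 k / 3)` (isotropic turbulence), held for an eddy lifetime
#' `tau_e = 2 T_L` with the Lagrangian time scale `T_L = 0.15 k / eps`.
#'
#' @param k Turbulent kinetic energy in cm^2/s^2 (>= 0).
#' @param eps Dissipation rate in cm^2/s^3 (> 0).
#' @return List with `fluctuation` (length-2, m/s) and `lifetime` (s).
#' @export
drw_fluctuation <- function(k, eps) {
  if (k < 0) stop("`k` must be non-negative", call. = FALSE)
  if (eps <= 0) stop("`eps` must be positive", call. = FALSE)
  k_m <- k * 1e-4; eps_m <- eps * 1e-4
  sigma <- sqrt(2 * k_m / 3)
  list(fluctuation = stats::rnorm(2, 0, sigma),
       lifetime = 2 * 0.15 * k_m / eps_m)
}

#' Track algal-cell surrogate particles through a flow field
#'
#' Integrates the particle momentum equation
#' `dv/dt = drag + pressure gradient` with the instantaneous fluid
#' velocity equal to the interpolated mean flow plus the current
#' discrete-random-walk fluctuation, using classical 4th-order
#' Runge--Kutta steps. Because the quadratic drag of 10 micron particles
#' is numerically stiff, each outer step is subdivided adaptively to keep
#' the drag stage stable; the subdivision rule is deterministic, so runs
#' with a fixed seed are bit-reproducible. Walls reflect particles
#' specularly, conserving speed.
#'
#' @param field A [pbr_flow_field] object.
#' @param params A [particle_params()] object.
#' @param init Optional matrix/data.frame of initial positions
#'   (`depth`, `lateral` in mm, one row per particle); when absent,
#'   `params$n_particles` positions are drawn uniformly over the culture
#'   region. Initial particle velocity equals the local mean fluid
#'   velocity unless `init_velocity` is given.
#' @param init_velocity Optional matrix of initial particle velocities in
#'   m/s (same shape as `init`); defaults to the interpolated mean fluid
#'   velocity at the release points.
#' @return Data frame with columns `particle_id`, `time_s`, `depth_mm`,
#'   `lateral_mm`, `zone` — `round(max_time / record_interval)` samples
#'   per particle starting at `t = 0`. Recorded particle velocities are
#'   attached as attribute `velocity`.
#' @export
track <- function(field, params = particle_params(), init = NULL,
                  init_velocity = NULL) {
  stopifnot(inherits(field, "pbr_flow_field"),
            inherits(params, "pbr_particle_params"))
  geom <- field$geom
  if (!is.null(params$seed)) set.seed(params$seed)
  if (is.null(init)) {
    init <- sample_culture_points(geom, params$n_particles)
  } else {
    init <- as.matrix(init)[, 1:2, drop = FALSE]
    if (!all(in_culture(geom, init[, 1], init[, 2])))
      stop("initial positions must lie inside the culture region", call. = FALSE)
  }
  n <- nrow(init)
  v0 <- if (is.null(init_velocity)) interp_field(field, init[, 1], init[, 2])
        else as.matrix(init_velocity)[, 1:2, drop = FALSE]
  layout_code <- match(geom$layout, c("plain", "concentric", "tangent"))
  res <- track_particles_cpp(
    field$u_depth, field$u_lateral, field$k, field$eps,
    field$depth, field$lateral, field$spacing,
    init, matrix(v0, ncol = 2),
    params$integrator_step, params$record_interval, params$max_time,
    drag_coefficient_per_m(params),
    params$fluid_density / params$density,
    layout_code, geom$outer_radius,
    if (geom$layout == "plain") 0 else geom$inner_radius,
    if (geom$layout == "plain") 0 else geom$inner_center_depth,
    isTRUE(geom$fillet_enabled),
    if (isTRUE(geom$fillet_enabled)) geom$chord_depth else -Inf,
    params$use_drw)
  n_rec <- round(params$max_time / params$record_interval)
  times <- (seq_len(n_rec) - 1) * params$record_interval
  out <- data.frame(
    particle_id = rep(seq_len(n), each = n_rec),
    time_s = rep(times, times = n),
    depth_mm = as.vector(t(res$depth)),
    lateral_mm = as.vector(t(res$lateral)))
  out$zone <- ifelse(out$depth_mm > geom$boundary_depth, "light", "dark")
  attr(out, "velocity_final") <- res$v_final
  attr(out, "velocity") <- list(depth = res$v_depth, lateral = res$v_lateral)
  out
}

# uniform rejection sampling of culture points
sample_culture_points <- function(geom, n) {
  R <- geom$outer_radius
  pts <- matrix(NA_real_, 0, 2)
  while (nrow(pts) < n) {
    m <- 4 * (n - nrow(pts)) + 8
    cand <- cbind(stats::runif(m, -R, R), stats::runif(m, -R, R))
    keep <- in_culture(geom, cand[, 1], cand[, 2])
    pts <- rbind(pts, cand[keep, , drop = FALSE])
  }
  pts[seq_len(n), , drop = FALSE]
}
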