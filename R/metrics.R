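#' Field-synergy angle map
#'
#' The field-synergy angle `alpha` is the angle between the local liquid
#' velocity and the light propagation direction (straight down the depth
#' axis under normal incidence). `|cos(alpha)| = |u . g| / |u|` with `g`
#' the unit light direction: 1 means transport aligned with the light
#' path, 0 means transport across it. Cells with speed below `tol` are
#' marked undefined (`NA`) rather than coerced.
#'
#' @param field A [pbr_flow_field] object.
#' @param light_direction Unit vector `(depth, lateral)` of light travel
#'   (default `c(-1, 0)`, from the illuminated top downwards).
#' @param tol Stagnant-speed threshold in m/s (default 1e-9).
#' @return Matrix of `|cos(alpha)|` values in `[0, 1]`, `NA` where the
#'   fluid is stagnant or outside the culture region.
#' @export
cos_alpha_field <- function(field, light_direction = c(-1, 0), tol = 1e-9) {
  stopifnot(inherits(field, "pbr_flow_field"))
  nrm <- sqrt(sum(light_direction^2))
  if (!is.finite(nrm) || nrm < 1e-12)
    stop("`light_direction` must be a nonzero vector", call. = FALSE)
  g <- light_direction / nrm
  sp <- sqrt(field$u_depth^2 + field$u_lateral^2)
  ca <- abs(field$u_depth * g[1] + field$u_lateral * g[2]) / sp
  ca[sp < tol] <- NA
  ca[!field$mask] <- NA
  ca
}

#' Mean |cos(alpha)| synergy statistic
#'
#' Area-weighted mean of the synergy map over the culture region or over a
#' zone of it, ignoring undefined (stagnant) cells and reporting their
#' fraction.
#'
#' @inheritParams cos_alpha_field
#' @param region `"culture"`, `"light"` or `"dark"`.
#' @return List with `mean_abs_cos_alpha`, `undefined_fraction` and
#'   `n_cells`. `mean_abs_cos_alpha` is `NA` when every cell is undefined.
#' @export
mean_abs_cos_alpha <- function(field, region = "culture",
                               light_direction = c(-1, 0)) {
  ca <- cos_alpha_field(field, light_direction)
  sel <- region_mask(field, region)
  if (!any(sel)) stop("requested region contains no culture cells", call. = FALSE)
  vals <- ca[sel]
  list(mean_abs_cos_alpha = if (all(is.na(vals))) NA_real_
                            else mean(vals, na.rm = TRUE),
       undefined_fraction = mean(is.na(vals)),
       n_cells = length(vals))
}

region_mask <- function(field, region) {
  m <- field$mask
  if (identical(region, "culture")) return(m)
  dep <- matrix(field$depth, length(field$depth), length(field$lateral))
  b <- field$geom$boundary_depth
  switch(region,
    light = m & dep > b,
    dark  = m & dep <= b,
    stop("unknown region: ", region, call. = FALSE))
}

#' Monitoring-line profile of vertical velocity and synergy
#'
#' Samples the vertical (depth-axis) velocity component `V_r` — the
#' component that carries cells across the light/dark interface — and
#' `|cos(alpha)|` along a vertical monitoring line at a fixed lateral
#' offset, by bilinear interpolation, restricted to the culture region.
#'
#' @param field A [pbr_flow_field] object.
#' @param lateral_offset Lateral position of the line in mm
#'   (|offset| < outer radius).
#' @param n_samples Number of sample points along the line (default 401).
#' @return Data frame with columns `depth`, `v_r` (m/s) and
#'   `abs_cos_alpha`; zero rows if the line misses the culture region.
#' @export
vr_profile <- function(field, lateral_offset, n_samples = 401) {
  stopifnot(inherits(field, "pbr_flow_field"))
  R <- field$geom$outer_radius
  if (abs(lateral_offset) >= R)
    stop("monitoring line lies outside the outer tube", call. = FALSE)
  half <- sqrt(R^2 - lateral_offset^2)
  dep <- seq(-half, half, length.out = n_samples)
  keep <- in_culture(field$geom, dep, lateral_offset)
  dep <- dep[keep]
  if (!length(dep))
    return(data.frame(depth = numeric(), v_r = numeric(),
                      abs_cos_alpha = numeric()))
  v <- interp_field(field, dep, lateral_offset)
  sp <- sqrt(v[, 1]^2 + v[, 2]^2)
  ca <- ifelse(sp < 1e-9, NA, abs(v[, 1]) / sp)
  data.frame(depth = dep, v_r = v[, 1], abs_cos_alpha = ca)
}

#' Mean turbulent kinetic energy
#'
#' Area-weighted mean of the turbulent kinetic energy over the culture
#' region or a zone of it.
#'
#' @inheritParams mean_abs_cos_alpha
#' @return Mean TKE in cm^2/s^2.
#' @export
tke_mean <- function(field, region = "culture") {
  stopifnot(inherits(field, "pbr_flow_field"))
  sel <- region_mask(field, region)
  if (!any(sel)) stop("requested region contains no culture cells", call. = FALSE)
  mean(field$k[sel])
}

#' Dead-zone fraction
#'
#' Fraction of the culture area where the liquid speed falls below a
#' threshold — regions where algal cells settle instead of circulating.
#'
#' @param field A [pbr_flow_field] object.
#' @param speed_threshold Speed threshold in m/s (default 1e-3).
#' @return Fraction in `[0, 1]`.
#' @export
dead_zone_fraction <- function(field, speed_threshold = 1e-3) {
  stopifnot(inherits(field, "pbr_flow_field"))
  if (speed_threshold <= 0)
    stop("`speed_threshold` must be positive", call. = FALSE)
  sp <- sqrt(field$u_depth^2 + field$u_lateral^2)
  mean(sp[field$mask] < speed_threshold)
}

#' Light/dark cycle statistics from trajectories
#'
#' A light/dark cycle is the time for a cell to cross the light/dark
#' interface twice. Crossings are located where the depth coordinate
#' passes the boundary between consecutive samples, with the crossing time
#' linearly interpolated. For each particle completing at least one full
#' cycle (three or more crossings), the cycle period `T` is the mean
#' spacing between alternate crossings; the population `T` averages over
#' those particles and `f = 1/T`. The light-time ratio `phi` is the
#' light-zone residence fraction of every particle that crosses at least
#' once — a particle that dips into the dark zone and settles there
#' counts, with its long dark residence — averaged over those particles.
#' Particles that never cross are excluded from all statistics and
#' counted in `n_noncrossing`.
#'
#' @param trajectories Data frame as returned by [track()]: columns
#'   `particle_id`, `time_s`, `depth_mm` (and optionally `zone`).
#' @param geom A [make_geometry()] object supplying the boundary depth.
#' @param phi_method `"per_particle"` (mean of per-particle residence
#'   fractions, the default) or `"pooled"` (pooled light time over pooled
#'   tracked time of crossing particles).
#' @return List of class `pbr_ld_stats`: `mean_T_s`, `f_hz`, `phi`,
#'   `n_noncrossing`, `n_particles` and a `per_particle` data frame with
#'   `particle_id`, `T_s`, `phi`, `n_crossings`.
#' @export
ld_cycle_stats <- function(trajectories, geom, phi_method = c("per_particle",
                                                              "pooled")) {
  phi_method <- match.arg(phi_method)
  stopifnot(inherits(geom, "pbr_geometry"))
  if (!is.data.frame(trajectories) || nrow(trajectories) == 0)
    stop("`trajectories` must be a non-empty data frame", call. = FALSE)
  b <- geom$boundary_depth
  ids <- unique(trajectories$particle_id)
  per <- lapply(ids, function(id) {
    tr <- trajectories[trajectories$particle_id == id, ]
    tr <- tr[order(tr$time_s), ]
    s <- tr$depth_mm - b
    lit <- s > 0
    cross <- which(lit[-length(lit)] != lit[-1])
    n_cr <- length(cross)
    # full-trajectory zone residence (sample-weighted)
    t_l <- mean(lit) * diff(range(tr$time_s))
    t_tot <- diff(range(tr$time_s))
    T_p <- NA_real_
    if (n_cr >= 3) {   # at least one complete cycle
      frac <- s[cross] / (s[cross] - s[cross + 1])
      ct <- tr$time_s[cross] + frac * (tr$time_s[cross + 1] - tr$time_s[cross])
      T_p <- mean(ct[seq(3, n_cr)] - ct[seq(1, n_cr - 2)])
    }
    data.frame(particle_id = id, T_s = T_p,
               phi = if (n_cr >= 1) t_l / t_tot else NA_real_,
               n_crossings = n_cr, t_l = t_l, t_total = t_tot)
  })
  per <- do.call(rbind, per)
  ok_T <- !is.na(per$T_s)
  ok_phi <- per$n_crossings >= 1
  mean_T <- if (any(ok_T)) mean(per$T_s[ok_T]) else NA_real_
  phi <- if (!any(ok_phi)) NA_real_
         else if (phi_method == "per_particle") mean(per$phi[ok_phi])
         else sum(per$t_l[ok_phi]) / sum(per$t_total[ok_phi])
  structure(list(
    mean_T_s = mean_T,
    f_hz = if (is.na(mean_T)) NA_real_ else 1 / mean_T,
    phi = phi,
    n_noncrossing = sum(per$n_crossings == 0),
    n_particles = length(ids),
    per_particle = per[, c("particle_id", "T_s", "phi", "n_crossings")]
  ), class = "pbr_ld_stats")
}

#' @export
print.pbr_ld_stats <- function(x, ...) {
  cat(sprintf(paste0("<pbr_ld_stats> T = %.3f s, f = %.3f Hz, phi = %.3f ",
                     "(%d of %d particles cycling)\n"),
              x$mean_T_s, x$f_hz, x$phi,
              x$n_particles - x$n_noncrossing, x$n_particles))
  invisible(x)
}
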