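#' Gridded 2-D cross-sectional flow field
#'
#' `pbr_flow_field` objects hold the liquid flow of one reactor
#' cross-section on a uniform Cartesian grid of cell centres:
#'
#' * `depth`, `lateral` — cell-centre coordinates (mm), `spacing` — cell
#'   size (mm);
#' * `u_depth`, `u_lateral` — liquid velocity components (m/s), matrices
#'   indexed `[depth, lateral]`;
#' * `k` — turbulent kinetic energy (cm^2/s^2), `eps` — dissipation rate
#'   (cm^2/s^3);
#' * `mask` — logical culture-region membership; masked-out cells carry
#'   zero velocity;
#' * `geom` — the [make_geometry()] cross-section.
#'
#' Velocity fields are always derived from a scalar streamfunction by
#' centred differencing, so the matching centred discrete divergence
#' vanishes identically (to round-off) at every cell whose four neighbours
#' are in the culture mask; see [divergence()].
#'
#' @name pbr_flow_field
NULL

new_flow_field <- function(geom, depth, lateral, spacing, u_depth, u_lateral,
                           k, eps, mask, gas_fraction = NULL) {
  stopifnot(all(dim(u_depth) == c(length(depth), length(lateral))))
  u_depth[!mask] <- 0; u_lateral[!mask] <- 0
  structure(list(
    geom = geom, depth = depth, lateral = lateral, spacing = spacing,
    u_depth = u_depth, u_lateral = u_lateral, k = k, eps = eps,
    mask = mask, gas_fraction = gas_fraction
  ), class = "pbr_flow_field")
}

#' @export
print.pbr_flow_field <- function(x, ...) {
  cat(sprintf("<pbr_flow_field> %d x %d cells, spacing %g mm (%s layout)\n",
              length(x$depth), length(x$lateral), x$spacing, x$geom$layout))
  sp <- sqrt(x$u_depth^2 + x$u_lateral^2)[x$mask]
  cat(sprintf("  peak speed %.4g m/s, mean TKE %.4g cm2/s2 over %d culture cells\n",
              max(sp), mean(x$k[x$mask]), sum(x$mask)))
  invisible(x)
}

# Symmetric cell-centre coordinates covering the outer disc plus a margin.
field_axes <- function(geom, spacing) {
  R <- geom$outer_radius
  n <- 2L * ceiling((R + 2 * spacing) / spacing)
  (seq_len(n) - (n + 1) / 2) * spacing
}

# Signed distance (mm) to the nearest culture wall, positive inside.
wall_distance <- function(geom, depth, lateral) {
  r <- sqrt(depth^2 + lateral^2)
  d <- geom$outer_radius - r
  if (geom$layout != "plain") {
    ri <- sqrt((depth - geom$inner_center_depth)^2 + lateral^2)
    d <- pmin(d, ri - geom$inner_radius)
  }
  if (isTRUE(geom$fillet_enabled)) d <- pmin(d, depth - geom$chord_depth)
  d
}

#' Build a flow field from a scalar streamfunction
#'
#' Evaluates `psi(depth, lateral)` on the cell-centre grid and recovers the
#' velocity by centred differences: `u_depth = d(psi)/d(lateral)`,
#' `u_lateral = -d(psi)/d(depth)`. Because mixed second differences
#' commute, the centred discrete divergence of the result is identically
#' zero wherever the stencil is available. With `wall_damp = TRUE` the
#' streamfunction is multiplied by a smoothstep of the wall distance so
#' that it is constant (zero) on every wall — the no-penetration
#' condition — before differencing.
#'
#' Units: with coordinates in mm, `psi` must be in m/s * mm for velocities
#' in m/s.
#'
#' @param geom A [make_geometry()] object.
#' @param psi Vectorised function of `(depth, lateral)` in mm.
#' @param spacing Grid spacing in mm (default 2).
#' @param wall_damp Impose no-penetration by wall damping (default `TRUE`).
#' @param damp_length Wall damping length scale in mm (default 6).
#' @param k,eps Background turbulence fields: scalars or matrices
#'   (cm^2/s^2 and cm^2/s^3).
#' @return A [pbr_flow_field] object.
#' @export
field_from_streamfunction <- function(geom, psi, spacing = 2,
                                      wall_damp = TRUE, damp_length = 6,
                                      k = 0, eps = 1e-6) {
  stopifnot(inherits(geom, "pbr_geometry"))
  if (2 * geom$outer_radius / spacing < 20)
    stop("grid spacing too coarse: need at least 20 cells across the outer diameter",
         call. = FALSE)
  ax <- field_axes(geom, spacing)
  nd <- length(ax); nl <- length(ax)
  dep <- matrix(ax, nd, nl)
  lat <- matrix(ax, nd, nl, byrow = TRUE)
  p <- psi(as.vector(dep), as.vector(lat))
  dim(p) <- c(nd, nl)
  if (wall_damp) {
    t <- pmin(1, pmax(0, wall_distance(geom, as.vector(dep), as.vector(lat)) /
                        damp_length))
    s <- t * t * (3 - 2 * t)
    dim(s) <- c(nd, nl)
    p <- p * s
  }
  ud <- ul <- matrix(0, nd, nl)
  i <- 2:(nd - 1); j <- 2:(nl - 1)
  ud[i, j] <- (p[i, j + 1] - p[i, j - 1]) / (2 * spacing)
  ul[i, j] <- -(p[i + 1, j] - p[i - 1, j]) / (2 * spacing)
  mask <- in_culture(geom, as.vector(dep), as.vector(lat))
  dim(mask) <- c(nd, nl)
  mask[c(1, nd), ] <- FALSE; mask[, c(1, nl)] <- FALSE
  if (length(k) == 1) k <- matrix(k, nd, nl)
  if (length(eps) == 1) eps <- matrix(eps, nd, nl)
  new_flow_field(geom, ax, ax, spacing, ud, ul, k, eps, mask)
}

#' Flow component specifications
#'
#' Parametric building blocks for synthetic cross-sectional flow:
#'
#' * `vortex_component()` — a Gaussian-core (Lamb--Oseen-like) vortex with
#'   streamfunction `strength * exp(-r^2 / (2 core^2))`; the swirl speed
#'   peaks at `r = core` with value `strength / core * exp(-1/2)` (m/s when
#'   `strength` is in m/s * mm). Positive `strength` rotates so that the
#'   flow above the centre points toward negative lateral.
#' * `jet_component()` — a dipole streamfunction producing a localised jet
#'   of speed `strength` (m/s) at `center`, directed `direction_deg`
#'   degrees from the horizontal (positive up the depth axis), with a
#'   Gaussian envelope of scale `core`.
#'
#' @param center Length-2 numeric, `(depth, lateral)` centre in mm.
#' @param strength Circulation scale (m/s * mm) or jet speed (m/s).
#' @param core Core radius in mm (> 0).
#' @param direction_deg Jet direction, degrees from horizontal toward the
#'   illuminated top; the lateral sign of the direction follows
#'   `sign(lateral_heading)`.
#' @param lateral_heading +1 for a jet with a positive-lateral heading, -1
#'   for negative (default +1).
#' @return A `pbr_flow_component` list.
#' @export
vortex_component <- function(center, strength, core) {
  stopifnot(length(center) == 2, core > 0)
  structure(list(kind = "vortex", center = as.numeric(center),
                 strength = strength, core = core),
            class = "pbr_flow_component")
}

#' @rdname vortex_component
#' @export
jet_component <- function(center, strength, core, direction_deg,
                          lateral_heading = 1) {
  stopifnot(length(center) == 2, core > 0)
  th <- direction_deg * pi / 180
  dir <- c(sin(th), sign(lateral_heading) * cos(th))  # (depth, lateral) unit
  structure(list(kind = "jet_plume", center = as.numeric(center),
                 strength = strength, core = core, direction = dir),
            class = "pbr_flow_component")
}

component_psi <- function(comp) {
  ctr <- comp$center; core <- comp$core
  switch(comp$kind,
    vortex = function(depth, lateral) {
      r2 <- (depth - ctr[1])^2 + (lateral - ctr[2])^2
      comp$strength * exp(-r2 / (2 * core^2))
    },
    jet_plume = function(depth, lateral) {
      dd <- depth - ctr[1]; dl <- lateral - ctr[2]
      # perpendicular offset so the curl at the centre points along `direction`
      perp <- -comp$direction[2] * dd + comp$direction[1] * dl
      comp$strength * perp * exp(-(dd^2 + dl^2) / (2 * core^2))
    },
    stop("unknown flow component kind: ", comp$kind, call. = FALSE))
}

#' Compose a divergence-free field from flow components
#'
#' Sums the streamfunctions of a list of [vortex_component()] /
#' [jet_component()] blocks and differentiates through
#' [field_from_streamfunction()], so the result inherits the discrete
#' divergence-free property and the no-penetration wall treatment.
#'
#' @param geom A [make_geometry()] object.
#' @param components Non-empty list of `pbr_flow_component` objects.
#' @inheritParams field_from_streamfunction
#' @return A [pbr_flow_field] object.
#' @export
compose_field <- function(geom, components, spacing = 2, wall_damp = TRUE,
                          damp_length = 6, k = 0, eps = 1e-6) {
  if (length(components) == 0)
    stop("`components` must contain at least one flow component", call. = FALSE)
  psis <- lapply(components, component_psi)
  psi <- function(depth, lateral) {
    out <- 0
    for (f in psis) out <- out + f(depth, lateral)
    out
  }
  field_from_streamfunction(geom, psi, spacing, wall_damp, damp_length, k, eps)
}

#' Centred discrete divergence of a flow field
#'
#' Computed with the same centred stencil used to derive the velocities
#' from the streamfunction; evaluated at cells whose four neighbours are
#' culture cells (so no masked-out zero velocity enters the stencil).
#'
#' @param field A [pbr_flow_field] object.
#' @return List with `div` (matrix, 1/s; `NA` where unavailable) and
#'   `max_abs_rel` — the largest |divergence| times the cell size divided
#'   by the peak speed, a dimensionless defect measure.
#' @export
divergence <- function(field) {
  nd <- length(field$depth); nl <- length(field$lateral)
  h <- field$spacing
  dv <- matrix(NA_real_, nd, nl)
  i <- 2:(nd - 1); j <- 2:(nl - 1)
  m <- field$mask
  ok <- m[i - 1, j] & m[i + 1, j] & m[i, j - 1] & m[i, j + 1] & m[i, j]
  d <- (field$u_depth[i + 1, j] - field$u_depth[i - 1, j]) / (2 * h) +
       (field$u_lateral[i, j + 1] - field$u_lateral[i, j - 1]) / (2 * h)
  d[!ok] <- NA
  dv[i, j] <- d
  peak <- max(sqrt(field$u_depth^2 + field$u_lateral^2))
  list(div = dv,
       max_abs_rel = if (peak > 0) max(abs(dv), na.rm = TRUE) * h / peak
                     else 0)
}

#' Bilinear interpolation of field quantities at arbitrary points
#'
#' @param field A [pbr_flow_field] object.
#' @param depth,lateral Point coordinates in mm.
#' @param what Character vector of field names to interpolate
#'   (default the two velocity components).
#' @return Matrix with one column per requested quantity.
#' @export
interp_field <- function(field, depth, lateral,
                         what = c("u_depth", "u_lateral")) {
  n <- max(length(depth), length(lateral))
  depth <- rep_len(depth, n); lateral <- rep_len(lateral, n)
  ax_d <- field$depth; ax_l <- field$lateral; h <- field$spacing
  fi <- (depth - ax_d[1]) / h
  fj <- (lateral - ax_l[1]) / h
  i0 <- pmin(pmax(floor(fi), 0), length(ax_d) - 2)
  j0 <- pmin(pmax(floor(fj), 0), length(ax_l) - 2)
  wi <- pmin(pmax(fi - i0, 0), 1); wj <- pmin(pmax(fj - j0, 0), 1)
  i0 <- i0 + 1L; j0 <- j0 + 1L   # 1-based corner
  nd <- length(ax_d)
  idx <- function(i, j) (j - 1L) * nd + i
  out <- vapply(what, function(nm) {
    m <- field[[nm]]
    m[idx(i0, j0)]     * (1 - wi) * (1 - wj) +
    m[idx(i0 + 1L, j0)]     * wi * (1 - wj) +
    m[idx(i0, j0 + 1L)]     * (1 - wi) * wj +
    m[idx(i0 + 1L, j0 + 1L)] * wi * wj
  }, numeric(n))
  if (n == 1L) out <- matrix(out, nrow = 1, dimnames = list(NULL, what))
  out
}
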