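#' Cross-section geometry of a tubular photobioreactor
#'
#' Builds the 2-D culture cross-section of a tubular photobioreactor (PBR).
#' Three layouts are supported: `"plain"` (a single tube; the culture region
#' is the full disc), `"concentric"` (an inner aeration tube coaxial with the
#' outer tube; the culture region is the annulus) and `"tangent"` (the inner
#' tube internally tangent to the outer tube at the bottom; an arc is removed
#' from the bottom of the inner tube and the opening closed by a flat panel).
#'
#' The coordinate frame has a *depth axis* (positive toward the illuminated
#' top of the outer tube) and a *lateral axis*; the origin sits on the axis
#' of the outer tube. Light enters from the top and travels straight down
#' the depth axis (normal incidence). All lengths are millimetres.
#'
#' For the tangent layout the removed arc (default 60 degrees, centred on the
#' bottom of the inner tube) plus its closing panel are modelled as a single
#' horizontal chord at the depth of the arc end points: everything below the
#' chord — the panel gap and the two cusp corners pinched between the inner
#' and outer walls — is excluded from the culture region. Set
#' `fillet_enabled = FALSE` to keep the full annular gap.
#'
#' @param layout One of `"plain"`, `"concentric"`, `"tangent"`.
#' @param outer_radius Outer tube radius in mm (default 100).
#' @param inner_radius Inner tube radius in mm (default 40; ignored for
#'   `"plain"`).
#' @param removed_arc_deg Angular width in degrees of the arc removed from
#'   the bottom of the inner tube (tangent layout only, default 60).
#' @param boundary_depth Depth-axis coordinate in mm of the horizontal
#'   light/dark interface (default 0, through the outer-tube axis).
#' @param fillet_enabled Logical; model the removed arc + panel closure for
#'   the tangent layout (default `TRUE`).
#'
#' @return An object of class `pbr_geometry`: a list with the arguments
#'   above plus `inner_center_depth` (0 for concentric, `-(outer_radius -
#'   inner_radius)` for tangent) and, when the fillet is active,
#'   `chord_depth`, the depth of the panel chord.
#'
#' @examples
#' geom <- make_geometry("tangent")
#' geom$inner_center_depth   # -60: internal tangency at the bottom
#' culture_area(geom)
#' @export
make_geometry <- function(layout = c("tangent", "concentric", "plain"),
                          outer_radius = 100, inner_radius = 40,
                          removed_arc_deg = 60, boundary_depth = 0,
                          fillet_enabled = TRUE) {
  layout <- match.arg(layout)
  if (!is.numeric(outer_radius) || outer_radius <= 0)
    stop("`outer_radius` must be a positive length in mm", call. = FALSE)
  if (layout != "plain") {
    if (!is.numeric(inner_radius) || inner_radius <= 0)
      stop("`inner_radius` must be a positive length in mm", call. = FALSE)
    if (inner_radius >= outer_radius)
      stop("invalid geometry: `inner_radius` must be smaller than `outer_radius`",
           call. = FALSE)
  }
  inner_center_depth <- switch(layout,
    plain      = NA_real_,
    concentric = 0,
    tangent    = -(outer_radius - inner_radius))
  geom <- structure(list(
    layout = layout,
    outer_radius = outer_radius,
    inner_radius = if (layout == "plain") NA_real_ else inner_radius,
    inner_center_depth = inner_center_depth,
    removed_arc_deg = if (layout == "tangent") removed_arc_deg else NA_real_,
    boundary_depth = boundary_depth,
    fillet_enabled = fillet_enabled && layout == "tangent"
  ), class = "pbr_geometry")
  if (geom$fillet_enabled) {
    # depth of the arc end points: the panel chord closing the removed arc
    half <- removed_arc_deg / 2 * pi / 180
    geom$chord_depth <- inner_center_depth - inner_radius * cos(half)
  }
  geom
}

#' @export
print.pbr_geometry <- function(x, ...) {
  cat("<pbr_geometry>", x$layout,
      sprintf("outer R = %g mm", x$outer_radius))
  if (x$layout != "plain")
    cat(sprintf(", inner R = %g mm at depth %g mm",
                x$inner_radius, x$inner_center_depth))
  cat(sprintf("\n  light/dark boundary at depth %g mm", x$boundary_depth))
  if (isTRUE(x$fillet_enabled))
    cat(sprintf("; panel chord at depth %.3f mm", x$chord_depth))
  cat("\n")
  invisible(x)
}

#' Test whether points lie in the culture region
#'
#' A point is in the culture region when it lies inside the outer disc,
#' outside the inner disc (for double-tube layouts) and, for the tangent
#' layout with the panel fillet active, above the panel chord.
#'
#' @param geom A [make_geometry()] object.
#' @param depth,lateral Numeric vectors of point coordinates in mm
#'   (recycled to a common length).
#' @return Logical vector.
#' @export
in_culture <- function(geom, depth, lateral) {
  stopifnot(inherits(geom, "pbr_geometry"))
  n <- max(length(depth), length(lateral))
  depth <- rep_len(depth, n); lateral <- rep_len(lateral, n)
  ok <- depth^2 + lateral^2 <= geom$outer_radius^2
  if (geom$layout != "plain") {
    ok <- ok & (depth - geom$inner_center_depth)^2 + lateral^2 >=
      geom$inner_radius^2
  }
  if (isTRUE(geom$fillet_enabled)) ok <- ok & depth >= geom$chord_depth
  ok
}

#' Depth below the illuminated surface along the light path
#'
#' Distance from a point to the outer wall measured straight up the depth
#' axis, i.e. the light path length from the illuminated top of the tube to
#' the point under normal (90 degree) incidence.
#'
#' @inheritParams in_culture
#' @return Numeric vector of depths in mm.
#' @export
depth_below_surface <- function(geom, depth, lateral) {
  stopifnot(inherits(geom, "pbr_geometry"))
  n <- max(length(depth), length(lateral))
  depth <- rep_len(depth, n); lateral <- rep_len(lateral, n)
  if (any(depth^2 + lateral^2 > geom$outer_radius^2 + 1e-9))
    stop("point outside the outer disc has no light-path depth", call. = FALSE)
  sqrt(pmax(0, geom$outer_radius^2 - lateral^2)) - depth
}

#' Light or dark zone of points in the culture region
#'
#' The light/dark interface is the horizontal line at
#' `geom$boundary_depth`; points above it (larger depth-axis coordinate,
#' nearer the illuminated top) are in the light zone.
#'
#' @inheritParams in_culture
#' @return Character vector, `"light"` or `"dark"`.
#' @export
zone_of <- function(geom, depth, lateral) {
  stopifnot(inherits(geom, "pbr_geometry"))
  n <- max(length(depth), length(lateral))
  depth <- rep_len(depth, n); lateral <- rep_len(lateral, n)
  if (!all(in_culture(geom, depth, lateral)))
    stop("zone_of() is defined only inside the culture region", call. = FALSE)
  ifelse(depth > geom$boundary_depth, "light", "dark")
}

# Uniform cell-centre quadrature grid over the bounding box of the outer
# disc; `spacing` in mm. Returns data.frame of culture cell centres.
culture_grid <- function(geom, spacing) {
  R <- geom$outer_radius
  n <- 2L * ceiling(R / spacing)
  ctr <- (seq_len(n) - (n + 1) / 2) * spacing
  g <- expand.grid(depth = ctr, lateral = ctr, KEEP.OUT.ATTRS = FALSE)
  g[in_culture(geom, g$depth, g$lateral), , drop = FALSE]
}

#' Area of the culture region
#'
#' Numerical area by uniform cell-centre counting. For the plain disc and
#' the concentric annulus this agrees with the closed forms
#' \eqn{\pi R^2} and \eqn{\pi (R^2 - r^2)} to better than 0.1% at the
#' default spacing.
#'
#' @param geom A [make_geometry()] object.
#' @param spacing Quadrature cell size in mm (default `outer_radius / 500`).
#' @return Area in mm^2.
#' @export
culture_area <- function(geom, spacing = geom$outer_radius / 500) {
  stopifnot(inherits(geom, "pbr_geometry"))
  nrow(culture_grid(geom, spacing)) * spacing^2
}

#' Light-to-dark area ratio for a given light penetration depth
#'
#' Splits the culture region at a light penetration depth: cells whose
#' light-path depth ([depth_below_surface()]) is smaller than
#' `penetration_depth` form the light area; the rest is dark. Returns
#' light area / dark area. If the dark area vanishes (light reaches
#' everywhere) the ratio is `Inf`.
#'
#' @param geom A [make_geometry()] object.
#' @param penetration_depth Light penetration depth in mm (> 0).
#' @param spacing Quadrature cell size in mm.
#' @return Dimensionless ratio (possibly `Inf`).
#' @export
light_dark_area_ratio <- function(geom, penetration_depth,
                                  spacing = geom$outer_radius / 500) {
  stopifnot(inherits(geom, "pbr_geometry"))
  if (!is.numeric(penetration_depth) || penetration_depth <= 0)
    stop("`penetration_depth` must be a positive length in mm", call. = FALSE)
  g <- culture_grid(geom, spacing)
  lit <- depth_below_surface(geom, g$depth, g$lateral) < penetration_depth
  n_dark <- sum(!lit)
  if (n_dark == 0L) return(Inf)
  sum(lit) / n_dark
}
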