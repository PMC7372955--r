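#' Aeration specification
#'
#' Describes how the inner tube sparges gas into the culture: jet direction,
#' aeration rate and pore layout. The tangent double-tube layout carries two
#' mirror-symmetric rows of pores on the sides of the inner tube with a
#' configurable jet direction; the concentric layout carries a single row on
#' one side, canted 45 degrees downwards.
#'
#' @param direction_deg Signed jet angle from the horizontal in degrees
#'   (positive up the depth axis, negative down). The reactor studies here
#'   use +60, +30, 0, -20 and -30 for the tangent layout.
#' @param rate_vvm Aeration rate in gas volumes per culture volume per
#'   minute (1/min).
#' @param pore_diameter_mm Pore diameter in mm (default 5).
#' @param pores_per_row Number of pores along the tube per row (default 4,
#'   one every 250 mm of a 1 m tube).
#' @param n_rows Number of pore rows (default 2 for tangent, 1 for
#'   concentric; set explicitly to override).
#' @param tube_length_mm Axial tube length used for the vvm conversion
#'   (default 1000).
#' @return An `pbr_aeration` list.
#' @export
aeration_spec <- function(direction_deg = -30, rate_vvm = 0.7,
                          pore_diameter_mm = 5, pores_per_row = 4,
                          n_rows = 2, tube_length_mm = 1000) {
  stopifnot(rate_vvm >= 0, pore_diameter_mm > 0,
            pores_per_row >= 1, n_rows >= 1, tube_length_mm > 0)
  structure(list(direction_deg = direction_deg, rate_vvm = rate_vvm,
                 pore_diameter_mm = pore_diameter_mm,
                 pores_per_row = pores_per_row, n_rows = n_rows,
                 tube_length_mm = tube_length_mm),
            class = "pbr_aeration")
}

#' Pore sites and jet directions on the inner tube
#'
#' Tangent layout: two pore sites on the lateral sides of the inner tube,
#' mirror-symmetric about the vertical plane, with jets at
#' `spec$direction_deg` from horizontal pointing away from the tube.
#' Concentric layout: a single site on one side (negative lateral), canted
#' 45 degrees downwards.
#'
#' @param geom A [make_geometry()] object with an inner tube.
#' @param spec An [aeration_spec()] object.
#' @return Data frame with columns `depth`, `lateral` (mm),
#'   `direction_deg` and `lateral_heading` (+1/-1, the lateral sign of the
#'   jet direction).
#' @export
pore_layout <- function(geom, spec) {
  stopifnot(inherits(geom, "pbr_geometry"), inherits(spec, "pbr_aeration"))
  if (geom$layout == "plain")
    stop("the plain layout has no inner tube to aerate", call. = FALSE)
  cd <- geom$inner_center_depth; ri <- geom$inner_radius
  if (geom$layout == "tangent") {
    data.frame(depth = c(cd, cd), lateral = c(ri, -ri),
               direction_deg = rep(spec$direction_deg, 2),
               lateral_heading = c(1, -1))
  } else {
    # one row on one side, canted downwards by 45 degrees
    s <- sqrt(0.5)
    data.frame(depth = cd - ri * s, lateral = -ri * s,
               direction_deg = -45, lateral_heading = -1)
  }
}

#' Convert an aeration rate in vvm to a pore jet speed
#'
#' The volumetric gas flow is `rate_vvm` times the culture volume per
#' minute, with culture volume = cross-section area times tube length;
#' dividing by the total pore cross-sectional area gives the superficial
#' jet speed at the pores.
#'
#' @param spec An [aeration_spec()] object.
#' @param culture_area_mm2 Culture cross-section area in mm^2.
#' @return Jet speed in m/s.
#' @examples
#' geom <- make_geometry("concentric")
#' spec <- aeration_spec(rate_vvm = 0.7, n_rows = 1)
#' vvm_to_jet_speed(spec, culture_area(geom))  # ~3.9 m/s
#' @export
vvm_to_jet_speed <- function(spec, culture_area_mm2) {
  stopifnot(inherits(spec, "pbr_aeration"))
  if (!is.numeric(culture_area_mm2) || culture_area_mm2 <= 0)
    stop("`culture_area_mm2` must be positive", call. = FALSE)
  n_pores <- spec$pores_per_row * spec$n_rows
  pore_area_m2 <- n_pores * pi * (spec$pore_diameter_mm / 2 / 1000)^2
  if (pore_area_m2 <= 0)
    stop("total pore area is zero; check the pore configuration", call. = FALSE)
  volume_m3 <- culture_area_mm2 * 1e-6 * spec$tube_length_mm * 1e-3
  (spec$rate_vvm * volume_m3 / 60) / pore_area_m2
}
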