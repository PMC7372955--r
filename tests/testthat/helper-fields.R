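# Fixture builders shared across the suite. Everything is generated in
# code; no stored data.

plain_geom <- function(R = 100) make_geometry("plain", outer_radius = R)

tangent_geom <- function(...) make_geometry("tangent", ...)

# solid-body rotation at angular velocity omega (rad/s): speed omega * r
# with r in metres, i.e. psi = -omega r^2 / 2 scaled mm -> m
solid_body_field <- function(omega, geom = plain_geom(), spacing = 2,
                             k = 0, eps = 1e-6) {
  field_from_streamfunction(
    geom, function(d, l) -omega * (d^2 + l^2) / 2 / 1000,
    spacing = spacing, wall_damp = FALSE, k = k, eps = eps)
}

# spatially uniform flow (m/s) via a linear streamfunction
uniform_field <- function(u_depth, u_lateral = 0, geom = plain_geom(),
                          spacing = 2, k = 0, eps = 1e-6) {
  field_from_streamfunction(
    geom, function(d, l) u_depth * l - u_lateral * d,
    spacing = spacing, wall_damp = FALSE, k = k, eps = eps)
}

# reproducible random multi-vortex field
random_vortex_field <- function(seed, geom = plain_geom(), n = 5,
                                spacing = 2) {
  set.seed(seed)
  comps <- lapply(seq_len(n), function(i) {
    vortex_component(center = runif(2, -50, 50),
                     strength = runif(1, -0.5, 0.5),
                     core = runif(1, 8, 20))
  })
  fld <- compose_field(geom, comps, spacing = spacing)
  fld$k <- matrix(runif(length(fld$k), 0, 100), nrow(fld$k))
  fld$eps <- matrix(runif(length(fld$eps), 1, 10), nrow(fld$eps))
  fld
}

# laterally mirrored copy of a field (u_depth even, u_lateral odd under
# reflection)
mirror_field <- function(field) {
  flip <- function(m) m[, rev(seq_len(ncol(m)))]
  field$u_depth <- flip(field$u_depth)
  field$u_lateral <- -flip(field$u_lateral)
  field$k <- flip(field$k)
  field$eps <- flip(field$eps)
  field$mask <- flip(field$mask)
  field
}

# default tangent scenario cached per test file run
tangent_scenario <- local({
  cache <- new.env()
  function(direction_deg = -30, rate_vvm = 0.7) {
    key <- paste(direction_deg, rate_vvm)
    if (is.null(cache[[key]]))
      cache[[key]] <- default_scenario(
        tangent_geom(), aeration_spec(direction_deg = direction_deg,
                                      rate_vvm = rate_vvm))
    cache[[key]]
  }
})
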