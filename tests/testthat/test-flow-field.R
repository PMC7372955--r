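test_that("streamfunction differencing recovers solid-body rotation", {
  omega <- 2
  fld <- solid_body_field(omega)
  nd <- length(fld$depth)
  dep <- matrix(fld$depth, nd, nd)
  lat <- matrix(fld$lateral, nd, nd, byrow = TRUE)
  r <- sqrt(dep^2 + lat^2)
  sel <- fld$mask & r > 20 & r < 80
  speed <- sqrt(fld$u_depth^2 + fld$u_lateral^2)
  expect_lt(max(abs(speed[sel] - omega * r[sel] / 1000) /
                (omega * r[sel] / 1000)), 0.01)
})

test_that("generated fields are discretely divergence-free", {
  for (fld in list(
    compose_field(plain_geom(), list(vortex_component(c(10, -20), 0.4, 15))),
    random_vortex_field(3),
    tangent_scenario())) {
    expect_lt(divergence(fld)$max_abs_rel, 1e-6)
    expect_true(all(fld$u_depth[!fld$mask] == 0))
    expect_true(all(fld$u_lateral[!fld$mask] == 0))
    expect_true(all(is.finite(fld$u_depth)), all(is.finite(fld$u_lateral)))
  }
})

test_that("a mirror vortex pair has symmetric u_depth and antisymmetric u_lateral", {
  fld <- compose_field(plain_geom(), list(
    vortex_component(c(0,  40), -0.3, 14),
    vortex_component(c(0, -40),  0.3, 14)))
  flip <- function(m) m[, rev(seq_len(ncol(m)))]
  expect_equal(fld$u_depth, flip(fld$u_depth), tolerance = 1e-12)
  expect_equal(fld$u_lateral, -flip(fld$u_lateral), tolerance = 1e-12)
})

test_that("too coarse a grid is rejected", {
  expect_error(compose_field(plain_geom(),
                             list(vortex_component(c(0, 0), 1, 30)),
                             spacing = 15), "coarse")
})

test_that("field tables round-trip bit-exactly and validate their input", {
  fld <- random_vortex_field(11, spacing = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_field_table(fld, path)
  back <- read_field_table(path, fld$geom)
  for (nm in c("depth", "lateral", "u_depth", "u_lateral", "k", "eps"))
    expect_identical(unname(back[[nm]]), unname(fld[[nm]]))
  expect_identical(back$mask, fld$mask)

  # missing column is reported by name
  tab <- utils::read.csv(path)
  tab$eps_cm2_s3 <- NULL
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, p2, row.names = FALSE)
  expect_error(read_field_table(p2), "eps_cm2_s3")

  # ragged grid rejected
  utils::write.csv(utils::read.csv(path)[-3, ], p2, row.names = FALSE)
  expect_error(read_field_table(p2), "rectangular")

  # non-numeric cell reported with its row
  tab <- utils::read.csv(path, colClasses = "character")
  tab$u_depth_m_s[5] <- "fast"
  utils::write.csv(tab, p2, row.names = FALSE)
  expect_error(read_field_table(p2), "row 5")
})

test_that("a hand-written table of zeros reads as a stagnant field", {
  path <- withr::local_tempfile(fileext = ".csv")
  g <- expand.grid(lateral_mm = c(-2, 0, 2), depth_mm = c(-2, 0, 2))
  df <- data.frame(depth_mm = g$depth_mm, lateral_mm = g$lateral_mm,
                   u_depth_m_s = 0, u_lateral_m_s = 0, k_cm2_s2 = 0,
                   eps_cm2_s3 = 1e-6)
  utils::write.csv(df, path, row.names = FALSE)
  fld <- read_field_table(path, plain_geom(10))
  expect_true(all(fld$u_depth == 0) && all(fld$u_lateral == 0))
  expect_true(all(fld$mask))   # 3 x 3 patch near the axis is culture
})

test_that("scenario calibration hits the monitoring-line peak and mean TKE", {
  targets <- list(`0.3` = 0.0393, `0.7` = 0.045, `1` = 0.049)
  for (rate in names(targets)) {
    fld <- tangent_scenario(-30, as.numeric(rate))
    pk <- max(abs(c(vr_profile(fld, 40)$v_r, vr_profile(fld, -40)$v_r)))
    expect_equal(pk, targets[[rate]], tolerance = 0.02)
    scn <- attr(fld, "scenario")
    expect_equal(tke_mean(fld), scn$mean_tke_target, tolerance = 0.02)
    expect_true(all(fld$k[fld$mask] >= 0), all(fld$eps[fld$mask] > 0))
  }
  conc <- default_scenario(make_geometry("concentric"),
                           aeration_spec(-45, 0.7, n_rows = 1))
  pk <- max(abs(c(vr_profile(conc, 40)$v_r, vr_profile(conc, -40)$v_r)))
  expect_equal(pk, 0.047, tolerance = 0.02)
  expect_equal(tke_mean(conc), 54, tolerance = 0.02)
})

test_that("unreachable calibration raises a calibration error", {
  g <- tangent_geom()
  expect_error(default_scenario(g, aeration_spec(-30, rate_vvm = 0),
                                peak_vr = 0.04),
               "calibration")
})

test_that("near-wall flow is suppressed relative to the pore region", {
  for (fld in list(tangent_scenario(-30, 0.7), tangent_scenario(-30, 0.3))) {
    m40 <- mean(abs(c(vr_profile(fld, 40)$v_r, vr_profile(fld, -40)$v_r)))
    m85 <- mean(abs(c(vr_profile(fld, 85)$v_r, vr_profile(fld, -85)$v_r)))
    expect_gt(m40 / m85, 5)
  }
})

test_that("upward aeration starves the dark zone relative to downward", {
  g <- tangent_geom()
  comp_up <- pbrflash:::scenario_components(g, aeration_spec(60, 0.3))
  comp_dn <- pbrflash:::scenario_components(g, aeration_spec(-30, 0.3))
  f_up <- compose_field(g, comp_up)
  f_dn <- compose_field(g, comp_dn)
  dark <- pbrflash:::region_mask(f_up, "dark")
  sp <- function(f) mean(sqrt(f$u_depth^2 + f$u_lateral^2)[dark])
  expect_lt(sp(f_up), sp(f_dn))
})

test_that("field metrics are invariant under lateral mirroring", {
  fld <- tangent_scenario(-30, 0.7)
  mir <- mirror_field(fld)
  expect_equal(mean_abs_cos_alpha(fld)$mean_abs_cos_alpha,
               mean_abs_cos_alpha(mir)$mean_abs_cos_alpha, tolerance = 1e-9)
  expect_equal(tke_mean(fld), tke_mean(mir), tolerance = 1e-9)
  expect_equal(dead_zone_fraction(fld), dead_zone_fraction(mir),
               tolerance = 1e-9)
})
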