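test_that("synergy map matches aligned, orthogonal and 3-4-5 flows", {
  aligned <- uniform_field(0.03, 0)
  expect_equal(unique(na.omit(as.vector(cos_alpha_field(aligned)))), 1)
  ortho <- uniform_field(0, 0.05)
  expect_equal(unique(na.omit(as.vector(cos_alpha_field(ortho)))), 0)
  diag <- uniform_field(0.03, 0.04)
  expect_equal(unique(round(na.omit(as.vector(cos_alpha_field(diag))), 12)),
               0.6)
  expect_error(cos_alpha_field(diag, light_direction = c(0, 0)), "nonzero")
})

test_that("synergy is bounded and invariant under velocity rescaling", {
  fld <- random_vortex_field(21)
  ca <- cos_alpha_field(fld)
  vals <- na.omit(as.vector(ca))
  expect_true(all(vals >= 0 & vals <= 1))
  scaled <- fld
  scaled$u_depth <- 7.3 * scaled$u_depth
  scaled$u_lateral <- 7.3 * scaled$u_lateral
  ca2 <- cos_alpha_field(scaled)
  both <- !is.na(ca) & !is.na(ca2)   # cells within tol of stagnant may flip
  expect_equal(ca2[both], ca[both], tolerance = 1e-12)
  expect_gt(mean(both, na.rm = TRUE), 0)
})

test_that("area means agree with brute-force per-cell loops", {
  fld <- random_vortex_field(8)
  ca <- cos_alpha_field(fld)
  acc <- n <- 0; acc_k <- n_k <- 0
  for (i in seq_along(fld$depth)) for (j in seq_along(fld$lateral)) {
    if (fld$mask[i, j]) {
      acc_k <- acc_k + fld$k[i, j]; n_k <- n_k + 1
      if (!is.na(ca[i, j])) { acc <- acc + ca[i, j]; n <- n + 1 }
    }
  }
  expect_equal(mean_abs_cos_alpha(fld)$mean_abs_cos_alpha, acc / n,
               tolerance = 1e-12)
  expect_equal(tke_mean(fld), acc_k / n_k, tolerance = 1e-12)
})

test_that("half-and-half constructed fields average as expected", {
  fld <- uniform_field(0, 0)
  lat_neg <- fld$lateral < 0
  fld$u_depth[, lat_neg] <- 0.03      # aligned half: |cos a| = 1
  fld$u_lateral[, !lat_neg] <- 0.05   # orthogonal half: |cos a| = 0
  fld$u_depth[!fld$mask] <- 0; fld$u_lateral[!fld$mask] <- 0
  expect_equal(mean_abs_cos_alpha(fld)$mean_abs_cos_alpha, 0.5,
               tolerance = 1e-6)
  fld$k[] <- ifelse(col(fld$k) %in% which(lat_neg), 100, 0)
  expect_equal(tke_mean(fld), 50, tolerance = 1e-6)
  expect_equal(dead_zone_fraction(uniform_field(0, 0)), 1)
  expect_equal(dead_zone_fraction(uniform_field(0.05, 0)), 0)
  expect_equal(dead_zone_fraction(fld), 0, tolerance = 1e-6)  # both halves move
})

test_that("monitoring-line profiles sample the vertical velocity component", {
  fld <- uniform_field(0.02, 0)
  pr <- vr_profile(fld, 40)
  # interpolation at the extreme ends of the line draws on zeroed
  # outside-culture cells; interior samples carry the uniform value
  interior <- abs(pr$depth) < max(abs(pr$depth)) - 2 * fld$spacing
  expect_true(all(abs(pr$v_r[interior] - 0.02) < 1e-9))
  expect_true(all(abs(pr$abs_cos_alpha[interior] - 1) < 1e-9))

  pair <- compose_field(plain_geom(), list(
    vortex_component(c(0,  40), -0.3, 14),
    vortex_component(c(0, -40),  0.3, 14)), wall_damp = FALSE)
  expect_lt(max(abs(vr_profile(pair, 40)$v_r - vr_profile(pair, -40)$v_r)),
            1e-12)

  omega <- 3
  sb <- solid_body_field(omega)
  pr <- vr_profile(sb, 40)
  inner <- abs(pr$depth) < 70   # away from the wall-adjacent cells
  expect_lt(max(abs(abs(pr$v_r[inner]) - omega * 0.040) / (omega * 0.040)),
            0.01)

  expect_error(vr_profile(fld, 150), "outside")
})

test_that("square-wave trajectories give T = 0.5 s, f = 2 Hz, phi = 0.5", {
  t <- seq(0, 20, by = 0.05)
  depth <- ifelse(floor((t + 0.125) / 0.25) %% 2 == 0, 5, -5)
  traj <- data.frame(particle_id = 1L, time_s = t, depth_mm = depth,
                     lateral_mm = 0)
  ld <- ld_cycle_stats(traj, plain_geom())
  expect_equal(ld$mean_T_s, 0.5, tolerance = 1e-6)
  expect_equal(ld$f_hz, 2, tolerance = 1e-6)
  expect_equal(ld$phi, 0.5, tolerance = 0.01)
  expect_equal(ld$f_hz * ld$mean_T_s, 1)
})

test_that("a tracer on solid-body rotation crosses the diameter twice per turn", {
  # omega = pi rad/s: period 2 s, boundary crossed twice per revolution
  t <- seq(0, 20, by = 0.1)
  traj <- data.frame(particle_id = 1L, time_s = t,
                     depth_mm = 40 * sin(pi * (t + 0.037)),
                     lateral_mm = 40 * cos(pi * (t + 0.037)))
  ld <- ld_cycle_stats(traj, plain_geom())
  expect_equal(ld$mean_T_s, 2, tolerance = 1e-3)
  expect_equal(ld$f_hz, 0.5, tolerance = 1e-3)
  expect_equal(ld$phi, 0.5, tolerance = 0.01)
})

test_that("non-crossing particles are excluded and counted", {
  t <- seq(0, 10, by = 0.1)
  traj <- rbind(
    data.frame(particle_id = 1L, time_s = t,
               depth_mm = 30 * sin(2 * pi * (t + 0.02)), lateral_mm = 0),
    data.frame(particle_id = 2L, time_s = t, depth_mm = -50, lateral_mm = 0))
  ld <- ld_cycle_stats(traj, plain_geom())
  expect_equal(ld$n_noncrossing, 1)
  expect_equal(nrow(ld$per_particle), 2)
  expect_true(is.na(ld$per_particle$T_s[2]))
  expect_equal(ld$f_hz, 1, tolerance = 1e-2)   # stats over the cycling particle
  expect_error(ld_cycle_stats(traj[0, ], plain_geom()), "non-empty")
})

test_that("cycle statistics transform correctly under mirroring and replay speed", {
  set.seed(5)
  t <- seq(0, 30, by = 0.1)
  depth <- 20 * sin(0.7 * t) + cumsum(rnorm(length(t), 0, 0.8))
  traj <- data.frame(particle_id = 1L, time_s = t, depth_mm = depth,
                     lateral_mm = 0)
  ld <- ld_cycle_stats(traj, plain_geom())

  mirrored <- transform(traj, depth_mm = -depth_mm)
  expect_equal(ld_cycle_stats(mirrored, plain_geom())$phi, 1 - ld$phi,
               tolerance = 1e-9)

  faster <- transform(traj, time_s = time_s / 2)
  ld2 <- ld_cycle_stats(faster, plain_geom())
  expect_equal(ld2$f_hz, 2 * ld$f_hz, tolerance = 1e-9)
  expect_equal(ld2$phi, ld$phi, tolerance = 1e-9)
})

test_that("crossing counts are invariant under linear-interpolation refinement", {
  set.seed(9)
  t <- seq(0, 30, by = 0.2)
  depth <- 15 * sin(0.9 * t) + cumsum(rnorm(length(t), 0, 1.1))
  refine <- function(t, x) {
    tm <- (t[-1] + t[-length(t)]) / 2
    xm <- (x[-1] + x[-length(x)]) / 2
    ord <- order(c(t, tm))
    list(t = c(t, tm)[ord], x = c(x, xm)[ord])
  }
  fine <- refine(t, depth)
  ld1 <- ld_cycle_stats(data.frame(particle_id = 1L, time_s = t,
                                   depth_mm = depth, lateral_mm = 0),
                        plain_geom())
  ld2 <- ld_cycle_stats(data.frame(particle_id = 1L, time_s = fine$t,
                                   depth_mm = fine$x, lateral_mm = 0),
                        plain_geom())
  expect_identical(ld1$per_particle$n_crossings, ld2$per_particle$n_crossings)
  expect_equal(ld1$mean_T_s, ld2$mean_T_s, tolerance = 1e-9)
})
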