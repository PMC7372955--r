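#!/usr/bin/env Rscript
# Generate the calibrated synthetic cross-sectional flow fields and verify
# their construction guarantees: monitoring-line peak vertical velocity,
# culture-mean turbulent kinetic energy, divergence-free velocities, and
# near-wall suppression (flow an order of magnitude weaker on the +-85 mm
# lines than near the aeration pores at +-40 mm).

suppressPackageStartupMessages(library(pbrflash))
dir.create("results", showWarnings = FALSE)

geom <- make_geometry("tangent")
rows <- list()
for (rate in c(0.3, 0.7, 1.0)) {
  fld <- default_scenario(geom, aeration_spec(direction_deg = -30,
                                              rate_vvm = rate))
  scn <- attr(fld, "scenario")
  m40 <- mean(abs(c(vr_profile(fld, 40)$v_r, vr_profile(fld, -40)$v_r)))
  m85 <- mean(abs(c(vr_profile(fld, 85)$v_r, vr_profile(fld, -85)$v_r)))
  rows[[length(rows) + 1]] <- data.frame(
    layout = "tangent", rate_vvm = rate,
    peak_vr_target_m_s = scn$peak_vr_target,
    peak_vr_achieved_m_s = round(scn$peak_vr_achieved, 5),
    mean_tke_target = scn$mean_tke_target,
    mean_tke_achieved = round(scn$mean_tke_achieved, 3),
    wall_suppression = round(m40 / m85, 1),
    max_rel_divergence = signif(divergence(fld)$max_abs_rel, 2),
    dead_zone_fraction = round(dead_zone_fraction(fld), 3))
}
conc <- default_scenario(make_geometry("concentric"),
                         aeration_spec(direction_deg = -45, rate_vvm = 0.7,
                                       n_rows = 1))
scn <- attr(conc, "scenario")
rows[[length(rows) + 1]] <- data.frame(
  layout = "concentric", rate_vvm = 0.7,
  peak_vr_target_m_s = scn$peak_vr_target,
  peak_vr_achieved_m_s = round(scn$peak_vr_achieved, 5),
  mean_tke_target = scn$mean_tke_target,
  mean_tke_achieved = round(scn$mean_tke_achieved, 3),
  wall_suppression = NA,
  max_rel_divergence = signif(divergence(conc)$max_abs_rel, 2),
  dead_zone_fraction = round(dead_zone_fraction(conc), 3))

tab <- do.call(rbind, rows)
print(tab, row.names = FALSE)
write.csv(tab, "results/field_calibration.csv", row.names = FALSE)
cat("\nall calibration targets hit by construction; wrote results/field_calibration.csv\n")
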