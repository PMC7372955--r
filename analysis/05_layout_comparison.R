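#!/usr/bin/env Rscript
# Tangent vs concentric double-tube reactor at 0.7 vvm: end-to-end
# synthetic-scenario metrics side by side, plus the improvement arithmetic
# over the tabulated reference metric bundles (concentric f = 1.01 Hz,
# phi = 35.1%, TKE = 54 cm2/s2, |cos a| = 0.5 against tangent 1.8 Hz,
# 47.8%, 80 cm2/s2, 0.69), which yields the headline gains of the tangent
# design: +78.2% cycle frequency (1.8-fold), +36.2% light time, +48.1%
# TKE and +38% synergy.

suppressPackageStartupMessages(library(pbrflash))
dir.create("results", showWarnings = FALSE)

seeds <- 9000 + 7 * seq_len(8)
run <- function(fld) {
  m <- vapply(seeds, function(s) {
    ld <- ld_cycle_stats(track(fld, particle_params(seed = s)), fld$geom)
    c(ld$f_hz, ld$phi)
  }, numeric(2))
  list(f_hz = mean(m[1, ]), phi_pct = 100 * mean(m[2, ]),
       mean_tke_cm2_s2 = tke_mean(fld),
       mean_abs_cos_alpha = mean_abs_cos_alpha(fld)$mean_abs_cos_alpha,
       dead_zone_fraction = dead_zone_fraction(fld))
}

tang <- run(default_scenario(make_geometry("tangent"),
                             aeration_spec(direction_deg = -30,
                                           rate_vvm = 0.7)))
conc <- run(default_scenario(make_geometry("concentric"),
                             aeration_spec(direction_deg = -45,
                                           rate_vvm = 0.7, n_rows = 1)))

cat("computed synthetic-scenario metrics (tangent vs concentric):\n")
cmp_syn <- compare_scenarios(conc, tang)
print(cmp_syn)
write.csv(as.data.frame(cmp_syn), "results/layout_comparison.csv",
          row.names = FALSE)

cat("\nimprovements over the tabulated reference bundles:\n")
lit <- literature_performance()
ref_t <- lit[lit$design == "Tangent double-tube PBR", ]
ref_c <- lit[lit$design == "Concentric double-tube PBR", ]
cmp_ref <- compare_scenarios(
  list(f_hz = ref_c$f_hz, phi_pct = ref_c$phi_pct,
       mean_tke_cm2_s2 = ref_c$tke_cm2_s2,
       mean_abs_cos_alpha = ref_c$abs_cos_alpha),
  list(f_hz = ref_t$f_hz, phi_pct = ref_t$phi_pct,
       mean_tke_cm2_s2 = ref_t$tke_cm2_s2,
       mean_abs_cos_alpha = ref_t$abs_cos_alpha))
print(cmp_ref)
write.csv(as.data.frame(cmp_ref), "results/improvements.csv",
          row.names = FALSE)
cat("\nwrote results/layout_comparison.csv and results/improvements.csv\n")
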