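#' Pairwise comparison arithmetic
#'
#' `percent_change()` returns `100 * (new - baseline) / baseline`;
#' `fold_ratio()` returns `new / baseline`. Both report full precision;
#' display rounding (one decimal, the convention used in reactor
#' comparison tables) is applied by [compare_scenarios()] formatting.
#'
#' @param baseline,new Numeric scalars; `baseline` must be nonzero.
#' @return Numeric scalar.
#' @examples
#' percent_change(54, 80)   # 48.1% TKE enhancement
#' fold_ratio(1.01, 1.8)    # 1.8-fold cycle-frequency gain
#' @export
percent_change <- function(baseline, new) {
  if (!is.finite(baseline) || baseline == 0)
    stop("undefined comparison: baseline must be finite and nonzero",
         call. = FALSE)
  100 * (new - baseline) / baseline
}

#' @rdname percent_change
#' @export
fold_ratio <- function(baseline, new) {
  if (!is.finite(baseline) || baseline == 0)
    stop("undefined comparison: baseline must be finite and nonzero",
         call. = FALSE)
  new / baseline
}

#' Bundle the evaluation metrics of one scenario
#'
#' Runs the metric layer over a (synthetic or externally supplied) flow
#' field and a set of particle trajectories and gathers the headline
#' numbers used to rank reactor designs.
#'
#' @param field A [pbr_flow_field] object.
#' @param trajectories Data frame from [track()], or `NULL` to skip the
#'   cycle statistics.
#' @param id Free-form scenario identifier list (stored as-is).
#' @return `pbr_scenario_report`: list with `id`, `metrics` (named list:
#'   `f_hz`, `phi_pct`, `mean_T_s`, `mean_tke_cm2_s2`,
#'   `mean_abs_cos_alpha`, `dead_zone_fraction`, `n_noncrossing`) and
#'   `provenance`.
#' @export
scenario_report <- function(field, trajectories = NULL, id = list()) {
  stopifnot(inherits(field, "pbr_flow_field"))
  syn <- mean_abs_cos_alpha(field)
  metrics <- list(
    f_hz = NA_real_, phi_pct = NA_real_, mean_T_s = NA_real_,
    mean_tke_cm2_s2 = tke_mean(field),
    mean_abs_cos_alpha = syn$mean_abs_cos_alpha,
    dead_zone_fraction = dead_zone_fraction(field),
    n_noncrossing = NA_integer_)
  if (!is.null(trajectories)) {
    ld <- ld_cycle_stats(trajectories, field$geom)
    metrics$f_hz <- ld$f_hz
    metrics$phi_pct <- 100 * ld$phi
    metrics$mean_T_s <- ld$mean_T_s
    metrics$n_noncrossing <- ld$n_noncrossing
  }
  scn <- attr(field, "scenario")
  structure(list(id = if (length(id)) id else scn, metrics = metrics,
                 provenance = if (is.null(scn)) "external" else "synthetic"),
            class = "pbr_scenario_report")
}

#' @export
print.pbr_scenario_report <- function(x, ...) {
  cat("<pbr_scenario_report>\n")
  m <- x$metrics
  cat(sprintf("  f = %.3g Hz, phi = %.3g%%, TKE = %.3g cm2/s2, |cos a| = %.3g, dead zone = %.3g\n",
              m$f_hz, m$phi_pct, m$mean_tke_cm2_s2, m$mean_abs_cos_alpha,
              m$dead_zone_fraction))
  invisible(x)
}

comparable_metrics <- c("mean_abs_cos_alpha", "mean_tke_cm2_s2", "f_hz",
                        "phi_pct", "dead_zone_fraction")

#' Compare two scenario reports metric by metric
#'
#' Per-metric percent change and fold ratio of `new` over `baseline`,
#' in the conventional comparison-table column order (synergy, TKE, cycle
#' frequency, light-time ratio, dead-zone fraction). Metrics missing on
#' either side are kept in the table with `NA` comparisons and shown as
#' "-" by `format()`.
#'
#' @param baseline,new `pbr_scenario_report` objects (or plain named
#'   metric lists).
#' @return Data frame of class `pbr_comparison` with columns `metric`,
#'   `baseline`, `new`, `percent_change`, `fold_ratio`.
#' @export
compare_scenarios <- function(baseline, new) {
  get_metrics <- function(x) {
    if (inherits(x, "pbr_scenario_report")) x$metrics else as.list(x)
  }
  mb <- get_metrics(baseline); mn <- get_metrics(new)
  rows <- lapply(comparable_metrics, function(nm) {
    b <- mb[[nm]]; v <- mn[[nm]]
    has <- !is.null(b) && !is.null(v) && is.finite(b) && is.finite(v) && b != 0
    data.frame(metric = nm,
               baseline = if (is.null(b)) NA_real_ else b,
               new = if (is.null(v)) NA_real_ else v,
               percent_change = if (has) percent_change(b, v) else NA_real_,
               fold_ratio = if (has) fold_ratio(b, v) else NA_real_)
  })
  structure(do.call(rbind, rows), class = c("pbr_comparison", "data.frame"))
}

#' @export
format.pbr_comparison <- function(x, ...) {
  fmt <- function(v, digits = 1) ifelse(is.na(v), "-",
                                        formatC(v, format = "f", digits = digits))
  data.frame(metric = x$metric,
             baseline = fmt(x$baseline, 3), new = fmt(x$new, 3),
             `change_pct` = fmt(x$percent_change),
             fold = fmt(x$fold_ratio))
}

#' @export
print.pbr_comparison <- function(x, ...) {
  print(format(x), row.names = FALSE)
  invisible(x)
}

#' Run one scenario end to end from a configuration list
#'
#' Pipeline: geometry -> flow field (synthetic, or read from a field table
#' when `config$field_file` is set) -> particle tracking -> metrics ->
#' scenario report. With a fixed `config$seed` the result is
#' bit-reproducible. When `out_dir` is given, the field table, trajectory
#' table and report JSON are written there.
#'
#' Recognised configuration entries (all optional except `layout`):
#' `layout`, `outer_diameter_mm`, `inner_diameter_mm`, `removed_arc_deg`,
#' `boundary_depth_mm`, `fillet_enabled`; `direction_deg`, `rate_vvm`,
#' `pore_diameter_mm`, `pores_per_row`, `n_rows`, `tube_length_mm`;
#' `peak_vr`, `mean_tke`, `grid_spacing_mm`; `n_particles`, `max_time_s`,
#' `record_interval_s`, `integrator_step_s`; `seed`; `field_file`.
#' A path to a JSON (or YAML, if the yaml package is installed)
#' configuration file may be given instead of a list.
#'
#' @param config Named list or path to a JSON/YAML file.
#' @param out_dir Optional output directory.
#' @return A [scenario_report()] object; intermediate objects are attached
#'   as attributes `field` and `trajectories`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(is.list(config), !is.null(config$layout))
  pick <- function(nm, default) if (is.null(config[[nm]])) default else config[[nm]]
  geom <- make_geometry(
    layout = config$layout,
    outer_radius = pick("outer_diameter_mm", 200) / 2,
    inner_radius = pick("inner_diameter_mm", 80) / 2,
    removed_arc_deg = pick("removed_arc_deg", 60),
    boundary_depth = pick("boundary_depth_mm", 0),
    fillet_enabled = pick("fillet_enabled", TRUE))
  seed <- pick("seed", 1L)
  if (is.null(config$field_file)) {
    aer <- aeration_spec(
      direction_deg = pick("direction_deg", -30),
      rate_vvm = pick("rate_vvm", 0.7),
      pore_diameter_mm = pick("pore_diameter_mm", 5),
      pores_per_row = pick("pores_per_row", 4),
      n_rows = pick("n_rows", if (config$layout == "concentric") 1 else 2),
      tube_length_mm = pick("tube_length_mm", 1000))
    field <- default_scenario(geom, aer,
                              peak_vr = config$peak_vr,
                              mean_tke = config$mean_tke,
                              spacing = pick("grid_spacing_mm", 2))
  } else {
    field <- read_field_table(config$field_file, geom)
  }
  params <- particle_params(
    n_particles = pick("n_particles", 20),
    max_time = pick("max_time_s", 60),
    record_interval = pick("record_interval_s", 0.1),
    integrator_step = pick("integrator_step_s", 0.01),
    seed = seed)
  traj <- track(field, params)
  rep <- scenario_report(field, traj,
                         id = list(layout = config$layout,
                                   direction_deg = pick("direction_deg", -30),
                                   rate_vvm = pick("rate_vvm", 0.7),
                                   seed = seed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_field_table(field, file.path(out_dir, "field.csv"))
    utils::write.csv(traj, file.path(out_dir, "trajectories.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(id = rep$id, metrics = rep$metrics,
                              provenance = rep$provenance),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  attr(rep, "field") <- field
  attr(rep, "trajectories") <- traj
  rep
}

read_pipeline_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configurations requires the yaml package", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Literature comparison table
#'
#' Published performance figures for tubular photobioreactor designs
#' (field-synergy statistic, mean TKE, light/dark cycle frequency and
#' light-time ratio), reproduced as static reference metadata for
#' comparison tables. These are literature values, never recomputed here.
#'
#' @return Data frame with columns `design`, `abs_cos_alpha`,
#'   `tke_cm2_s2`, `f_hz`, `phi_pct`, `source`.
#' @export
literature_performance <- function() {
  path <- system.file("extdata", "literature_pbr_performance.csv",
                      package = "pbrflash", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE)
}
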