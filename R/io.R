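# Configuration loading/validation, result serialization and run manifests.
# Config files are flat YAML; keys carry explicit unit suffixes (_C, _mm,
# _s, ...) and are converted internally exactly once.

.CONFIG_KEYS <- c(
  "nominal_flux_kW_m2", "exposure_s", "cooling_s", "ambient_C", "rh_pct",
  "gap_mm", "metabolic_W_m2", "metabolic_cooling_W_m2", "safe_core_C",
  "burn_skin_C", "source_temp_K",
  "source_emissivity", "source_area_m2", "sample_area_m2", "gas_emissivity",
  "shell_ambient_viewfactor", "char_length_m", "cavity_height_m",
  "gap_kappa_m1", "orientation", "skin_emissivity", "evap_efficiency",
  "dx_fabric_m", "dx_gap_m", "dt_s", "tol_K", "max_iter")

#' Load and validate a scenario configuration file
#'
#' Reads a flat YAML file whose keys are the arguments of
#' [scenario_config()] (all optional: an empty file yields the full default
#' bench scenario of 8.5 kW/m^2, 300 s + 2500 s, 30 degC / 65% RH, 6.4 mm
#' gap). Unknown keys are a hard error, and all schema violations are
#' reported together rather than first-failure.
#'
#' @param path path to the YAML file; missing/empty files give defaults.
#' @return a fully resolved [scenario_config()].
#' @export
load_config <- function(path) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
    vals <- vals[!vapply(vals, is.null, TRUE)] # explicit nulls = defaults
  }
  problems <- character(0)
  unknown <- setdiff(names(vals), .CONFIG_KEYS)
  if (length(unknown)) {
    problems <- c(problems, sprintf("unknown key(s): %s", paste(unknown, collapse = ", ")))
  }
  num_keys <- setdiff(.CONFIG_KEYS, "orientation")
  for (k in intersect(names(vals), num_keys)) {
    if (!is.numeric(vals[[k]]) || length(vals[[k]]) != 1 || !is.finite(vals[[k]])) {
      problems <- c(problems, sprintf("%s must be a single finite number", k))
    }
  }
  chk <- function(key, ok, msg) {
    if (key %in% names(vals) && is.numeric(vals[[key]]) && !ok(vals[[key]])) {
      problems <<- c(problems, sprintf("%s %s (got %g)", key, msg, vals[[key]]))
    }
  }
  chk("gap_mm", function(v) v >= 0, "must be >= 0")
  chk("exposure_s", function(v) v > 0, "must be > 0")
  chk("cooling_s", function(v) v > 0, "must be > 0")
  chk("rh_pct", function(v) v >= 0 && v <= 100, "must lie in [0, 100]")
  chk("safe_core_C", function(v) v > 35, "must be > 35 degC")
  chk("burn_skin_C", function(v) v > 35, "must be > 35 degC")
  chk("dt_s", function(v) v > 0, "must be > 0")
  chk("dx_fabric_m", function(v) v > 0, "must be > 0")
  chk("dx_gap_m", function(v) v > 0, "must be > 0")
  chk("evap_efficiency", function(v) v >= 0 && v <= 1, "must lie in [0, 1]")
  chk("cavity_height_m", function(v) v > 0, "must be > 0")
  for (k in intersect("orientation", names(vals))) {
    if (!vals[[k]] %in% c("vertical", "horizontal")) {
      problems <- c(problems, "orientation must be 'vertical' or 'horizontal'")
    }
  }
  if (length(problems)) {
    stop(paste0("invalid configuration:\n  - ",
                paste(problems, collapse = "\n  - ")), call. = FALSE)
  }
  do.call(scenario_config, vals)
}

#' Dump a resolved configuration back to YAML
#'
#' Round-trip partner of [load_config()]: writes every resolved key (the
#' clothing ensemble is referenced by its packaged default and not dumped).
#'
#' @param cfg a [scenario_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  vals <- cfg[.CONFIG_KEYS]
  vals <- vals[!vapply(vals, is.null, TRUE)]
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Write the outputs of a run to a directory
#'
#' Serializes the full-precision time series as CSV, the strain metrics as
#' JSON, and a run manifest (resolved configuration, derived quantities,
#' package version, timestamp) sufficient to re-run the scenario
#' bit-identically.
#'
#' @param run a `strain_run` from [run_scenario()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
write_outputs <- function(run, dir) {
  stopifnot(inherits(run, "strain_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  series_path <- file.path(dir, "series.csv")
  metrics_path <- file.path(dir, "metrics.json")
  manifest_path <- file.path(dir, "manifest.json")
  write.csv(format(run$series, digits = 17, trim = TRUE, scientific = FALSE),
            series_path, row.names = FALSE, quote = FALSE)
  m <- run$metrics
  m$effective_cooling_time_s <-
    if (is.infinite(m$effective_cooling_time_s)) "> simulated cooling" else m$effective_cooling_time_s
  if (!is.null(m$dangerous_zone_s) && any(is.infinite(m$dangerous_zone_s))) {
    m$dangerous_zone_s <- as.character(m$dangerous_zone_s)
  }
  jsonlite::write_json(m, metrics_path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  cfg <- run$config
  manifest <- list(
    package = "firestrain",
    version = as.character(utils::packageVersion("firestrain")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = cfg[.CONFIG_KEYS],
    derived = list(
      F_hs_shell = run$scenario$F_hs_shell,
      T_hs_K = run$scenario$T_hs_K,
      grid_nodes = run$grid_nodes
    ),
    outputs = list(series = "series.csv", metrics = "metrics.json")
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  c(series = series_path, metrics = metrics_path, manifest = manifest_path)
}

#' Re-run a scenario from its manifest
#'
#' @param manifest_path path to a `manifest.json` written by
#'   [write_outputs()].
#' @return a `strain_run` (identical to the original run).
#' @export
rerun_from_manifest <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  vals <- as.list(man$config)
  vals <- vals[!vapply(vals, function(v) is.null(v) || length(v) == 0, TRUE)]
  run_scenario(do.call(scenario_config, vals))
}
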