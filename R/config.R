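# Run configuration: one JSON document holding the knobs shared by the CLI
# subcommands. Unknown keys are rejected so typos fail loudly.

default_run_config <- function() {
  list(
    grid = list(rows = 3L, cols = 3L, pitch = 34, origin = c(24, 24),
                expected_radius = 10),
    standards = c(1.71, 3.41, 4.71),
    fence = list(k = 0.5, min_outlier_spots = 2L, method = "linear"),
    ci_level = 0.95,
    colormap = "viridis",
    scale = list(min_conc = 0, max_conc = 4.71),
    wand = list(tolerance = 20, connectivity = 8L),
    calibration_line = list(slope = -20.98, intercept = 241.71),
    noise_sd = 3,
    out_dir = ".",
    seed = 1L
  )
}

merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    if (!key %in% names(base)) {
      stopf("unknown config key: %s%s", path, key, class = "aminoblot_config_error")
    }
    if (is.list(base[[key]]) && is.list(override[[key]])) {
      base[[key]] <- merge_config(base[[key]], override[[key]],
                                  paste0(path, key, "."))
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

validate_run_config <- function(cfg) {
  g <- cfg$grid
  grid_spec(g$rows, g$cols, g$pitch, unlist(g$origin), g$expected_radius)
  fence_params(cfg$fence$k, cfg$fence$min_outlier_spots, cfg$fence$method)
  if (cfg$ci_level <= 0 || cfg$ci_level >= 1) {
    stopf("ci_level must be in (0, 1)", class = "aminoblot_config_error")
  }
  if (!is.numeric(cfg$standards) || length(cfg$standards) < 1L ||
      any(cfg$standards <= 0)) {
    stopf("standards must be positive concentrations", class = "aminoblot_config_error")
  }
  if (cfg$scale$min_conc >= cfg$scale$max_conc) {
    stopf("scale.min_conc must be < scale.max_conc", class = "aminoblot_config_error")
  }
  if (!cfg$wand$connectivity %in% c(4L, 8L)) {
    stopf("wand.connectivity must be 4 or 8", class = "aminoblot_config_error")
  }
  invisible(cfg)
}

#' Load a run configuration
#'
#' Starts from package defaults, merges an optional JSON file and then any
#' programmatic overrides; unknown keys are rejected.
#'
#' @param path optional JSON file.
#' @param overrides optional named list merged last (e.g. from CLI flags).
#' @return validated config list.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stopf("config file not found: %s", path, class = "aminoblot_config_error")
    }
    cfg <- merge_config(cfg, jsonlite::read_json(path, simplifyVector = TRUE))
  }
  cfg <- merge_config(cfg, overrides)
  validate_run_config(cfg)
  cfg
}

config_grid <- function(cfg) {
  g <- cfg$grid
  grid_spec(g$rows, g$cols, g$pitch, unlist(g$origin), g$expected_radius)
}

config_fence <- function(cfg) {
  fence_params(cfg$fence$k, cfg$fence$min_outlier_spots, cfg$fence$method)
}

config_scale <- function(cfg) {
  color_scale(min_conc = cfg$scale$min_conc, max_conc = cfg$scale$max_conc,
              colormap = cfg$colormap, ticks = cfg$standards)
}
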