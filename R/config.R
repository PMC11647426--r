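#' Shipped default pipeline configuration
#'
#' All tunable constants of the pipeline live in one JSON config file
#' (`inst/extdata/default_config.json`): arena geometry, the saline
#' behavioural calibration, per-drug pharmacodynamics, the dosing design,
#' metric thresholds (2 s minimum immobility/freezing, 0.8 m/s jitter cap,
#' 5-min bins, 10-60 min TOI) and statistics options.
#'
#' @return Nested list (class `run_config`).
#' @export
default_config <- function() {
  load_config(system.file("extdata", "default_config.json",
                          package = "parkfield", mustWork = TRUE))
}

#' Load a pipeline configuration file
#'
#' Reads a JSON config and merges it over the shipped defaults, so a user
#' config only needs the keys it overrides.
#'
#' @param path Path to a JSON config file.
#' @return Nested list (class `run_config`).
#' @export
load_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- if (basename(path) == "default_config.json" &&
              dirname(path) == system.file("extdata", package = "parkfield"))
    NULL else unclass(default_config())
  merged <- if (is.null(base)) cfg else modify_list_deep(base, cfg)
  validate_config(merged)
  structure(merged, class = "run_config")
}

modify_list_deep <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]) &&
        !is.null(names(override[[k]])))
      base[[k]] <- modify_list_deep(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

validate_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed),
            cfg$arena$side_length > 0,
            cfg$session$dt > 0, cfg$session$duration_min <= 90,
            cfg$metrics$min_dur > 0, cfg$metrics$filter_cap > 0,
            length(cfg$metrics$toi_min) == 2L,
            cfg$metrics$toi_min[1] < cfg$metrics$toi_min[2],
            cfg$stats$sidak_family %in% c("per_row", "per_table", "per_column"))
  invisible(cfg)
}

#' Build domain objects from a config
#'
#' Convenience constructors translating `run_config` blocks into the package's
#' parameter objects.
#' @param cfg A `run_config`.
#' @return An [arena_geometry()], [behavior_params()], or named list of
#'   per-drug [pd_params()] respectively.
#' @export
config_arena <- function(cfg)
  arena_geometry(cfg$arena$side_length, cfg$arena$grid_cell,
                 cfg$arena$wall_height)

#' @rdname config_arena
#' @export
config_behavior <- function(cfg) do.call(behavior_params, cfg$behavior)

#' @rdname config_arena
#' @export
config_pd <- function(cfg)
  lapply(cfg$pharmacodynamics, function(p) do.call(pd_params, p))
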