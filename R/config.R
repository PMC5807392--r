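#' Default run configuration
#'
#' The configuration bundles everything a reproducible run needs:
#' `model` (parameter overrides, all defaulting to the reference set),
#' `protocol` (pulse train), `analysis` (thresholds, integrator step,
#' scan grids) and `behavior` (synthetic raster settings, the only seeded
#' component).  Unspecified fields fall back to these defaults, so a bare
#' command reproduces the reference runs.
#'
#' @return Nested list of defaults.
#' @export
default_run_config <- function() {
  list(
    model = unclass(mcell_params()),
    protocol = list(frequency = 1, count = 40, amplitude = 4.5,
                    width = 20, onset = 20000),
    analysis = list(spike_threshold = 0, area_threshold = -30, step = 0.01,
                    frequencies = c(0.1, 0.2, 0.5, 1, 2, 5),
                    ag_max_values = seq(40.5, 44.5, by = 0.25),
                    amplitude_values = seq(3, 6, by = 0.25),
                    jumpup_region = c(3, 3.2, 0.9, 1.2),
                    jumpup_increment = 0.01,
                    map_window = c(100000, 300000)),
    behavior = list(seed = 1, n_animals = 20, n_stimuli = 40, frequency = 1)
  )
}

#' Read a run configuration file
#'
#' YAML file with any subset of the sections of [default_run_config()];
#' missing fields are filled from the defaults (recursively), so a config
#' file only needs to state what deviates from the reference setup.
#'
#' @param path YAML config file, or `NULL` for pure defaults.
#' @return Nested configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) stop("unknown config section(s): ",
                        paste(bad, collapse = ", "))
  modifyList(cfg, user)
}

config_params <- function(cfg) {
  do.call(mcell_params, cfg$model[names(cfg$model) != "ag_max"] |>
            c(list(ag_max = cfg$model$ag_max)))
}

write_manifest <- function(path, command, cfg, extra = list()) {
  manifest <- c(list(command = command,
                     package = "mcellhab",
                     version = as.character(utils::packageVersion("mcellhab")),
                     config = cfg),
                extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
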