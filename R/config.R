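#' Default run configuration
#'
#' All defaults reproduce the model's standard settings: 0.05 mm mesh,
#' stimulus constants a = 0.0375 and b = 3 um/s, smoothing window 10,
#' 35 healing days, 8 um applied displacement, friction coefficient 0.3
#' for the optional contact mode, and the stock material table.
#'
#' @return Named list of class `oh_config`.
#' @export
default_config <- function() {
  structure(list(
    implant = "A",
    element_size = 0.05,
    days = 35L,
    smoothing_window = 10L,
    load = list(top_displacement = 8, ramp_duration = 1,
                n_time_steps = 10L),
    interface = list(mode = "coulomb_penalty", friction_coefficient = 0.3),
    constants = list(a = 0.0375, b = 3),
    thresholds = list(fibrous = 3, cartilage = 1, immature = 0.266,
                      mature = 0.010),
    diffusivity = "calibrate",
    saturation_threshold = 0.99,
    n_threads = 8L,
    output_dir = "healing-out",
    seed = 1L), class = "oh_config")
}

#' Load a run configuration file
#'
#' Reads a YAML configuration, validates its keys against
#' [default_config()] and fills unset keys with defaults. An empty file
#' yields the all-defaults configuration; an unknown key is an error that
#' names the key.
#'
#' @param path path to a YAML file.
#' @return An `oh_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such config file: ", path))
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  if (is.null(raw)) return(cfg)
  merge_keys <- function(base, new, prefix = "") {
    for (k in names(new)) {
      if (!k %in% names(base)) {
        rlang::abort(paste0("unknown configuration key: ", prefix, k))
      }
      if (is.list(base[[k]]) && is.list(new[[k]])) {
        base[[k]] <- merge_keys(base[[k]], new[[k]],
                                paste0(prefix, k, "."))
      } else {
        base[[k]] <- new[[k]]
      }
    }
    base
  }
  out <- merge_keys(unclass(cfg), raw)
  structure(out, class = "oh_config")
}

#' Write a run configuration file
#'
#' @param config an `oh_config` list.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 12)
  invisible(path)
}

#' Run a healing simulation from a configuration
#'
#' Builds the implant geometry (catalog label or explicit chamber
#' parameters), meshes it, and runs the daily healing loop.
#'
#' @param config an `oh_config`.
#' @param verbose print per-day progress.
#' @return An `oh_healing` run.
#' @export
run_from_config <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "oh_config") || is.list(config))
  if (is.character(config$implant)) {
    cat8 <- catalog_implants(n_threads = config$n_threads)
    if (!config$implant %in% names(cat8)) {
      rlang::abort(paste0("unknown implant label: ", config$implant))
    }
    entry <- cat8[[config$implant]]
    params <- entry$params
    dom <- entry$domain
  } else {
    params <- do.call(chamber_params, config$implant)
    dom <- list(cortical_thickness = 1.5, callus_margin = 0.5,
                domain_extent = c(params$outer_radius + 3,
                                  params$collar_length +
                                    params$n_threads * params$pitch +
                                    params$apex_length + 4))
  }
  layout <- build_domain(build_chamber_profile(params),
                         cortical_thickness = dom$cortical_thickness,
                         callus_margin = dom$callus_margin,
                         domain_extent = dom$domain_extent)
  mesh <- generate_mesh(layout, config$element_size)
  run_healing(
    mesh, days = config$days,
    load = load_case(config$load$top_displacement,
                     config$load$ramp_duration,
                     config$load$n_time_steps),
    interface = interface_spec(config$interface$mode,
                               config$interface$friction_coefficient),
    constants = stimulus_constants(config$constants$a, config$constants$b),
    D = config$diffusivity, N = config$smoothing_window,
    saturation_threshold = config$saturation_threshold,
    thresholds = unlist(config$thresholds), verbose = verbose)
}
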