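## JSON run configuration: schema with materialized defaults, unknown-key
## rejection, and round-trippable serialization.

neuron_defaults <- function() list(a = 0.02, b = 0.2, c_reset = -65, d = 8,
                                   v_peak = 30, omega = 1, beta = 0)
metabolic_defaults <- function() list(kappa = 5e-4, tau = 20, k_g = 0.05,
                                      k_m = 0.01, g_max = 5, m_max = 1,
                                      drive_mode = "rectified")
population_defaults <- function() list(n = 50, coupling = "all_to_all",
                                       p_connect = 0.2, w = 5, syn_tau = 5,
                                       I_dc = 0, sigma_noise = 0.2,
                                       shared_glycogen = TRUE)

config_schema <- function(kind) {
  base <- list(experiment = kind, seed = 0, out_dir = ".")
  extra <- switch(kind,
    percolation_run = list(N = 32, c = 1, alpha = 1, d_min = 2, k = 3,
                           eps = 0, p0 = 0.9, max_steps = 200),
    percolation_phase_diagram = list(lambda_grid = seq(0, 4, by = 0.5),
                                     k_values = c(2, 3, 4), tol = 1e-8),
    mc_critical = list(N = 32, c = 1, alpha = 1, d_min = 2, k = 3,
                       reps = 20, max_steps = 300, tol = 0.02),
    can_unit = list(T = 1000, dt = 0.1, I = 10,
                    neuron = neuron_defaults(),
                    metabolic = metabolic_defaults()),
    can_population = list(T = 1000, dt = 0.1,
                          neuron = neuron_defaults(),
                          metabolic = metabolic_defaults(),
                          population = population_defaults()),
    hysteresis = list(param_name = "I_dc", values = seq(0, 6, by = 0.75),
                      dwell = 600, dt = 0.2, delta_min = 0.2,
                      neuron = neuron_defaults(),
                      metabolic = metabolic_defaults(),
                      population = population_defaults()),
    cusp_scan = list(kappa_grid = c(0, 2e-4, 5e-4, 1e-3),
                     beta_grid = c(0, 0.15, 0.3, 0.5),
                     T = 1200, dt = 0.2, delta_min = 0.2,
                     neuron = neuron_defaults(),
                     metabolic = metabolic_defaults(),
                     population = population_defaults()),
    cone_fit = list(nr = 16, nc = 16, apex = c(7, 7), gamma = 0.2,
                    phi0 = 0.5, noise_sd = 0.1),
    stop_config(sprintf("unknown experiment kind '%s'", kind))
  )
  c(base, extra)
}

## merge user values into defaults, rejecting keys absent from the schema
merge_config <- function(defaults, user, path = "") {
  bad <- setdiff(names(user), names(defaults))
  if (length(bad))
    stop_config(sprintf("unknown config key(s): %s",
                        paste0(path, bad, collapse = ", ")))
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], as.list(user[[nm]]),
                                     paste0(path, nm, "."))
    } else {
      v <- user[[nm]]
      if (is.list(v) && is.null(names(v))) v <- unlist(v)   # JSON arrays
      ## keep the schema's storage mode so load -> save -> load is identity
      if (is.double(defaults[[nm]]) && is.integer(v)) v <- as.double(v)
      defaults[[nm]] <- v
    }
  }
  defaults
}

#' Load and validate a JSON run configuration
#'
#' The document must carry an \code{experiment} field naming the run kind;
#' all other fields are optional and take materialized defaults. Unknown
#' keys are rejected by name. load -> save -> load is the identity.
#'
#' @param path JSON file.
#' @return Object of class \code{"run_config"} (a named list with every
#'   field explicit).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("config file not found: %s", path))
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_run_config(user)
}

#' Build a validated run configuration from a list
#' @param user named list with at least \code{experiment}.
#' @return Object of class \code{"run_config"}.
#' @export
as_run_config <- function(user) {
  if (is.null(user$experiment)) stop_config("config must name an 'experiment'")
  schema <- config_schema(user$experiment)
  cfg <- merge_config(schema, user)
  structure(cfg, class = "run_config")
}

#' Save a run configuration as JSON
#' @param config a \code{"run_config"}.
#' @param path output file.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("run_config: %s (seed %s)\n", x$experiment, x$seed))
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}
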