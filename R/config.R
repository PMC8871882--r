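#' Build a run configuration
#'
#' A run configuration collects everything a command-line run needs: model
#' parameters, an intervention (either explicit bars or a `(mode, level)`
#' pair from the scenario registry), the initial state, simulation controls,
#' clustering controls and a seed. Omitted fields default to the benchmark
#' values, and the object serializes losslessly to a sectioned YAML file.
#'
#' @param model named list overriding [benchmark_config()] parameters
#'   (`alpha1`, ..., `tau`, `c`, `g`, `k`, `N`).
#' @param intervention named list of bar overrides (`alpha1_bar`, ...), or a
#'   list with `mode` and `level` referring to the scenario registry.
#' @param initial named list/vector overriding the benchmark initial state.
#' @param simulation named list with any of `horizon`, `grid_step`,
#'   `extinction_threshold`, `materiality`.
#' @param clustering named list with any of `eps`, `min_pts`,
#'   `n_advocates`, `n_supporters`, `n_amplifiers`.
#' @param seed integer seed used by every stochastic component.
#' @return A `run_config` list with sections `model`, `intervention`,
#'   `initial`, `simulation`, `clustering`, `seed`.
#' @export
run_config <- function(model = list(), intervention = list(),
                       initial = list(), simulation = list(),
                       clustering = list(), seed = 0) {
  cfg <- benchmark_config()
  m <- utils::modifyList(unclass(cfg$params), as.list(model))
  init <- utils::modifyList(as.list(unclass(cfg$initial)), as.list(initial))
  sim <- utils::modifyList(list(horizon = 1000, grid_step = 0.1,
                                extinction_threshold = 1e-4,
                                materiality = 0.01),
                           as.list(simulation))
  clu <- utils::modifyList(list(eps = 1.2, min_pts = 10,
                                n_advocates = 104, n_supporters = 656,
                                n_amplifiers = 1182),
                           as.list(clustering))
  iv <- as.list(intervention)
  if (!is.null(iv$mode)) {
    sp <- scenario(iv$mode, if (is.null(iv$level)) 1 else iv$level)
    iv <- list(mode = sp$mode, level = sp$level)
  } else {
    iv <- utils::modifyList(list(alpha1_bar = 0, alpha2_bar = 0,
                                 gamma1_bar = 0, gamma2_bar = 0,
                                 theta_bar = 0, tau_bar = 0), iv)
  }
  out <- list(model = m, intervention = iv, initial = init,
              simulation = sim, clustering = clu,
              seed = as.integer(seed))
  class(out) <- "run_config"
  validate_run_config(out)
}

validate_run_config <- function(config) {
  # coercion through the constructors performs all range checks
  config_params(config)
  config_intervention(config)
  config_initial(config)
  with(config$simulation, {
    if (horizon < grid_step || grid_step <= 0)
      validation_error("simulation: need horizon >= grid_step > 0")
    if (extinction_threshold <= 0)
      validation_error("simulation: extinction_threshold must be positive")
    if (materiality < 0)
      validation_error("simulation: materiality must be non-negative")
  })
  with(config$clustering, {
    if (eps <= 0 || min_pts < 1)
      validation_error("clustering: need eps > 0 and min_pts >= 1")
  })
  config
}

config_params <- function(config) {
  do.call(model_parameters, config$model[c("alpha1", "alpha2", "beta1",
                                           "beta2", "gamma1", "gamma2",
                                           "theta", "tau", "c", "g", "k",
                                           "N")])
}

config_intervention <- function(config) {
  iv <- config$intervention
  if (!is.null(iv$mode)) scenario(iv$mode, iv$level)$adjustments
  else do.call(intervention, iv)
}

config_initial <- function(config) {
  do.call(state, config$initial[c("I", "ES", "EA", "RS", "RA")])
}

#' Read / write a run configuration as YAML
#'
#' @param path file path.
#' @param config a `run_config`.
#' @return `read_run_config()` returns the validated `run_config`; the
#'   round trip `read_run_config(write_run_config(cfg, path))` reproduces
#'   `cfg` exactly.
#' @export
read_run_config <- function(path) {
  raw <- tryCatch(yaml::read_yaml(path), error = function(e)
    validation_error(sprintf("cannot parse config '%s': %s", path,
                             conditionMessage(e))))
  if (!is.list(raw)) validation_error("config file must contain a YAML mapping")
  run_config(model = raw$model, intervention = raw$intervention,
             initial = raw$initial, simulation = raw$simulation,
             clustering = raw$clustering,
             seed = if (is.null(raw$seed)) 0 else raw$seed)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}
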