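# Defaults that are modelling choices rather than tabulated parameter
# values; these names are flagged in emitted run metadata so a reader can
# tell anchored values from package defaults at a glance.
NON_PAPER_DEFAULTS <- c(
  "model.eps_MO_GOa", "model.sigma",
  "scenario.midpoints", "scenario.steepness",
  "scenario.active_eps_Glu_GO", "scenario.active_eps_GOa_MO",
  "scenario.active_eps_Ox_MO",
  "scenario.hypoxia_factor", "scenario.damping_factor",
  "simulation.init"
)

#' Names of configuration defaults that are not literature-anchored
#'
#' @return Character vector of dotted config keys.
#' @export
non_paper_defaults <- function() NON_PAPER_DEFAULTS

default_config <- function() {
  list(
    model = default_parameters(),
    simulation = list(duration = 2000, dt = 0.1, seed = 1L,
                      init = "random", noise = TRUE),
    scenario = list(name = "healthy", hypoxia_factor = 0.2,
                    damping_factor = 1,
                    midpoints = list(eps_Glu_GO = 1.25, eps_MO_GO = 1.125,
                                     eps_GO_MO = 1.375, eps_GOa_MO = 1.375,
                                     eps_Ox_MO = 1.125),
                    steepness = 20),
    sweep = list(S = seq(1, 1.5, by = 0.05),
                 eps_MO_GO = seq(0, 0.3, length.out = 31),
                 eps_GO_MO = seq(0, 0.3, length.out = 31)),
    output_dir = ".",
    log_level = "INFO"
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration whose sections are `model` (the resting-state
#' parameter schema: `omega_<osc>`, `A_<osc>`, `wmod_<osc>`, `sigma_<osc>`,
#' the seven couplings, plus the conveniences `sigma` / `A` / `wmod` that
#' apply to all oscillators), `simulation` (`duration`, `dt`, `seed`,
#' `init`, `noise`), `scenario`, `sweep`, `output_dir` and `log_level`. Any
#' key absent from the file takes its package default; an empty file yields
#' the full healthy resting-state defaults. Validation errors name the
#' offending key.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#'
#' @return A list of class `nvu_config` with every default resolved.
#' @export
#' @examples
#' cfg <- load_config(NULL)
#' cfg$model$eps_MO_GO
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) {
      if (!is.list(user)) stop("config must be a YAML mapping")
      unknown <- setdiff(names(user), names(cfg))
      if (length(unknown)) stop("unknown config section: ", unknown[1])
      for (sec in names(user)) {
        if (is.list(cfg[[sec]])) {
          sub <- user[[sec]]
          if (!is.list(sub)) stop("config section `", sec, "` must be a mapping")
          extra <- c("sigma", "A", "wmod")
          ok_keys <- if (sec == "model") c(names(cfg$model), extra) else names(cfg[[sec]])
          bad <- setdiff(names(sub), ok_keys)
          if (length(bad)) stop("unknown config key: ", sec, ".", bad[1])
          cfg[[sec]][names(sub)] <- sub
        } else {
          cfg[[sec]] <- user[[sec]]
        }
      }
    }
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  m <- cfg$model
  for (conv in c("sigma", "A", "wmod")) {
    if (!is.null(m[[conv]])) {
      m[paste0(conv, "_", OSC_IDS)] <- m[[conv]]
      m[[conv]] <- NULL
    }
  }
  cfg$model <- m
  for (nm in EPS_NAMES) {
    v <- m[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      stop("config key `model.", nm, "` must be a single non-negative number")
    }
  }
  for (id in OSC_IDS) {
    if (m[[paste0("omega_", id)]] <= 0) {
      stop("config key `model.omega_", id, "` must be positive")
    }
    if (m[[paste0("sigma_", id)]] < 0) {
      stop("config key `model.sigma_", id, "` must be non-negative")
    }
    a <- m[[paste0("A_", id)]]
    if (a < 0 || a >= 1) {
      stop("config key `model.A_", id, "` must lie in [0, 1)")
    }
  }
  sim <- cfg$simulation
  if (!is.numeric(sim$duration) || sim$duration <= 0) {
    stop("config key `simulation.duration` must be positive")
  }
  if (!is.numeric(sim$dt) || sim$dt <= 0 || sim$dt > sim$duration) {
    stop("config key `simulation.dt` must be in (0, duration]")
  }
  if (!(is.character(sim$init) && sim$init %in% c("random", "zeros")) &&
      !(is.numeric(sim$init) && length(sim$init) == 5)) {
    stop("config key `simulation.init` must be 'random', 'zeros' or a 5-vector")
  }
  sc <- cfg$scenario
  if (!sc$name %in% c("healthy", "dementia_oxygen", "dementia_glucose")) {
    stop("config key `scenario.name` must be one of: ",
         "healthy, dementia_oxygen, dementia_glucose")
  }
  structure(cfg, class = "nvu_config")
}

#' Build the network model described by a configuration
#'
#' @param config An `nvu_config` from [load_config()].
#' @return An `nvu_model`.
#' @export
model_from_config <- function(config) {
  stopifnot(inherits(config, "nvu_config"))
  model_from_parameters(config$model)
}

#' Build the scenario profile described by a configuration
#'
#' @param config An `nvu_config`.
#' @return An `nvu_scenario`.
#' @export
scenario_from_config <- function(config) {
  stopifnot(inherits(config, "nvu_config"))
  sc <- config$scenario
  sigma_all <- vapply(paste0("sigma_", OSC_IDS), function(k) config$model[[k]],
                      numeric(1))
  build_scenario(
    sc$name, hypoxia_factor = sc$hypoxia_factor,
    damping_factor = sc$damping_factor,
    midpoints = unlist(sc$midpoints), steepness = sc$steepness,
    sigma = max(sigma_all)
  )
}

#' Write run metadata
#'
#' Emits a JSON provenance record sufficient to re-run a simulation
#' bit-identically (noise-free) or distribution-identically (noisy): the
#' fully resolved configuration, the seed, the package version, and the
#' list of configuration keys whose defaults are modelling choices rather
#' than literature-anchored values.
#'
#' @param config An `nvu_config`.
#' @param path Output JSON path.
#' @param extra Optional named list merged into the record (e.g. expanded
#'   scenario curves).
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(config, path, extra = list()) {
  stopifnot(inherits(config, "nvu_config"))
  meta <- c(
    list(
      package = "nvuphase",
      version = as.character(utils::packageVersion("nvuphase")),
      config = unclass(config),
      non_paper_default = NON_PAPER_DEFAULTS
    ),
    extra
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a configuration back to YAML
#'
#' Round-trips losslessly through [load_config()].
#'
#' @param config An `nvu_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "nvu_config"))
  yaml::write_yaml(unclass(config), path, precision = 17)
  invisible(path)
}
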