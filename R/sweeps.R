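#' Replace coupling strengths of an existing model
#'
#' @param model An `nvu_model`.
#' @param ... Named coupling overrides (see [coupling_names()]).
#' @return An `nvu_model`.
#' @export
#' @examples
#' update_couplings(healthy_rest_model(), eps_MO_GO = 0.05)
update_couplings <- function(model, ...) {
  stopifnot(inherits(model, "nvu_model"))
  dots <- list(...)
  unknown <- setdiff(names(dots), EPS_NAMES)
  if (length(unknown) || is.null(names(dots)) || any(names(dots) == "")) {
    stop("coupling overrides must be named with: ",
         paste(EPS_NAMES, collapse = ", "))
  }
  p <- parameters_from_model(model)
  p[names(dots)] <- dots
  model_from_parameters(p)
}

#' Sweep the mutual metabolic couplings at fixed supply scale
#'
#' For every point of the `eps_MO_GO` x `eps_GO_MO` grid, instantiates the
#' scenario at supply scale S, overrides the two mutual couplings between
#' the neuronal glycolytic and mitochondrial oscillators, integrates, and
#' classifies the synchronisation state. The result is the tidy analogue of
#' a coupling-space phase diagram: the full eight-state map and its coarse
#' metabolic-mode simplification in one table.
#'
#' All cells share the same initial-phase draw (and, when the scenario is
#' noisy, the same noise realisation), so cells differ only through the
#' swept parameters.
#'
#' @param profile An [build_scenario()] profile.
#' @param S Supply scale.
#' @param eps_MO_GO,eps_GO_MO Strictly increasing grids of non-negative
#'   coupling values (default 31 points over `[0, 0.3]` each).
#' @param duration,dt Simulation grid per cell, s.
#' @param seed Integer seed for the shared initial phases / noise.
#' @param init Initial-phase policy passed to [simulate_phases()]; the
#'   default draws one random 5-vector with `seed` and reuses it across all
#'   cells.
#' @param window Analysis-window fraction (see [analyse_sync()]).
#'
#' @return A tibble of class `nvu_state_map` with columns `eps_MO_GO`,
#'   `eps_GO_MO`, `S`, `state_index`, `state_label`, `mode`.
#' @export
#' @examples
#' sc <- build_scenario("healthy")
#' sweep_metabolic_couplings(sc, S = 1,
#'                           eps_MO_GO = c(0.05, 0.2),
#'                           eps_GO_MO = c(0.05, 0.1),
#'                           duration = 400)
sweep_metabolic_couplings <- function(profile, S = 1,
                                      eps_MO_GO = seq(0, 0.3, length.out = 31),
                                      eps_GO_MO = seq(0, 0.3, length.out = 31),
                                      duration = 2000, dt = 0.1, seed = 1L,
                                      init = "random", window = 0.5) {
  stopifnot(inherits(profile, "nvu_scenario"),
            length(eps_MO_GO) >= 1, length(eps_GO_MO) >= 1,
            all(eps_MO_GO >= 0), all(eps_GO_MO >= 0),
            !is.unsorted(eps_MO_GO, strictly = TRUE),
            !is.unsorted(eps_GO_MO, strictly = TRUE))
  base <- apply_supply_scaling(profile, S)
  if (identical(init, "random")) init <- draw_initial_phases(seed)
  grid <- tidyr::expand_grid(eps_MO_GO = eps_MO_GO, eps_GO_MO = eps_GO_MO)
  res <- purrr::pmap_dfr(grid, function(eps_MO_GO, eps_GO_MO) {
    m <- update_couplings(base, eps_MO_GO = eps_MO_GO, eps_GO_MO = eps_GO_MO)
    traj <- tryCatch(
      simulate_phases(m, duration = duration, dt = dt, seed = seed,
                      init = init),
      error = function(e) {
        stop(sprintf("simulation failed at grid point (eps_MO_GO = %g, eps_GO_MO = %g): %s",
                     eps_MO_GO, eps_GO_MO, conditionMessage(e)))
      }
    )
    rep_ <- analyse_sync(traj, window)
    tibble::tibble(eps_MO_GO = eps_MO_GO, eps_GO_MO = eps_GO_MO, S = S,
                   state_index = rep_$state_index,
                   state_label = rep_$state_label, mode = rep_$mode)
  })
  structure(res,
            class = c("nvu_state_map", class(tibble::tibble())),
            scenario = profile$name, seed = as.integer(seed),
            duration = duration, dt = dt, window = window)
}

#' Sweep the supply scale and record entrainment frequencies
#'
#' For each S on the grid, instantiates the scenario, integrates, and
#' records every oscillator's mean frequency over the analysis window. As S
#' rises in the healthy scenario the metabolic oscillators detach from the
#' oxygen supply and entrain to the glucose supply.
#'
#' @param profile An [build_scenario()] profile.
#' @param S Supply-scale grid within the profile domain.
#' @inheritParams sweep_metabolic_couplings
#'
#' @return A tibble of class `nvu_freq_curves` with columns `S`, `osc`,
#'   `mean_freq_rad_s`.
#' @export
#' @examples
#' fc <- sweep_supply_scale(build_scenario("healthy"),
#'                          S = c(1, 1.5), duration = 400)
sweep_supply_scale <- function(profile, S = seq(1, 1.5, by = 0.05),
                               duration = 2000, dt = 0.1, seed = 1L,
                               init = "random", window = 0.5) {
  stopifnot(inherits(profile, "nvu_scenario"), length(S) >= 1)
  if (identical(init, "random")) init <- draw_initial_phases(seed)
  res <- purrr::map_dfr(S, function(s) {
    m <- apply_supply_scaling(profile, s)
    traj <- simulate_phases(m, duration = duration, dt = dt, seed = seed,
                            init = init)
    rep_ <- analyse_sync(traj, window)
    dplyr::mutate(rep_$frequencies, S = s, .before = 1)
  })
  structure(res,
            class = c("nvu_freq_curves", class(tibble::tibble())),
            scenario = profile$name, seed = as.integer(seed),
            duration = duration, dt = dt, window = window)
}

#' Classify the metabolic mode along a supply-scale grid
#'
#' Runs one simulation per S and returns the synchronisation state and
#' metabolic mode at each point. In the healthy scenario the sequence runs
#' aerobic at rest, through a transitional band, to glycolytic at full
#' activation.
#'
#' @inheritParams sweep_supply_scale
#' @return A tibble with columns `S`, `state_index`, `state_label`, `mode`.
#' @export
#' @examples
#' sweep_supply_modes(build_scenario("healthy"), S = c(1, 1.5),
#'                    duration = 400)
sweep_supply_modes <- function(profile, S = seq(1, 1.5, by = 0.05),
                               duration = 2000, dt = 0.1, seed = 1L,
                               init = "random", window = 0.5) {
  stopifnot(inherits(profile, "nvu_scenario"), length(S) >= 1)
  if (identical(init, "random")) init <- draw_initial_phases(seed)
  purrr::map_dfr(S, function(s) {
    m <- apply_supply_scaling(profile, s)
    traj <- simulate_phases(m, duration = duration, dt = dt, seed = seed,
                            init = init)
    rep_ <- analyse_sync(traj, window)
    tibble::tibble(S = s, state_index = rep_$state_index,
                   state_label = rep_$state_label, mode = rep_$mode)
  })
}
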