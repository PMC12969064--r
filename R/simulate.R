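#' One fixed-step fourth-order Runge-Kutta update
#'
#' Advances the five phases by one classical RK4 step of length `dt`. The
#' noise forcing is held constant across the four stages (it is a
#' band-limited external forcing sampled on the integration grid, not white
#' noise).
#'
#' This is the reference R implementation of the update rule; full
#' trajectories from [simulate_phases()] use a compiled loop of the same
#' scheme.
#'
#' @param model An `nvu_model`.
#' @param phases Numeric 5-vector of unwrapped phases (rad).
#' @param t Current time, s.
#' @param dt Step length, s; positive.
#' @param noise Numeric 5-vector of already-scaled additive forcing (rad/s).
#'
#' @return Named numeric 5-vector of phases at `t + dt`.
#' @export
#' @examples
#' m <- healthy_rest_model()
#' rk4_step(m, rep(0, 5), t = 0, dt = 0.1)
rk4_step <- function(model, phases, t, dt, noise = rep(0, 5)) {
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) {
    stop("`dt` must be a single positive number")
  }
  k1 <- phase_velocity(model, phases, t, noise)
  k2 <- phase_velocity(model, phases + dt / 2 * k1, t + dt / 2, noise)
  k3 <- phase_velocity(model, phases + dt / 2 * k2, t + dt / 2, noise)
  k4 <- phase_velocity(model, phases + dt * k3, t + dt, noise)
  out <- phases + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  names(out) <- OSC_IDS
  out
}

#' Simulate the phase trajectory of the network
#'
#' Integrates the five-oscillator phase system with a fixed-step classical
#' RK4 scheme, the scheme and default grid (2000 s at dt = 0.1 s) being the
#' standard choice for resolving phase locking in coupled-oscillator models
#' at these time scales. Phases are stored unwrapped, in radians; wrapping is
#' left to analysis.
#'
#' When any oscillator has `sigma > 0` and `noise = TRUE`, an independent
#' pink-noise series is generated per oscillator from substreams of `seed`
#' and applied as a piecewise-constant forcing, one sample per step.
#'
#' @param model An `nvu_model`.
#' @param duration Total simulated time, s (default 2000).
#' @param dt Step length, s (default 0.1); the trajectory has
#'   `round(duration / dt) + 1` rows.
#' @param seed Integer seed controlling initial phases (under the
#'   `"random"` policy) and noise substreams.
#' @param init Initial-phase policy: `"random"` (uniform on `[0, 2*pi)`,
#'   drawn with `seed`), `"zeros"`, or an explicit numeric 5-vector (rad).
#' @param noise Logical; set `FALSE` to force a noise-free run regardless of
#'   the model's `sigma` values.
#'
#' @return A tibble of class `nvu_trajectory` with columns `t`, `phi_Ox`,
#'   `phi_Glu`, `phi_GOa`, `phi_GO`, `phi_MO`; the model, grid and seed are
#'   attached as attributes.
#' @seealso [analyse_sync()] to classify the result, [autoplot.nvu_trajectory()].
#' @export
#' @examples
#' traj <- simulate_phases(healthy_rest_model(), duration = 50, seed = 1)
#' dplyr::glimpse(traj)
simulate_phases <- function(model, duration = 2000, dt = 0.1, seed = 1L,
                            init = "random", noise = TRUE) {
  stopifnot(inherits(model, "nvu_model"))
  if (!is.numeric(duration) || duration <= 0) stop("`duration` must be positive")
  if (!is.numeric(dt) || dt <= 0 || dt > duration) {
    stop("`dt` must be positive and no larger than `duration`")
  }
  n_steps <- as.integer(round(duration / dt))
  if (n_steps < 2) stop("grid must contain at least 2 steps")

  if (is.numeric(init)) {
    if (length(init) != 5 || !all(is.finite(init))) {
      stop("explicit `init` must be a finite numeric 5-vector")
    }
    phi0 <- as.numeric(init)
    init_policy <- "explicit"
  } else {
    init_policy <- match.arg(init, c("random", "zeros"))
    phi0 <- if (init_policy == "zeros") rep(0, 5) else draw_initial_phases(seed)
  }

  arr <- model_arrays(model)
  noisy <- isTRUE(noise) && any(arr$sigma > 0)
  forcing <- if (noisy) {
    seeds <- noise_substream_seeds(seed)
    vapply(
      seq_len(5),
      function(i) arr$sigma[i] * as.numeric(pink_noise(n_steps, dt, seeds[i])),
      numeric(n_steps)
    )
  } else {
    matrix(0, nrow = 1, ncol = 5)
  }

  phases <- rk4_integrate_cpp(phi0, 0, dt, n_steps,
                              arr$omega, arr$A, arr$wmod, arr$eps, forcing)
  colnames(phases) <- paste0("phi_", OSC_IDS)
  out <- tibble::as_tibble(as.data.frame(phases))
  out <- tibble::add_column(out, t = seq(0, by = dt, length.out = n_steps + 1),
                            .before = 1)
  new_trajectory(out, model = model, dt = dt, duration = duration,
                 seed = as.integer(seed), init = init_policy, noise = noisy)
}

draw_initial_phases <- function(seed) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  stats::runif(5, 0, 2 * pi)
}

new_trajectory <- function(df, model, dt, duration, seed, init, noise) {
  structure(
    df,
    class = c("nvu_trajectory", class(tibble::tibble())),
    model = model, dt = dt, duration = duration, seed = seed,
    init = init, noise = noise
  )
}

#' @export
print.nvu_trajectory <- function(x, ...) {
  cat(sprintf(
    "<nvu_trajectory> %d samples, dt = %g s, duration = %g s, init = %s%s\n",
    nrow(x), attr(x, "dt"), attr(x, "duration"), attr(x, "init"),
    if (isTRUE(attr(x, "noise"))) ", pink noise on" else ""
  ))
  NextMethod()
}

# Trajectories keep their class through dplyr verbs only when the phase
# columns survive; otherwise fall back to a plain tibble.
trajectory_model <- function(traj) attr(traj, "model")
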