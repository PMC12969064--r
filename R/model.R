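#' @keywords internal
"_PACKAGE"

## usethis namespace: start
#' @importFrom Rcpp sourceCpp
#' @useDynLib nvuphase, .registration = TRUE
## usethis namespace: end
NULL

# Fixed oscillator ordering used for every 5-vector and trajectory column
# layout: oxygen supply, glucose supply, astrocytic glycolysis, neuronal
# glycolysis, neuronal oxidative phosphorylation (mitochondrial).
OSC_IDS <- c("Ox", "Glu", "GOa", "GO", "MO")

# The seven directed phase couplings, in the fixed order the integrator uses.
# MO->GO and MO->GOa enter the velocity field with a leading minus sign
# (mitochondrial activity inhibits glycolysis); all others enter with plus.
EPS_NAMES <- c(
  "eps_Glu_GO", "eps_MO_GO", "eps_Glu_GOa", "eps_MO_GOa",
  "eps_GO_MO", "eps_GOa_MO", "eps_Ox_MO"
)

#' Oscillator identifiers
#'
#' Returns the five oscillator identifiers in the fixed order used for all
#' vector and trajectory layouts: `"Ox"` (oxygen supply), `"Glu"` (glucose
#' supply), `"GOa"` (astrocytic glycolytic oscillator), `"GO"` (neuronal
#' glycolytic oscillator), `"MO"` (neuronal mitochondrial / oxidative
#' phosphorylation oscillator).
#'
#' @return Character vector of length 5.
#' @export
#' @examples
#' oscillator_ids()
oscillator_ids <- function() OSC_IDS

#' Coupling parameter names
#'
#' The seven directed coupling strengths of the network, named
#' `eps_<from>_<to>`. `eps_MO_GO` and `eps_MO_GOa` are inhibitory (they enter
#' the phase-velocity field with a minus sign); the rest are excitatory.
#'
#' @return Character vector of length 7.
#' @export
coupling_names <- function() EPS_NAMES

#' Create a single oscillator specification
#'
#' An oscillator is described by its central angular frequency `omega`
#' (rad/s), an optional deterministic frequency modulation
#' `omega * (1 + A * sin(wmod * t))`, and a pink-noise forcing strength
#' `sigma` (rad/s).
#'
#' @param id One of [oscillator_ids()].
#' @param omega Central angular frequency, rad/s; must be positive.
#' @param A Modulation amplitude, dimensionless, in `[0, 1)` so the
#'   modulated frequency stays positive.
#' @param wmod Modulation angular frequency, rad/s, non-negative.
#' @param sigma Pink-noise forcing strength, rad/s, non-negative.
#'
#' @return An object of class `nvu_oscillator`.
#' @export
#' @examples
#' oscillator_spec("MO", omega = 2 * pi / 100)
oscillator_spec <- function(id, omega, A = 0, wmod = 0, sigma = 0) {
  id <- match.arg(id, OSC_IDS)
  stopifnot(is.numeric(omega), length(omega) == 1, is.finite(omega))
  if (omega <= 0) stop("`omega` must be positive for oscillator ", id)
  if (A < 0 || A >= 1) {
    stop("`A` must lie in [0, 1) for oscillator ", id,
         " (modulated frequency must stay positive)")
  }
  if (wmod < 0) stop("`wmod` must be non-negative for oscillator ", id)
  if (sigma < 0) stop("`sigma` must be non-negative for oscillator ", id)
  structure(
    list(id = id, omega = omega, A = A, wmod = wmod, sigma = sigma),
    class = "nvu_oscillator"
  )
}

#' Time-modulated natural frequency
#'
#' Evaluates the nonautonomous natural frequency
#' `omega(t) = omega * (1 + A * sin(wmod * t))` of one oscillator. With
#' `A = 0` this reduces to the constant central frequency.
#'
#' @param spec An [oscillator_spec()].
#' @param t Time or vector of times, s.
#'
#' @return Angular frequency (rad/s), same length as `t`; strictly positive.
#' @export
#' @examples
#' o <- oscillator_spec("GO", omega = 1, A = 0.1, wmod = 2 * pi)
#' modulated_frequency(o, 0.25) # 1.1
modulated_frequency <- function(spec, t) {
  stopifnot(inherits(spec, "nvu_oscillator"))
  spec$omega * (1 + spec$A * sin(spec$wmod * t))
}

#' Create a five-oscillator network model
#'
#' Bundles the five oscillator specifications with the seven directed
#' coupling strengths. The supply oscillators (`Ox`, `Glu`) receive no
#' incoming couplings: apart from noise and frequency modulation they run
#' autonomously at their natural frequencies.
#'
#' @param specs Named list of five [oscillator_spec()] objects, one per id in
#'   [oscillator_ids()].
#' @param couplings Named numeric vector or list with the seven entries of
#'   [coupling_names()], all non-negative (rad/s).
#'
#' @return An object of class `nvu_model`.
#' @seealso [healthy_rest_model()] for the literature-anchored default
#'   parameterisation.
#' @export
nvu_model <- function(specs, couplings) {
  if (!setequal(names(specs), OSC_IDS)) {
    stop("`specs` must contain exactly one entry per oscillator id: ",
         paste(OSC_IDS, collapse = ", "))
  }
  specs <- specs[OSC_IDS]
  ok <- vapply(specs, inherits, logical(1), what = "nvu_oscillator")
  if (!all(ok)) stop("every entry of `specs` must be an oscillator_spec()")
  bad_id <- OSC_IDS[vapply(OSC_IDS, function(i) specs[[i]]$id != i, logical(1))]
  if (length(bad_id)) {
    stop("spec stored under '", bad_id[1], "' has id '",
         specs[[bad_id[1]]]$id, "'")
  }
  couplings <- unlist(couplings)
  if (!setequal(names(couplings), EPS_NAMES)) {
    stop("`couplings` must contain exactly: ", paste(EPS_NAMES, collapse = ", "))
  }
  couplings <- couplings[EPS_NAMES]
  neg <- names(couplings)[couplings < 0]
  if (length(neg)) stop("coupling must be non-negative: ", neg[1])
  structure(list(specs = specs, couplings = couplings), class = "nvu_model")
}

#' @export
print.nvu_model <- function(x, ...) {
  cat("<nvu_model> five-oscillator neurovascular phase network\n")
  om <- vapply(x$specs, `[[`, numeric(1), "omega")
  sg <- vapply(x$specs, `[[`, numeric(1), "sigma")
  cat("  omega (rad/s):",
      paste(sprintf("%s=%.4g", OSC_IDS, om), collapse = " "), "\n")
  if (any(sg > 0)) {
    cat("  sigma (rad/s):",
        paste(sprintf("%s=%.3g", OSC_IDS, sg), collapse = " "), "\n")
  }
  cat("  couplings:",
      paste(sprintf("%s=%.4g", names(x$couplings), x$couplings),
            collapse = " "), "\n")
  invisible(x)
}

#' Healthy resting-state parameterisation
#'
#' Builds the network model for the healthy brain at rest: supply periods of
#' 100 s (oxygen) and 200 s (glucose), glycolytic periods of 200 s,
#' mitochondrial period of 100 s, and the literature-anchored coupling
#' strengths (`eps_Ox_MO = 0.1`, `eps_Glu_GO = 0.1`, `eps_Glu_GOa = 0.05`,
#' `eps_GOa_MO = 0.025`, `eps_GO_MO = 0.1`, `eps_MO_GO = 0.2`).
#' `eps_MO_GOa` has no tabulated resting value and defaults to 0. Frequency
#' modulation is off (`A = 0`) and noise is off (`sigma = 0`) unless
#' overridden.
#'
#' @param ... Named overrides. Coupling names (see [coupling_names()]),
#'   per-oscillator frequencies `omega_<id>`, or `A_<id>`, `wmod_<id>`,
#'   `sigma_<id>`.
#' @param sigma Convenience: sets the noise strength of all five oscillators.
#' @param A Convenience: sets the modulation amplitude of all five.
#' @param wmod Convenience: sets the modulation frequency of all five.
#'
#' @return An `nvu_model`.
#' @export
#' @examples
#' m <- healthy_rest_model()
#' m$couplings[["eps_MO_GO"]] # 0.2
#' healthy_rest_model(eps_Ox_MO = 0)$couplings[["eps_Ox_MO"]]
healthy_rest_model <- function(..., sigma = NULL, A = NULL, wmod = NULL) {
  p <- default_parameters()
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == "")) {
      stop("all overrides must be named")
    }
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown)) stop("unknown parameter: ", unknown[1])
    p[names(dots)] <- dots
  }
  if (!is.null(sigma)) p[paste0("sigma_", OSC_IDS)] <- sigma
  if (!is.null(A)) p[paste0("A_", OSC_IDS)] <- A
  if (!is.null(wmod)) p[paste0("wmod_", OSC_IDS)] <- wmod
  model_from_parameters(p)
}

# Flat default parameter list mirroring the resting-state parameter table.
default_parameters <- function() {
  p <- list(
    omega_Ox = 2 * pi / 100, omega_Glu = 2 * pi / 200,
    omega_GOa = 2 * pi / 200, omega_GO = 2 * pi / 200,
    omega_MO = 2 * pi / 100,
    eps_Glu_GO = 0.1, eps_MO_GO = 0.2, eps_Glu_GOa = 0.05,
    eps_MO_GOa = 0, eps_GO_MO = 0.1, eps_GOa_MO = 0.025, eps_Ox_MO = 0.1
  )
  for (id in OSC_IDS) {
    p[[paste0("A_", id)]] <- 0
    p[[paste0("wmod_", id)]] <- 0
    p[[paste0("sigma_", id)]] <- 0
  }
  p
}

model_from_parameters <- function(p) {
  specs <- lapply(OSC_IDS, function(id) {
    oscillator_spec(
      id,
      omega = p[[paste0("omega_", id)]],
      A = p[[paste0("A_", id)]],
      wmod = p[[paste0("wmod_", id)]],
      sigma = p[[paste0("sigma_", id)]]
    )
  })
  names(specs) <- OSC_IDS
  nvu_model(specs, unlist(p[EPS_NAMES]))
}

# Inverse of model_from_parameters() for metadata emission.
parameters_from_model <- function(model) {
  p <- list()
  for (id in OSC_IDS) {
    s <- model$specs[[id]]
    p[[paste0("omega_", id)]] <- s$omega
    p[[paste0("A_", id)]] <- s$A
    p[[paste0("wmod_", id)]] <- s$wmod
    p[[paste0("sigma_", id)]] <- s$sigma
  }
  c(p, as.list(model$couplings))
}

#' Deterministic phase-velocity field
#'
#' Evaluates the right-hand side of the five-phase Kuramoto system at a given
#' state: each oscillator advances at its (time-modulated) natural frequency
#' plus sine-of-phase-difference coupling terms, plus an externally supplied
#' noise forcing. The supply oscillators carry only frequency and noise
#' terms. The mitochondrial inhibition of glycolysis (`eps_MO_GO`,
#' `eps_MO_GOa`) enters with a minus sign; all other couplings are
#' excitatory.
#'
#' @param model An `nvu_model`.
#' @param phases Numeric 5-vector of unwrapped phases (rad), in
#'   [oscillator_ids()] order.
#' @param t Time, s (used only through the frequency modulation).
#' @param noise Numeric 5-vector of additive forcing (rad/s); all zero for
#'   noise-free evaluation. The per-oscillator `sigma` is *not* applied here:
#'   pass the already-scaled forcing.
#'
#' @return Named numeric 5-vector of phase velocities (rad/s).
#' @export
#' @examples
#' m <- healthy_rest_model()
#' phase_velocity(m, phases = rep(0, 5), t = 0)
phase_velocity <- function(model, phases, t = 0, noise = rep(0, 5)) {
  stopifnot(inherits(model, "nvu_model"),
            length(phases) == 5, length(noise) == 5)
  if (!all(is.finite(phases))) {
    stop("non-finite phase for oscillator ",
         OSC_IDS[which(!is.finite(phases))[1]])
  }
  if (!all(is.finite(noise))) {
    stop("non-finite noise sample for oscillator ",
         OSC_IDS[which(!is.finite(noise))[1]])
  }
  w <- vapply(model$specs, modulated_frequency, numeric(1), t = t)
  e <- model$couplings
  phi <- unname(phases)
  v <- c(
    Ox  = w[["Ox"]],
    Glu = w[["Glu"]],
    GOa = w[["GOa"]] -
      e[["eps_MO_GOa"]] * sin(phi[5] - phi[3]) +
      e[["eps_Glu_GOa"]] * sin(phi[2] - phi[3]),
    GO  = w[["GO"]] -
      e[["eps_MO_GO"]] * sin(phi[5] - phi[4]) +
      e[["eps_Glu_GO"]] * sin(phi[2] - phi[4]),
    MO  = w[["MO"]] +
      e[["eps_GO_MO"]] * sin(phi[4] - phi[5]) +
      e[["eps_GOa_MO"]] * sin(phi[3] - phi[5]) +
      e[["eps_Ox_MO"]] * sin(phi[1] - phi[5])
  )
  v + unname(noise)
}

# Flatten a model into the numeric arrays the C++ integrator consumes.
model_arrays <- function(model) {
  list(
    omega = vapply(model$specs, `[[`, numeric(1), "omega"),
    A = vapply(model$specs, `[[`, numeric(1), "A"),
    wmod = vapply(model$specs, `[[`, numeric(1), "wmod"),
    sigma = vapply(model$specs, `[[`, numeric(1), "sigma"),
    eps = unname(model$couplings[EPS_NAMES])
  )
}
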