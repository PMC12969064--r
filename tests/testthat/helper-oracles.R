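# Independent brute-force evaluation of the phase-velocity field, written
# as a loop over an explicit edge table rather than the vectorised
# expressions the package uses. Signs: the mitochondrial inhibition of
# glycolysis enters negatively, everything else positively.
EDGE_TABLE <- data.frame(
  target = c("GO", "GO", "GOa", "GOa", "MO", "MO", "MO"),
  source = c("Glu", "MO", "Glu", "MO", "GO", "GOa", "Ox"),
  eps = c("eps_Glu_GO", "eps_MO_GO", "eps_Glu_GOa", "eps_MO_GOa",
          "eps_GO_MO", "eps_GOa_MO", "eps_Ox_MO"),
  sign = c(+1, -1, +1, -1, +1, +1, +1),
  stringsAsFactors = FALSE
)

brute_force_velocity <- function(model, phases, t = 0, noise = rep(0, 5)) {
  ids <- oscillator_ids()
  names(phases) <- ids
  v <- vapply(ids, function(id) {
    modulated_frequency(model$specs[[id]], t)
  }, numeric(1))
  for (k in seq_len(nrow(EDGE_TABLE))) {
    e <- EDGE_TABLE[k, ]
    v[e$target] <- v[e$target] +
      e$sign * model$couplings[[e$eps]] *
        sin(phases[[e$source]] - phases[[e$target]])
  }
  v + noise
}

# Circular-variance lock detector, independent of the range criterion: on a
# constant-frequency (noise-free) trajectory a locked pair has resultant
# length ~1, a drifting pair ~0.
circular_lock_oracle <- function(traj, pair, window = 0.5, threshold = 0.9) {
  dphi <- phase_difference(traj, pair)$dphi
  n <- length(dphi)
  w <- dphi[seq.int(n - floor(window * n) + 1L, n)]
  Mod(mean(exp(1i * w))) > threshold
}

# Drop provenance attributes so frames compare on their data alone.
plain_frame <- function(x) {
  out <- as.data.frame(x)
  attributes(out) <- attributes(out)[c("names", "row.names", "class")]
  out
}

# Two-oscillator reduction: glucose supply driving the astrocytic
# glycolytic oscillator, every other coupling zero. Detuning is imposed on
# the astrocyte frequency.
two_oscillator_model <- function(eps, detuning) {
  healthy_rest_model(
    eps_Glu_GO = 0, eps_MO_GO = 0, eps_Glu_GOa = eps, eps_MO_GOa = 0,
    eps_GO_MO = 0, eps_GOa_MO = 0, eps_Ox_MO = 0,
    omega_GOa = 2 * pi / 200 + detuning
  )
}
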