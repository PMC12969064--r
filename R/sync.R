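# The five oscillator pairs whose 1:1 locking defines the synchronisation
# state taxonomy. Order matters: it matches the state table columns.
MONITORED_PAIRS <- c("Glu-GO", "GO-MO", "Ox-MO", "GOa-MO", "Glu-GOa")

# Synchronisation-state table: rows 0-7, columns the monitored pairs, final
# column the coarse metabolic mode. TRUE marks a locked pair.
STATE_TABLE <- matrix(
  c(
    TRUE,  FALSE, TRUE,  FALSE, TRUE,   # 0 Transition
    FALSE, FALSE, TRUE,  FALSE, TRUE,   # 1 Transition
    FALSE, TRUE,  TRUE,  FALSE, TRUE,   # 2 Aerobic
    TRUE,  FALSE, FALSE, FALSE, TRUE,   # 3 Transition
    FALSE, FALSE, FALSE, FALSE, TRUE,   # 4 Transition
    FALSE, TRUE,  FALSE, FALSE, TRUE,   # 5 Transition
    TRUE,  TRUE,  FALSE, TRUE,  TRUE,   # 6 Glycolytic
    FALSE, FALSE, FALSE, TRUE,  TRUE    # 7 Glycolytic
  ),
  nrow = 8, byrow = TRUE, dimnames = list(0:7, MONITORED_PAIRS)
)
STATE_MODES <- c("TRANSITION", "TRANSITION", "AEROBIC", "TRANSITION",
                 "TRANSITION", "TRANSITION", "GLYCOLYTIC", "GLYCOLYTIC")

#' Monitored oscillator pairs
#'
#' The five pairs whose pairwise 1:1 phase locking defines the
#' synchronisation-state taxonomy, in table-column order.
#'
#' @return Character vector of length 5.
#' @export
monitored_pairs <- function() MONITORED_PAIRS

pair_members <- function(pair) {
  pair <- match.arg(pair, MONITORED_PAIRS)
  strsplit(pair, "-", fixed = TRUE)[[1]]
}

#' Instantaneous phase difference of a monitored pair
#'
#' Computes `dphi(t) = phi_a(t) - phi_b(t)` on the unwrapped phases, with
#' `a` the first-listed member of the pair (so `"GO-MO"` gives
#' `phi_GO - phi_MO`).
#'
#' @param traj An `nvu_trajectory`.
#' @param pair One of [monitored_pairs()].
#'
#' @return A tibble with columns `t` and `dphi` (rad).
#' @export
#' @examples
#' traj <- simulate_phases(healthy_rest_model(), duration = 100, init = "zeros")
#' phase_difference(traj, "GO-MO")
phase_difference <- function(traj, pair) {
  m <- pair_members(pair)
  a <- traj[[paste0("phi_", m[1])]]
  b <- traj[[paste0("phi_", m[2])]]
  if (is.null(a) || is.null(b)) stop("trajectory lacks phases for pair ", pair)
  tibble::tibble(t = traj$t, dphi = a - b)
}

#' Test 1:1 phase locking over an analysis window
#'
#' Two oscillators are considered synchronised when the range
#' (max minus min) of their unwrapped phase difference over the analysis
#' window stays below `2 * pi`. By default the window is the latter half of
#' the series, which also discards the initial transient.
#'
#' @param delta_phi Numeric vector of unwrapped phase differences (rad), or
#'   the tibble returned by [phase_difference()].
#' @param window Fraction of the series (taken from the end) to analyse, in
#'   `(0, 1]`; default 0.5.
#'
#' @return A list with elements `locked` (logical) and `range` (rad).
#' @export
#' @examples
#' is_synchronised(rep(0.3, 100))          # locked, range 0
#' is_synchronised(0.01 * seq(0, 2000))    # drifting, not locked
is_synchronised <- function(delta_phi, window = 0.5) {
  if (is.data.frame(delta_phi)) delta_phi <- delta_phi$dphi
  stopifnot(is.numeric(delta_phi), length(delta_phi) >= 1)
  if (!is.numeric(window) || window <= 0 || window > 1) {
    stop("`window` must lie in (0, 1]")
  }
  x <- window_tail(delta_phi, window)
  rng <- max(x) - min(x)
  list(locked = rng < 2 * pi, range = rng)
}

window_tail <- function(x, window) {
  n <- length(x)
  x[seq.int(n - floor(window * n) + 1L, n)]
}

#' Mean frequency of one oscillator over the analysis window
#'
#' Endpoint estimate `(phi(t_end) - phi(t_start)) / (t_end - t_start)` over
#' the latter part of the run. On the fixed grid this equals the average of
#' the finite-difference phase velocities, and it is robust to noise within
#' the window.
#'
#' @param traj An `nvu_trajectory`.
#' @param osc One of [oscillator_ids()].
#' @inheritParams is_synchronised
#'
#' @return Mean angular frequency, rad/s.
#' @export
#' @examples
#' traj <- simulate_phases(healthy_rest_model(), duration = 200, init = "zeros")
#' mean_frequency(traj, "Ox") # 2*pi/100
mean_frequency <- function(traj, osc, window = 0.5) {
  osc <- match.arg(osc, OSC_IDS)
  phi <- traj[[paste0("phi_", osc)]]
  tt <- window_tail(traj$t, window)
  ph <- window_tail(phi, window)
  if (length(tt) < 2) stop("analysis window spans fewer than 2 samples")
  (ph[length(ph)] - ph[1]) / (tt[length(tt)] - tt[1])
}

#' Map a pairwise lock pattern to a synchronisation state and metabolic mode
#'
#' Matches the five lock flags against the eight tabulated synchronisation
#' states. State 2 is the aerobic mode (oxygen-driven oxidative
#' phosphorylation); states 6 and 7 are glycolytic (glucose/lactate-driven);
#' the remaining tabulated states, and any pattern outside the table, are
#' transitional.
#'
#' @param flags Logical vector of length 5, named or in the order of
#'   [monitored_pairs()].
#'
#' @return A list with `state_index` (integer 0-7, or `NA` for patterns
#'   outside the table), `state_label` (`"0"`..`"7"` or `"OTHER"`), and
#'   `mode` (`"AEROBIC"`, `"TRANSITION"` or `"GLYCOLYTIC"`).
#' @export
#' @examples
#' classify_state(c(`Glu-GO` = FALSE, `GO-MO` = TRUE, `Ox-MO` = TRUE,
#'                  `GOa-MO` = FALSE, `Glu-GOa` = TRUE)) # state 2, AEROBIC
classify_state <- function(flags) {
  stopifnot(is.logical(flags), length(flags) == 5)
  if (!is.null(names(flags))) {
    if (!setequal(names(flags), MONITORED_PAIRS)) {
      stop("`flags` names must be exactly: ",
           paste(MONITORED_PAIRS, collapse = ", "))
    }
    flags <- flags[MONITORED_PAIRS]
  }
  hit <- which(apply(unname(STATE_TABLE), 1, identical, y = unname(flags)))
  if (length(hit) == 1) {
    idx <- as.integer(rownames(STATE_TABLE)[hit])
    list(state_index = idx, state_label = as.character(idx),
         mode = STATE_MODES[hit])
  } else {
    list(state_index = NA_integer_, state_label = "OTHER",
         mode = "TRANSITION")
  }
}

#' Full synchronisation analysis of a trajectory
#'
#' Computes, over the analysis window (by default the latter half of the
#' run): the lock flag and phase-difference range for each monitored pair,
#' the mean frequency of each oscillator, and the synchronisation state and
#' coarse metabolic mode implied by the lock pattern.
#'
#' @param traj An `nvu_trajectory`.
#' @inheritParams is_synchronised
#'
#' @return An object of class `nvu_sync`: a list with tibbles `pairs`
#'   (`pair`, `locked`, `range`) and `frequencies` (`osc`,
#'   `mean_freq_rad_s`), plus `state_index`, `state_label`, `mode` and
#'   `window`. Use [generics::tidy()] / [generics::glance()] for tibble
#'   views.
#' @export
#' @examples
#' traj <- simulate_phases(healthy_rest_model(), duration = 500, seed = 2)
#' analyse_sync(traj)
analyse_sync <- function(traj, window = 0.5) {
  pairs <- purrr::map(MONITORED_PAIRS, function(p) {
    res <- is_synchronised(phase_difference(traj, p), window)
    tibble::tibble(pair = p, locked = res$locked, range = res$range)
  })
  pairs <- dplyr::bind_rows(pairs)
  freqs <- tibble::tibble(
    osc = OSC_IDS,
    mean_freq_rad_s = unname(vapply(OSC_IDS, function(o) {
      mean_frequency(traj, o, window)
    }, numeric(1)))
  )
  cls <- classify_state(stats::setNames(pairs$locked, pairs$pair))
  structure(
    list(pairs = pairs, frequencies = freqs,
         state_index = cls$state_index, state_label = cls$state_label,
         mode = cls$mode, window = window),
    class = "nvu_sync"
  )
}

#' @export
print.nvu_sync <- function(x, ...) {
  cat(sprintf("<nvu_sync> state %s, mode %s (window = latter %g%%)\n",
              x$state_label, x$mode, 100 * x$window))
  locked <- x$pairs$pair[x$pairs$locked]
  cat("  locked pairs:",
      if (length(locked)) paste(locked, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a synchronisation report
#'
#' One row per monitored pair: lock flag and phase-difference range.
#'
#' @param x An `nvu_sync` object.
#' @param ... Unused.
#' @return A tibble with columns `pair`, `locked`, `range`.
#' @export
tidy.nvu_sync <- function(x, ...) x$pairs

#' One-row summary of a synchronisation report
#'
#' @param x An `nvu_sync` object.
#' @param ... Unused.
#' @return A one-row tibble: `state_index`, `state_label`, `mode`,
#'   `n_locked`, and the five oscillator mean frequencies as
#'   `freq_<osc>` columns (rad/s).
#' @export
glance.nvu_sync <- function(x, ...) {
  f <- stats::setNames(x$frequencies$mean_freq_rad_s,
                       paste0("freq_", x$frequencies$osc))
  dplyr::bind_cols(
    tibble::tibble(
      state_index = x$state_index, state_label = x$state_label,
      mode = x$mode, n_locked = sum(x$pairs$locked)
    ),
    tibble::as_tibble(as.list(f))
  )
}

#' Serialise a synchronisation report to JSON
#'
#' @param x An `nvu_sync` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sync_json <- function(x, path) {
  stopifnot(inherits(x, "nvu_sync"))
  jsonlite::write_json(
    list(
      pairs = x$pairs, frequencies = x$frequencies,
      state_index = x$state_index, state_label = x$state_label,
      mode = x$mode, window = x$window
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Build a synthetic trajectory realising a requested lock pattern
#'
#' Constructs a purely synthetic constant-frequency trajectory whose
#' [analyse_sync()] output reproduces the requested pairwise lock pattern:
#' oscillators that must lock share one frequency; groups that must stay
#' unlocked are separated by a detuning large enough that the phase
#' difference drifts past `2 * pi` within the analysis window. Patterns
#' whose transitive closure forces two oscillators of an unlocked pair into
#' the same frequency group are unrealisable with constant frequencies and
#' raise an error.
#'
#' @param pattern Logical vector of length 5 (named or in
#'   [monitored_pairs()] order): which pairs must be locked.
#' @param duration,dt Grid of the synthetic trajectory, s.
#'
#' @return An `nvu_trajectory`.
#' @export
#' @examples
#' pat <- c(`Glu-GO` = FALSE, `GO-MO` = TRUE, `Ox-MO` = TRUE,
#'          `GOa-MO` = FALSE, `Glu-GOa` = TRUE)
#' analyse_sync(make_lock_fixture(pat))$mode # "AEROBIC"
make_lock_fixture <- function(pattern, duration = 2000, dt = 0.1) {
  stopifnot(is.logical(pattern), length(pattern) == 5)
  if (!is.null(names(pattern))) {
    if (!setequal(names(pattern), MONITORED_PAIRS)) {
      stop("`pattern` names must be exactly: ",
           paste(MONITORED_PAIRS, collapse = ", "))
    }
    pattern <- pattern[MONITORED_PAIRS]
  } else {
    names(pattern) <- MONITORED_PAIRS
  }

  # Union-find over oscillators: locked pairs share a frequency group.
  group <- stats::setNames(seq_along(OSC_IDS), OSC_IDS)
  find <- function(i) { while (group[i] != i) i <- group[i]; i }
  for (p in MONITORED_PAIRS[pattern]) {
    m <- match(pair_members(p), OSC_IDS)
    group[find(m[1])] <- find(m[2])
  }
  root <- vapply(seq_along(OSC_IDS), find, integer(1))
  for (p in MONITORED_PAIRS[!pattern]) {
    m <- match(pair_members(p), OSC_IDS)
    if (root[m[1]] == root[m[2]]) {
      stop("pattern is unrealisable: pair ", p,
           " must stay unlocked but its members are transitively locked")
    }
  }

  # Distinct groups get frequencies separated by 0.1 rad/s; over a window of
  # duration/2 that drifts by >> 2*pi, so unlocked pairs stay unlocked.
  base <- 2 * pi / 100
  freq <- base + 0.1 * (match(root, sort(unique(root))) - 1)
  tt <- seq(0, duration, by = dt)
  phases <- outer(tt, freq)
  colnames(phases) <- paste0("phi_", OSC_IDS)
  out <- tibble::as_tibble(as.data.frame(phases))
  out <- tibble::add_column(out, t = tt, .before = 1)
  new_trajectory(out, model = NULL, dt = dt, duration = duration,
                 seed = NA_integer_, init = "fixture", noise = FALSE)
}

#' Lock pattern of a tabulated synchronisation state
#'
#' @param state_index Integer 0-7.
#' @return Named logical vector over [monitored_pairs()].
#' @export
#' @examples
#' state_pattern(2)
state_pattern <- function(state_index) {
  stopifnot(state_index %in% 0:7)
  stats::setNames(STATE_TABLE[as.character(state_index), ], MONITORED_PAIRS)
}

#' The synchronisation-state table
#'
#' @return A tibble with one row per tabulated state: `state_index`, one
#'   logical column per monitored pair, and `mode`.
#' @export
sync_state_table <- function() {
  out <- tibble::as_tibble(as.data.frame(STATE_TABLE))
  out <- tibble::add_column(out, state_index = 0:7, .before = 1)
  out$mode <- STATE_MODES
  out
}
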