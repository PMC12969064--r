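make_const_freq_traj <- function(freqs, duration = 1000, dt = 0.1,
                                 offsets = rep(0, 5)) {
  tt <- seq(0, duration, by = dt)
  phases <- outer(tt, freqs) + rep(offsets, each = length(tt))
  colnames(phases) <- paste0("phi_", oscillator_ids())
  out <- tibble::as_tibble(as.data.frame(phases))
  out <- tibble::add_column(out, t = tt, .before = 1)
  nvuphase:::new_trajectory(out, model = NULL, dt = dt, duration = duration,
                            seed = NA_integer_, init = "fixture",
                            noise = FALSE)
}

test_that("phase difference is first-listed minus second on unwrapped phases", {
  w <- 2 * pi / 100
  traj <- make_const_freq_traj(rep(w, 5), duration = 100,
                               offsets = c(0, 0, 0, 0.7, 0))
  # identical series difference is zero
  expect_true(all(phase_difference(traj, "Glu-GOa")$dphi == 0))
  # constant offset: phi_GO = w t + 0.7, phi_MO = w t, GO-MO gives +0.7
  expect_true(all(abs(phase_difference(traj, "GO-MO")$dphi - 0.7) < 1e-12))
  # detuned pair: slope of the difference equals the detuning
  traj2 <- make_const_freq_traj(c(w, w, w + 0.01, w, w), duration = 500)
  d <- phase_difference(traj2, "GOa-MO")
  fit <- stats::lm(dphi ~ t, data = d)
  expect_equal(unname(stats::coef(fit)[2]), 0.01, tolerance = 1e-10)
  expect_error(phase_difference(traj, "Ox-GO"), "should be one of")
})

test_that("the 2 pi range criterion flags locking on the latter half", {
  # constant difference: locked with zero range
  r <- is_synchronised(rep(0.3, 1000))
  expect_true(r$locked)
  expect_equal(r$range, 0)
  # drift of 0.01 rad/s sampled at 0.1 s over 2000 s: the latter-half
  # window spans 1000 s so the range is ~10 rad > 2 pi
  drift <- 0.01 * seq(0, 2000, by = 0.1)
  r <- is_synchronised(drift)
  expect_false(r$locked)
  expect_equal(r$range, 10, tolerance = 0.01)
  # bounded libration of amplitude < pi about a constant stays locked
  tt <- seq(0, 2000, by = 0.1)
  r <- is_synchronised(1 + 3 * sin(0.02 * tt))
  expect_true(r$locked)
  expect_lt(r$range, 2 * pi)
  expect_error(is_synchronised(rep(0, 10), window = 0), "\\(0, 1\\]")
})

test_that("mean frequency is the endpoint slope over the window", {
  w <- 2 * pi / 137
  traj <- make_const_freq_traj(c(w, w / 2, w / 2, w / 2, w))
  expect_equal(mean_frequency(traj, "Ox"), w, tolerance = 1e-12)
  expect_equal(mean_frequency(traj, "Glu"), w / 2, tolerance = 1e-12)
  # supply-locked oscillator on a real run: within 2 pi / window of the
  # supply frequency
  m <- two_oscillator_model(eps = 0.05, detuning = 0.005)
  tr <- simulate_phases(m, duration = 2000, dt = 0.1, init = "zeros")
  expect_lt(abs(mean_frequency(tr, "GOa") - m$specs$Glu$omega),
            2 * pi / 1000)
})

test_that("all eight tabulated lock patterns classify exactly", {
  tab <- sync_state_table()
  expect_equal(nrow(tab), 8)
  expect_equal(tab$mode, c("TRANSITION", "TRANSITION", "AEROBIC",
                           "TRANSITION", "TRANSITION", "TRANSITION",
                           "GLYCOLYTIC", "GLYCOLYTIC"))
  for (i in seq_len(nrow(tab))) {
    flags <- unlist(tab[i, monitored_pairs()])
    cls <- classify_state(flags)
    expect_equal(cls$state_index, tab$state_index[i])
    expect_equal(cls$mode, tab$mode[i])
  }
})

test_that("patterns outside the table fall back to OTHER / TRANSITION", {
  for (flags in list(rep(TRUE, 5), rep(FALSE, 5),
                     c(TRUE, TRUE, TRUE, TRUE, FALSE))) {
    cls <- classify_state(flags)
    expect_true(is.na(cls$state_index))
    expect_equal(cls$state_label, "OTHER")
    expect_equal(cls$mode, "TRANSITION")
  }
  expect_error(classify_state(c(a = TRUE, b = FALSE, c = TRUE, d = FALSE,
                                e = TRUE)), "names")
})

test_that("lock fixtures reproduce every tabulated state", {
  for (idx in 0:7) {
    pat <- state_pattern(idx)
    rep_ <- analyse_sync(make_lock_fixture(pat))
    expect_equal(rep_$state_index, idx, label = paste("state", idx))
    expect_equal(stats::setNames(rep_$pairs$locked, rep_$pairs$pair),
                 pat, label = paste("pattern", idx))
  }
})

test_that("degenerate and unrealisable lock patterns are handled", {
  # all five oscillators at one frequency: every monitored pair locks,
  # which matches no tabulated row
  rep_ <- analyse_sync(make_const_freq_traj(rep(2 * pi / 100, 5)))
  expect_true(all(rep_$pairs$locked))
  expect_equal(rep_$state_label, "OTHER")
  expect_equal(rep_$mode, "TRANSITION")
  # transitive contradiction: Glu-GO, GO-MO, Ox-MO, GOa-MO locked chains
  # every oscillator together, but Glu-GOa is required unlocked
  expect_error(
    make_lock_fixture(c(TRUE, TRUE, TRUE, TRUE, FALSE)),
    "unrealisable"
  )
})

test_that("analyse_sync agrees with a circular-variance lock oracle", {
  fixtures <- c(lapply(0:7, function(i) make_lock_fixture(state_pattern(i))),
                list(make_const_freq_traj(rep(2 * pi / 100, 5))))
  for (traj in fixtures) {
    rep_ <- analyse_sync(traj)
    for (k in seq_len(nrow(rep_$pairs))) {
      expect_equal(
        rep_$pairs$locked[k],
        circular_lock_oracle(traj, rep_$pairs$pair[k]),
        label = rep_$pairs$pair[k]
      )
    }
  }
})

test_that("classification is invariant to global shifts and time reversal", {
  m <- healthy_rest_model()
  traj <- simulate_phases(m, duration = 500, dt = 0.1, seed = 3)
  base <- analyse_sync(traj)
  shifted <- traj
  for (id in oscillator_ids()) {
    col <- paste0("phi_", id)
    shifted[[col]] <- shifted[[col]] + 5.5
  }
  shifted_rep <- analyse_sync(shifted)
  expect_equal(shifted_rep$state_label, base$state_label)
  expect_equal(shifted_rep$pairs$locked, base$pairs$locked)
  expect_equal(shifted_rep$pairs$range, base$pairs$range, tolerance = 1e-12)
  # the range is symmetric under reversing the order of window samples
  d <- phase_difference(traj, "GO-MO")$dphi
  n <- length(d)
  w <- d[(n - floor(n / 2) + 1):n]
  expect_equal(max(w) - min(w), max(rev(w)) - min(rev(w)))
})

test_that("locked pairs have matching mean frequencies on noise-free runs", {
  traj <- simulate_phases(healthy_rest_model(), duration = 2000, dt = 0.1,
                          seed = 2)
  rep_ <- analyse_sync(traj)
  freqs <- stats::setNames(rep_$frequencies$mean_freq_rad_s,
                           rep_$frequencies$osc)
  window_len <- 1000
  for (k in which(rep_$pairs$locked)) {
    members <- strsplit(rep_$pairs$pair[k], "-", fixed = TRUE)[[1]]
    expect_lt(abs(freqs[[members[1]]] - freqs[[members[2]]]),
              2 * pi / window_len)
  }
})

test_that("tidy and glance views expose the report as tibbles", {
  rep_ <- analyse_sync(make_lock_fixture(state_pattern(2)))
  td <- tidy(rep_)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("pair", "locked", "range"))
  gl <- glance(rep_)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$state_index, 2L)
  expect_equal(gl$mode, "AEROBIC")
  expect_true(all(paste0("freq_", oscillator_ids()) %in% names(gl)))
})
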