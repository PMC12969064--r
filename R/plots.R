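#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

MODE_COLOURS <- c(AEROBIC = "#3366aa", TRANSITION = "#999999",
                  GLYCOLYTIC = "#44aa66")

#' Plot a phase trajectory
#'
#' Either the unwrapped phases of all five oscillators (`what = "phases"`)
#' or the phase differences of the five monitored pairs
#' (`what = "differences"`), the latter being the view in which 1:1 locking
#' is visible as a bounded curve.
#'
#' @param object An `nvu_trajectory`.
#' @param what `"phases"` or `"differences"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nvu_trajectory <- function(object, what = c("phases", "differences"),
                                    ...) {
  what <- match.arg(what)
  if (what == "phases") {
    long <- tidyr::pivot_longer(
      tibble::as_tibble(object), dplyr::all_of(paste0("phi_", OSC_IDS)),
      names_to = "osc", values_to = "phi", names_prefix = "phi_"
    )
    long$osc <- factor(long$osc, levels = OSC_IDS)
    ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$phi,
                                       colour = .data$osc)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (s)", y = "unwrapped phase (rad)",
                    colour = "oscillator") +
      ggplot2::theme_minimal()
  } else {
    long <- purrr::map_dfr(MONITORED_PAIRS, function(p) {
      dplyr::mutate(phase_difference(object, p), pair = p)
    })
    long$pair <- factor(long$pair, levels = MONITORED_PAIRS)
    ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$dphi)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~pair, scales = "free_y") +
      ggplot2::labs(x = "time (s)", y = expression(Delta * phi ~ "(rad)")) +
      ggplot2::theme_minimal()
  }
}

#' Plot a coupling-space state map
#'
#' Heatmap over the swept mutual metabolic couplings, filled either by the
#' coarse metabolic mode (`fill = "mode"`) or by the full synchronisation
#' state (`fill = "state"`).
#'
#' @param object An `nvu_state_map`.
#' @param fill `"mode"` or `"state"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nvu_state_map <- function(object, fill = c("mode", "state"), ...) {
  fill <- match.arg(fill)
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$eps_MO_GO, .data$eps_GO_MO))
  if (fill == "mode") {
    p <- p +
      ggplot2::geom_tile(ggplot2::aes(fill = .data$mode)) +
      ggplot2::scale_fill_manual(values = MODE_COLOURS)
  } else {
    p <- p + ggplot2::geom_tile(ggplot2::aes(fill = .data$state_label)) +
      ggplot2::labs(fill = "state")
  }
  p +
    ggplot2::labs(
      x = expression(epsilon["MO" %->% "GO"]),
      y = expression(epsilon["GO" %->% "MO"]),
      title = sprintf("S = %g", df$S[1])
    ) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Plot frequency-entrainment curves
#'
#' Mean frequency of each oscillator against the supply scale S; entrainment
#' shows up as metabolic curves riding on a supply curve.
#'
#' @param object An `nvu_freq_curves`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nvu_freq_curves <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$osc <- factor(df$osc, levels = OSC_IDS)
  ggplot2::ggplot(df, ggplot2::aes(.data$S, .data$mean_freq_rad_s,
                                   colour = .data$osc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "supply scale S", y = "mean frequency (rad/s)",
                  colour = "oscillator") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
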