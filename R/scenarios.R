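# Supply-scale domain: S = 1 is rest, S = 1.5 full activation.
S_DOMAIN <- c(1, 1.5)

#' Define a sigmoidal coupling-vs-supply curve
#'
#' Couplings respond to increased substrate supply with a saturating,
#' sigmoidal dependence on the supply scale S: weak demand leaves the
#' coupling near its resting value, strong demand drives it towards its
#' activated value, with a smooth logistic transition between. The logistic
#' is rescaled so the curve passes exactly through `rest` at S = 1 and
#' `active` at S = 1.5, and it saturates (stays constant) outside that
#' domain.
#'
#' @param rest Coupling value at rest (S = 1), rad/s.
#' @param active Coupling value at full activation (S = 1.5), rad/s.
#' @param midpoint Logistic midpoint S0 (default 1.25).
#' @param steepness Logistic steepness k (default 20, giving a clearly
#'   saturating transition inside the domain).
#'
#' @return An object of class `nvu_sigmoid`.
#' @export
#' @examples
#' cv <- sigmoid_curve(0.1, 0.3)
#' sigmoid_coupling(cv, 1.25) # midpoint: (0.1 + 0.3) / 2
sigmoid_curve <- function(rest, active, midpoint = 1.25, steepness = 20) {
  stopifnot(rest >= 0, active >= 0, steepness > 0)
  structure(
    list(rest = rest, active = active, midpoint = midpoint,
         steepness = steepness),
    class = "nvu_sigmoid"
  )
}

#' Evaluate a sigmoidal coupling curve at a supply scale
#'
#' @param curve An [sigmoid_curve()].
#' @param S Supply scale(s); values outside `[1, 1.5]` saturate at the
#'   nearest anchor.
#'
#' @return Coupling value(s), rad/s; monotone in S between the anchors.
#' @export
sigmoid_coupling <- function(curve, S) {
  stopifnot(inherits(curve, "nvu_sigmoid"), is.numeric(S), all(S >= 0))
  S <- pmin(pmax(S, S_DOMAIN[1]), S_DOMAIN[2])
  L <- function(s) 1 / (1 + exp(-curve$steepness * (s - curve$midpoint)))
  l0 <- L(S_DOMAIN[1]); l1 <- L(S_DOMAIN[2])
  curve$rest + (curve$active - curve$rest) * (L(S) - l0) / (l1 - l0)
}

#' Build a scenario profile
#'
#' A scenario is a demand-dependent parameterisation of the network: the
#' supply frequencies scale linearly with S while designated couplings
#' follow sigmoidal curves between their resting and activated values.
#'
#' * `healthy`: resting anchors from the healthy parameter table. With
#'   activation, the supply couplings rise (glucose more strongly than
#'   oxygen, since glycolysis is preferentially upregulated under demand):
#'   `eps_Glu_GO` 0.1 to 0.3, `eps_GOa_MO` 0.025 to 0.1, `eps_Ox_MO` 0.1 to
#'   0.15. The mutual metabolic influence flips, `eps_MO_GO` 0.2 to 0.1 and
#'   `eps_GO_MO` 0.1 to 0.2, as glycolysis takes over from oxidative
#'   phosphorylation. The curves are staggered in S (see `midpoints`):
#'   oxygen delivery and the release of mitochondrial inhibition respond
#'   first, while the downstream pyruvate and lactate couplings build up
#'   only after glycolysis has upregulated. The stagger produces the
#'   transient mutual uncoupling of the metabolic oscillators through which
#'   the system passes between the aerobic and glycolytic regimes.
#' * `dementia_oxygen`: impaired oxygen delivery; the `eps_Ox_MO` curve is
#'   scaled down by `hypoxia_factor` at every S, all other curves unchanged.
#' * `dementia_glucose`: impaired glucose/lactate delivery; the resting
#'   glucose coupling is halved (`eps_Glu_GO` 0.1 to 0.05), the whole
#'   lactate-shuttle curve `eps_GOa_MO` is halved, and the post-stimulation
#'   rises of the glucose-dependent couplings are damped: `eps_Glu_GO` is
#'   capped at `damping_factor` times its halved resting value, and
#'   `eps_GO_MO` (pyruvate feed to the mitochondria, which cannot rise when
#'   glycolysis is substrate-limited) is capped at its resting value.
#'
#' The activated-state curve endpoints, midpoints and steepness are model
#' defaults rather than tabulated empirical values; they are exposed here
#' and flagged `non_paper_default` in emitted run metadata.
#'
#' @param name One of `"healthy"`, `"dementia_oxygen"`,
#'   `"dementia_glucose"`.
#' @param hypoxia_factor Multiplier on the oxygen-coupling curve in
#'   `dementia_oxygen` (default 0.2).
#' @param damping_factor Cap on the activated glucose coupling in
#'   `dementia_glucose`, as a multiple of its halved resting value
#'   (default 1: the rise is fully damped).
#' @param midpoints Named numeric vector of per-coupling logistic midpoints
#'   S0 for the five demand-dependent couplings.
#' @param steepness Shared logistic steepness of all demand-dependent
#'   curves.
#' @param sigma Noise strength applied to all oscillators of the scenario's
#'   models (default 0).
#'
#' @return An object of class `nvu_scenario`.
#' @export
#' @examples
#' sc <- build_scenario("healthy")
#' apply_supply_scaling(sc, 1) # the resting-state model
build_scenario <- function(name = c("healthy", "dementia_oxygen",
                                    "dementia_glucose"),
                           hypoxia_factor = 0.2, damping_factor = 1,
                           midpoints = c(eps_Glu_GO = 1.25,
                                         eps_MO_GO = 1.125,
                                         eps_GO_MO = 1.375,
                                         eps_GOa_MO = 1.375,
                                         eps_Ox_MO = 1.125),
                           steepness = 20, sigma = 0) {
  if (!is.character(name) || !name[1] %in% c("healthy", "dementia_oxygen",
                                             "dementia_glucose")) {
    stop("unknown scenario '", name[1],
         "'; valid scenarios: healthy, dementia_oxygen, dementia_glucose")
  }
  name <- name[1]
  stopifnot(hypoxia_factor > 0, hypoxia_factor <= 1, damping_factor >= 1)
  mids <- c(eps_Glu_GO = 1.25, eps_MO_GO = 1.125, eps_GO_MO = 1.375,
            eps_GOa_MO = 1.375, eps_Ox_MO = 1.125)
  mids[names(midpoints)] <- midpoints
  sc <- function(rest, active, nm) {
    m <- if (nm %in% names(mids)) mids[[nm]] else 1.25
    sigmoid_curve(rest, active, midpoint = m, steepness = steepness)
  }
  curves <- list(
    eps_Glu_GO  = sc(0.1, 0.3, "eps_Glu_GO"),
    eps_MO_GO   = sc(0.2, 0.1, "eps_MO_GO"),
    eps_Glu_GOa = sc(0.05, 0.05, "eps_Glu_GOa"),
    eps_MO_GOa  = sc(0, 0, "eps_MO_GOa"),
    eps_GO_MO   = sc(0.1, 0.2, "eps_GO_MO"),
    eps_GOa_MO  = sc(0.025, 0.1, "eps_GOa_MO"),
    eps_Ox_MO   = sc(0.1, 0.15, "eps_Ox_MO")
  )
  if (name == "dementia_oxygen") {
    cv <- curves$eps_Ox_MO
    curves$eps_Ox_MO <- sc(cv$rest * hypoxia_factor,
                           cv$active * hypoxia_factor, "eps_Ox_MO")
  } else if (name == "dementia_glucose") {
    half_rest <- curves$eps_Glu_GO$rest / 2
    curves$eps_Glu_GO <- sc(
      half_rest, min(curves$eps_Glu_GO$active, damping_factor * half_rest),
      "eps_Glu_GO"
    )
    curves$eps_GO_MO <- sc(curves$eps_GO_MO$rest, curves$eps_GO_MO$rest,
                           "eps_GO_MO")
    curves$eps_GOa_MO <- sc(curves$eps_GOa_MO$rest / 2,
                            curves$eps_GOa_MO$active / 2, "eps_GOa_MO")
  }
  structure(
    list(name = name, curves = curves, domain = S_DOMAIN, sigma = sigma,
         hypoxia_factor = if (name == "dementia_oxygen") hypoxia_factor else NULL,
         damping_factor = if (name == "dementia_glucose") damping_factor else NULL),
    class = "nvu_scenario"
  )
}

#' @export
print.nvu_scenario <- function(x, ...) {
  cat(sprintf("<nvu_scenario> %s, S in [%g, %g]\n",
              x$name, x$domain[1], x$domain[2]))
  for (nm in names(x$curves)) {
    cv <- x$curves[[nm]]
    cat(sprintf("  %-12s %.4g -> %.4g\n", nm, cv$rest, cv$active))
  }
  invisible(x)
}

#' Instantiate a scenario at a given supply scale
#'
#' Builds the network model at demand level S: supply frequencies scale
#' linearly (`omega_Glu = S * 2*pi/200`, `omega_Ox = S * 2*pi/100`), the
#' demand-dependent couplings follow the scenario's sigmoid curves, and all
#' other parameters keep their resting values.
#'
#' @param profile An [build_scenario()] profile.
#' @param S Supply scale, within the profile domain `[1, 1.5]`.
#'
#' @return An `nvu_model`.
#' @export
#' @examples
#' m <- apply_supply_scaling(build_scenario("healthy"), 1.5)
#' m$couplings[["eps_MO_GO"]] # ~0.1: the metabolic influence has flipped
apply_supply_scaling <- function(profile, S) {
  stopifnot(inherits(profile, "nvu_scenario"))
  if (!is.numeric(S) || length(S) != 1 ||
      S < profile$domain[1] || S > profile$domain[2]) {
    stop(sprintf("S = %s is outside the scenario domain [%g, %g]",
                 format(S), profile$domain[1], profile$domain[2]))
  }
  eps <- vapply(profile$curves, sigmoid_coupling, numeric(1), S = S)
  args <- c(
    as.list(eps),
    list(omega_Glu = S * 2 * pi / 200, omega_Ox = S * 2 * pi / 100,
         sigma = profile$sigma)
  )
  do.call(healthy_rest_model, args)
}

#' Tidy view of a scenario's coupling curves
#'
#' Evaluates every demand-dependent curve of the scenario on an S grid; handy
#' for plotting the coupling transitions.
#'
#' @param x An `nvu_scenario`.
#' @param S Supply-scale grid (default 101 points over the domain).
#' @param ... Unused.
#' @return A tibble with columns `S`, `coupling`, `value`.
#' @export
tidy.nvu_scenario <- function(x, S = NULL, ...) {
  if (is.null(S)) S <- seq(x$domain[1], x$domain[2], length.out = 101)
  purrr::map_dfr(names(x$curves), function(nm) {
    tibble::tibble(S = S, coupling = nm,
                   value = sigmoid_coupling(x$curves[[nm]], S))
  })
}
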