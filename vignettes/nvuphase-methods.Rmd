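---
title: "Modelling neurovascular energy metabolism with coupled phase oscillators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling neurovascular energy metabolism with coupled phase oscillators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(nvuphase)
```

## The model

`nvuphase` simulates brain energy metabolism in the neurovascular unit as a
network of five Kuramoto phase oscillators:

| id   | process                                   | natural frequency |
|------|-------------------------------------------|-------------------|
| Ox   | vascular oxygen supply                    | $2\pi/100$ rad/s  |
| Glu  | vascular glucose supply                   | $2\pi/200$ rad/s  |
| GOa  | astrocytic glycolysis                     | $2\pi/200$ rad/s  |
| GO   | neuronal glycolysis                       | $2\pi/200$ rad/s  |
| MO   | neuronal oxidative phosphorylation        | $2\pi/100$ rad/s  |

Only phases are modelled. Amplitudes, metabolite concentrations and ATP
stoichiometry are deliberately out of scope: the scientific question is
*coordination* — which processes run in step with which — and phase dynamics
answers it with a handful of parameters and no conservation-of-mass
bookkeeping, which would be inappropriate for a thermodynamically open
tissue.

Each phase obeys

$$\dot\varphi_i \;=\; \omega_i(t) \;+\; \textstyle\sum_j \pm\,
\varepsilon_{j\to i}\,\sin(\varphi_j - \varphi_i) \;+\; \sigma\,\eta_i(t),$$

with three ingredients:

1. **Nonautonomous natural frequencies.**
   $\omega_i(t) = \omega_i\,(1 + A_i \sin(\omega_{\mathrm{mod},i}\,t))$.
   Every oscillator carries its own modulation amplitude $A_i \in [0, 1)$
   and frequency; the default is $A_i = 0$ (no modulation), because no
   modulation amplitudes are tabulated and the reproducible baseline is the
   unmodulated limit. The machinery exists for robustness experiments.
2. **Directed sinusoidal couplings.** Seven directed strengths (rad/s)
   encode substrate routes: glucose drives neuronal and astrocytic
   glycolysis (`eps_Glu_GO`, `eps_Glu_GOa`), pyruvate and astrocytic
   lactate feed the mitochondria (`eps_GO_MO`, `eps_GOa_MO`), oxygen
   drives oxidative phosphorylation (`eps_Ox_MO`), and mitochondrial
   activity *inhibits* glycolysis — `eps_MO_GO` and `eps_MO_GOa` enter
   with a minus sign. The supply oscillators Ox and Glu receive no inputs:
   they are boundary conditions, not regulated quantities. `eps_MO_GOa`
   has no tabulated resting value; it defaults to 0 (astrocytic glycolysis
   is believed to be only weakly feedback-inhibited at rest) and is
   configurable.
3. **Pink-noise forcing.** $\eta_i(t)$ is unit-variance $1/f$ noise,
   independent per oscillator, scaled by a per-oscillator $\sigma$
   (default 0). $1/f$ fluctuations are the canonical model for the
   residual physiological influences on vascular and metabolic rhythms.

A disagreement between the two printed sources for `eps_Glu_GOa`
(0.05 in the consolidated parameter table, 0.025 in the running text) is
resolved in favour of the table; the field is configurable.

## Numerical scheme

Trajectories are advanced with the classical fixed-step fourth-order
Runge–Kutta scheme, 2000 s at $dt = 0.1$ s by default (20,001 samples).
The inner loop is compiled (Rcpp); an R reference implementation of the
identical update, `rk4_step()`, is exported and the two are cross-checked
in the test suite. Lower-order schemes resolve phase-locking boundaries
poorly at comparable step sizes, and adaptive stepping is pointless here:
the noise forcing is defined on the fixed grid.

Noise enters as a *piecewise-constant external forcing*: one sample per
step, held constant across the four RK4 stages. Pink noise is band-limited,
so this is a well-posed deterministic forcing, not an Itô/Stratonovich
stochastic integral; no stochastic calculus is required or used.

Pink noise is synthesised spectrally: independent complex Gaussian Fourier
coefficients are shaped by $f^{-1/2}$ (PSD exponent $-1$, a fixed constant
of the generator), inverse-transformed, and normalised to zero sample mean
and unit sample standard deviation — so scaling by $\sigma$ scales the
sample SD exactly. Each oscillator draws from its own substream, derived
once from the run seed; runs are bit-reproducible given `(seed, duration,
dt)`.

Phases are stored unwrapped, in radians, double precision. Initial phases
default to uniform on $[0, 2\pi)$ drawn with the run seed; a `"zeros"`
policy and explicit 5-vectors exist for deterministic tests. The analysis
window (below) doubles as the transient discard.

## Synchronisation analysis

Two oscillators are *1:1 phase locked* when the range (max − min) of their
unwrapped phase difference over the analysis window — the latter half of
the run — stays below $2\pi$. The window fraction is configurable.
Mean frequencies are endpoint slopes $(\varphi(t_{end}) -
\varphi(t_{start}))/(t_{end}-t_{start})$ over the same window; on a fixed
grid this equals the average instantaneous frequency and is robust to
noise.

Five pairs are monitored: Glu–GO, GO–MO, Ox–MO, GOa–MO, Glu–GOa. Their
lock pattern is matched against a table of eight synchronisation states;
state 2 (GO–MO, Ox–MO, Glu–GOa locked) is the **aerobic** mode, states 6
and 7 (lactate/glucose-driven patterns) are **glycolytic**, the remaining
tabulated states are **transitional**. Patterns outside the table map to
`OTHER` and count as transitional — the taxonomy's catch-all for
incompletely coordinated regimes. `make_lock_fixture()` constructs
synthetic constant-frequency trajectories realising any consistent
pattern, which is how the classifier is tested end-to-end.

## Demand scenarios

Cognitive demand is a supply scale $S \in [1, 1.5]$: supply frequencies
scale linearly ($\omega_{Glu} = S\,2\pi/200$, $\omega_{Ox} = S\,2\pi/100$)
while demand-dependent couplings follow logistic (sigmoidal) curves in
$S$, rescaled to pass exactly through their resting anchor at $S = 1$ and
activated anchor at $S = 1.5$ and clamped outside the domain. The
activated anchors are model defaults, not tabulated measurements (they
are flagged `non_paper_default` in run metadata):

* `eps_Glu_GO` 0.1 → 0.3 and `eps_GOa_MO` 0.025 → 0.1 — glucose routes
  upregulate strongly;
* `eps_Ox_MO` 0.1 → 0.15 — oxygen delivery rises more modestly;
* `eps_MO_GO` 0.2 → 0.1 and `eps_GO_MO` 0.1 → 0.2 — the mutual metabolic
  influence flips as glycolysis takes over from oxidative
  phosphorylation.

**Staggered midpoints.** The curves do not share one logistic midpoint.
Oxygen delivery and the release of mitochondrial inhibition respond early
(midpoint $S_0 = 1.125$), the central glucose drive at $S_0 = 1.25$, and
the downstream pyruvate and lactate couplings late ($S_0 = 1.375$) —
pyruvate and lactate fluxes can only build *after* glycolysis has
upregulated. This ordering matters: if all couplings moved together, the
sum of the mutual GO–MO couplings would stay near 0.3 throughout the
transition and the metabolic pair would never unlock, so the system would
jump straight from aerobic to glycolytic. With the stagger, mid-activation
($S \approx 1.2$–$1.25$) finds each metabolic oscillator locked to its own
supply but the pair mutually unlocked — the transient, unsustainable
uncoupling through which a flexible metabolism passes between regimes.
All midpoints and the shared steepness ($k = 20$) are configurable.

Two dementia-like presets modify only substrate-supply couplings:

* `dementia_oxygen` — the whole `eps_Ox_MO` curve is scaled by a hypoxia
  factor (default 0.2). Chosen so that the resting coupling (0.02 rad/s)
  cannot maintain mitochondrial synchrony against physiological
  fluctuations (see below).
* `dementia_glucose` — resting glucose and lactate couplings are halved
  (`eps_Glu_GO` 0.1 → 0.05, the whole `eps_GOa_MO` curve × 0.5), and the
  post-stimulation rises of the glucose-dependent couplings are damped:
  `eps_Glu_GO`'s activated value is capped at `damping_factor` (default 1)
  times its halved resting value, and `eps_GO_MO` — the pyruvate feed to
  the mitochondria, which cannot increase when glycolysis is
  substrate-limited — is capped at its resting value. With these defaults
  the resting state remains aerobic, but at $S = 1.5$ the glycolytic and
  mitochondrial oscillators run ~0.094 rad/s while the glucose supply is
  at 0.047 rad/s: the system cannot follow demand. One known limitation:
  GO and MO remain locked to *each other* (their mutual coupling never
  falls below 0.1 rad/s on these curves, far above the detuning), so the
  failure is loss of supply tracking rather than full mutual
  desynchronisation.

## Noise in the scenario maps

Coupling-space maps (`sweep_metabolic_couplings()`) classify every cell of
an `eps_MO_GO` × `eps_GO_MO` grid. For the dementia_oxygen resting map,
noise is *essential*, not decorative: oxygen supply and mitochondria share
the same natural frequency, so in a noise-free run any positive coupling
— however small — eventually locks them, and a spurious aerobic corner
survives at every hypoxia factor. With $1/f$ fluctuations at
$\sigma = 0.02$ rad/s the hypoxic coupling (≤ 0.03 rad/s) cannot hold the
pair inside a $2\pi$ range, while physiological couplings (≥ 0.05 rad/s)
can: the aerobic region disappears from the dementia map and persists in
the healthy one. $\sigma$ is a free parameter of the model (no value is
tabulated); 0.02 rad/s was fixed once as the smallest value in a coarse
scan (0.005–0.05) achieving that separation, and map runs are lengthened
to 4000 s (a 2000 s analysis window) because the lock-range statistic is a
maximum excursion of integrated $1/f$ noise and therefore heavy-tailed
over short windows: in rare noise realisations a marginal cell can retain
a sub-$2\pi$ range, and the longer window suppresses (though cannot
abolish) that tail. Entrainment and activation-sequence results use
$\sigma = 0$.

## Problem sizes and runtime

Default analyses use single 2000 s runs at $dt = 0.1$ (20,001 samples,
~15 ms compiled); scenario maps use 11 × 11 (tests) or 31 × 31 (default
API) grids of 4000 s runs; convergence tests use 50 s runs against a
$dt = 10^{-3}$ reference. The full test suite runs in about two minutes
on one core.

## What the synthetic fixtures do and do not show

Classifier tests use constant-frequency synthetic trajectories
(`make_lock_fixture()`): they exercise the lock criterion, the state table
and the mode mapping exactly, but say nothing about whether the *dynamics*
produce those patterns — that is covered by the scenario and sweep tests,
which run the full model. Conversely, all dynamical results here are
statements about this five-oscillator idealisation: real neurovascular
recordings have amplitude dynamics, nonstationary frequencies, spatial
heterogeneity and bidirectional neuronal–vascular feedback, none of which
are modelled. Passing tests validate the simulator and its
parameterisation, not the biology.

## A worked example

```{r rest}
traj <- simulate_phases(healthy_rest_model(), duration = 2000, seed = 1)
rep <- analyse_sync(traj)
rep
glance(rep)
```

```{r activation}
sc <- build_scenario("healthy")
sweep_supply_modes(sc, S = c(1, 1.25, 1.5), seed = 1)
```

```{r plots, fig.alt = "Phase differences of the five monitored pairs"}
autoplot(traj, what = "differences")
```

```{r curves, fig.alt = "Demand-dependent coupling curves of the healthy scenario"}
library(ggplot2)
ggplot(tidy(sc), aes(S, value, colour = coupling)) +
  geom_line() +
  labs(y = "coupling strength (rad/s)") +
  theme_minimal()
```
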