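Package: nvuphase
Title: Nonautonomous Phase-Oscillator Model of Neurovascular-Unit Energy Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates brain energy metabolism in the neurovascular unit as a
    network of five coupled Kuramoto phase oscillators: oxygen supply, glucose
    supply, astrocytic glycolysis, neuronal glycolysis, and neuronal oxidative
    phosphorylation. Oscillators carry time-modulated natural frequencies and
    pink (1/f) noise forcing, and are integrated with a fixed-step fourth-order
    Runge-Kutta scheme. Pairwise 1:1 phase locking over the latter half of each
    run is classified into synchronisation states and coarse metabolic modes
    (aerobic, transition, glycolytic). Demand-dependent supply scaling and
    dementia-like scenario presets support sweeps over coupling space and
    supply scale, producing tidy state maps and frequency-entrainment curves
    with ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
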