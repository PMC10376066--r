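Package: fhnflow
Title: Slow-Fast Dynamics and Waves in FitzHugh-Nagumo-Type Neuron Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the qualitative analysis of FitzHugh-Rinzel and
    FitzHugh-Nagumo neuron models and their non-homogeneous reaction-diffusion
    extensions. Provides fixed-step Runge-Kutta integration of the model
    families, fixed-point and Hopf-bifurcation analysis via the Routh-Hurwitz
    and Cardan criteria, detection and symbolic encoding of mixed-mode
    oscillations, a moving-focus approximation with a small-oscillation
    counting formula, slow-fast subsystems with a fold blow-up normal form and
    its first integral for canard classification, a Poincare return-map
    periodic-orbit finder, and a method-of-lines simulator for oscillatory-
    excitable media with wave-propagation diagnostics (frequency filtering,
    death spots). Results are returned as tibbles with broom-style tidiers
    and ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    readr,
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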