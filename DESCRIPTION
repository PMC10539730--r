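Package: hypercest
Title: Simulation and Analysis of Hyperpolarized Xe-129 Hyper-CEST and
    Ultra-Fast Z Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and analysing hyperpolarized Xe-129
    chemical-exchange saturation transfer (Hyper-CEST) experiments on
    xenon-host biosensors such as cryptophanes. Implements the analytic
    exchange-saturation model of the depolarization rate (direct
    spin-lock term plus Lorentzian CEST dips), a numerical two-pool
    Bloch-McConnell propagator used as an independent oracle, a spatially
    encoded ultra-fast Z (UFZ) spectroscopy simulator with gradient
    encoding and off/on subtraction, Lorentzian dip fitting with
    inversion back to the caged fraction and exchange rate, and
    experiment-design calculators (gradient bounds, saturation-strength
    regimes, saturation-time trade-offs). Spectra and profiles are plain
    tibbles; fitted dips carry broom-style tidy() and glance() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
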