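Package: stochpace
Title: Stochastic Pacing and Eigenmode Analysis of Cardiac Alternans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to study and predict action potential duration (APD)
    alternans in paced cardiac cells. Provides pluggable beat-to-beat cell
    models (restitution maps, a calcium-coupled two-variable map and a
    minimal two-current ionic model), numerical eigenmode analysis of the
    stimulus-to-stimulus map (Jacobian, alternans and memory eigenvalues),
    rational transfer functions between cycle-length and APD/DI deviation
    series, conventional restitution protocols (dynamic, S1S2, memory
    amplitude, bifurcation search), ARMA system identification during
    stochastic pacing, nonparametric DFT transfer estimates, and windowed
    tracking of the alternans eigenvalue during cycle-length ramps or
    simulated drug application, with extrapolation to the alternans onset.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
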