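Package: ellcorr
Title: Signal and Noise Correlations in a Cerebellum-Like Feedback Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a pair of electrosensory lateral line lobe (ELL)
    superficial pyramidal cells with depolarizing-afterpotential bursting,
    driven by sinusoidal amplitude modulations and by banks of spiking
    granule cells through plastic parallel-fiber synapses subject to
    anti-Hebbian burst-timing-dependent depression and slow non-associative
    potentiation. Provides the companion spike-train statistics: binned
    auto- and cross-correlograms, the shuffle predictor, noise
    correlograms, and signal/noise cross-correlation coefficients, along
    with structured low-pass-filtered noise generators, doubly stochastic
    surrogate spike trains for validating the analysis stage, and
    parameter-sweep experiments contrasting spatially local (feedback off)
    and global (feedback recruited) stimulation geometries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    stats,
    readr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
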