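Package: phasedyn
Title: Switching Dynamics of EEG Phase-Synchronization Networks Across the Lifespan
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify time-resolved reconfiguration ("switching
    dynamics") of EEG phase-synchronization networks and to relate it to a
    group-by-condition study design. Provides segment-level univariate
    variability metrics (Welch power spectra, multiscale standard deviation,
    multiscale sample entropy and its SD-normalized variant), Morlet-wavelet
    phase extraction with sliding-window circular-correlation networks, the
    correlation-distance matrix of network topologies over time with
    jump-length statistics (mean, SD, kurtosis) on a timescale-by-frequency
    grid, mean-centered Task Partial Least Squares with permutation and
    bootstrap inference, a connectome-coupled phase-oscillator network model
    with parameter sweeps and k-medoids state clustering, and a seeded
    synthetic-cohort generator with planted lifespan effects for end-to-end
    validation. Includes minimal readers for EDF, BrainVision and plain
    matrix-plus-sidecar EEG recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    cluster,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
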