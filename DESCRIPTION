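Package: neurodyn
Title: Multiscale Instability Analysis of Neuronal Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies dynamical instability of neuronal activity across
    scales: per-spike onset rapidness and local variation of interspike
    intervals, quartile-based three-state Markov chain transition analysis,
    local-divergence Lyapunov exponents in (V, dV/dt) phase space,
    Ornstein-Uhlenbeck modeling of local field potentials with Morlet
    wavelet decomposition and augmented Dickey-Fuller stationarity
    profiling, non-stationary noise analysis of voltage-clamp sodium
    current sweeps with Boltzmann inactivation fits, and spike-pattern
    clustering and classification (Gaussian mixtures on adjacent
    interspike intervals, random-forest probabilistic distances). Includes
    seeded synthetic-data generators with known ground truth for every
    input class.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    mclust,
    randomForest,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
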