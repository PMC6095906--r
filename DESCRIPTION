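Package: eegnetcomp
Title: Scalp- Versus Source-Level EEG Functional Network Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for comparing functional brain
    networks estimated from scalp EEG sensors with networks estimated after
    linear source reconstruction. Provides a coupled-oscillator cohort
    simulator with a spherical-head forward model, common-average referencing
    and zero-phase FIR filtering, weighted minimum-norm (wMNE) and sLORETA
    inverse operators with ROI aggregation, four connectivity estimators
    (phase locking value, phase lag index, amplitude envelope correlation,
    and leakage-corrected envelope correlation via symmetric
    orthogonalization), minimum spanning tree topology descriptors (leaf
    fraction, diameter, degree divergence, tree hierarchy), and a percentile
    bootstrap for comparing non-overlapping Spearman correlations between the
    two domains.
License: MIT + file LICENSE
Encoding: UTF-8
SystemRequirements: fftw3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
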