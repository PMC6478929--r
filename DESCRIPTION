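Package: nemadyn
Title: Locomotion State Inference, Repetitive-Reversal Quantification and
    Neural Time-Series Analysis for C. elegans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying Caenorhabditis elegans behavior and neural
    dynamics from tracking and imaging time series. Provides a six-state
    hidden Markov model (forward/backward crawling with body-orientation
    bookkeeping, forward and omega turns) fitted by Baum-Welch with fixed
    shape/direction emissions, censoring-aware discrete-hazard survival
    estimation of forward-bout durations, a perturbed-Poisson reversal model
    yielding a repetitive behavior index, complex Morlet wavelet
    time-frequency analysis of 1-Hz fluorescence traces with weighted
    genotype spectra and a bootstrap-permutation spectral comparison,
    motion-calcium phi-coefficient association, and a cross-species
    ortholog enrichment and association score over fold-enrichment cutoff
    grids. Seeded synthetic-data generators with ground truth make every
    stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
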