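Package: lm2r
Title: Lock-Mutate-Map-Rescue Analysis of RNA Secondary-Structure Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting RNA secondary-structure ensembles by
    compensatory mutagenesis read out through chemical mapping.  Designs
    mutate-map-rescue (M2R) quartets and double-base-pair "lock" mutants,
    reads and writes RDAT chemical-mapping files with normalization,
    signal-attenuation correction and background subtraction, computes the
    quantitative rescue factor for quartets of reactivity profiles, simulates
    M2R experiments with a bundled McCaskill partition-function backend to
    calibrate rescue factors against helix frequencies, and converts observed
    rescue factors into sample-based Bayesian posteriors over helix
    frequencies and helix-helix correlation values that discriminate
    Monod-Wyman-Changeux conformational-selection models from alternatives.
    Includes a synthetic-fixture generator for end-to-end validation and
    two-state linear decomposition of profiles against locked-state
    endpoints.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
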