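Package: neighborpref
Title: Complementarity of 2-D Fingerprint and 3-D Shape-Overlay Molecular Neighboring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds and compares precomputed chemical-structure neighbor
    relationships based on 2-D substructure-fingerprint Tanimoto similarity and
    on 3-D Gaussian-shape-overlay similarity (shape-, color- and
    combo-Tanimoto at the shape-optimized superposition). Provides the
    molecular data model with covalent-unit handling, parent-compound
    selection and conformer-eligibility filtering used to construct
    bias-corrected compound datasets, the Neighbor Preference Index (NPI)
    per-compound complementarity statistic with its histogram, delta-NPI and
    correlation diagnostics, threshold-comparability statistics, and a seeded
    synthetic-population generator with planted 2-D/3-D cluster structure for
    end-to-end testing without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ChemmineR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
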