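Package: tfatlas
Title: Transcription-Factor Repertoire Evolution, Network Isolation and
    Expression Contrasts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how mammalian transcription-factor (TF)
    repertoires evolve and how that evolution reshapes regulatory networks.
    Builds per-species TF catalogs from profile-HMM domain-hit tables,
    reconciles TF-family gene trees with a species tree by LCA mapping to
    produce a per-branch duplication/loss atlas and lineage turnover
    statistics, classifies TFs as isolated versus large-component in a
    score-thresholded TF-to-TF interaction network, computes functional
    cartography (within-module degree z-score and participation
    coefficient with eight role classes), fits negative-binomial
    expression contrasts across TF-interaction gene types, and compares
    per-GO-term TF sets between species with loess-smoothed overlap
    curves. A synthetic-data generator with recorded ground truth stands
    in for genome, interaction-database and expression downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
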