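Package: dhfrscan
Title: Deep Mutational Scanning Analysis of DHFR-PCA Interaction Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for deep mutational scanning (DMS) of protein
    interaction motifs measured by dihydrofolate reductase protein-fragment
    complementation assays (DHFR-PCA). Covers degenerate single-codon library
    design (NNN/NNK), a seeded synthetic-data generator for pooled competition
    assays, codon-variant calling from amplicon reads via global alignment to a
    wild-type reference, log2 enrichment interaction scores rescaled to a
    wild-type = 0 / nonsense median = -1 frame, selection coefficients from
    pooled competitions, a Mann-Whitney/Benjamini-Hochberg filter and
    classification cascade, sliding-window growth-rate estimation from optical
    density time series, and quantification of colony-array PCA screens.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
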