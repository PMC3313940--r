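Package: mirword
Title: miRNA Target Discovery from Ranked 3'UTR Word Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Target discovery for a single over-expressed microRNA.
    Ranks genes by an empirical-Bayes moderated t-statistic after a
    two-arm transfection experiment, scores every 3'UTR word of length
    5-7 for association with down-regulation using a running-sum rank
    statistic calibrated against dinucleotide-preserving sequence
    shuffles and rank permutations (Z-score, rank, empirical FDR),
    scans 3'UTRs for canonical seed-match sites (6mer, 7mer-A1,
    7mer-m8, 8mer), and integrates tumor-cohort miRNA/mRNA expression
    with external target predictions to nominate direct targets.
    Includes a synthetic-data generator that emulates both study
    designs so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    limma,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
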