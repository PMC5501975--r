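Package: mirTargetRank
Title: Multi-Cohort MicroRNA Target Prioritization and Drug-Synergy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to prioritize microRNA targets from multiple
    tumor/normal expression cohorts and to quantify drug synergy.
    Detects canonical seed-match sites (8mer, 7mer-m8, 7mer-A1, 6mer,
    offset-6mer) in 3'-UTR sequences and emulates a multi-predictor
    consensus vote; computes per-cohort permutation tumor-vs-normal
    tests with Benjamini-Hochberg false discovery rates, log2 fold
    changes and miRNA-mRNA Pearson anticorrelation on matched samples;
    combines cohort evidence with Fisher's and Stouffer's methods into
    a ranked target table; fits the Chou-Talalay median-effect model to
    dose-response data for CC50 determination and Loewe combination-index
    curves; and scans promoter sequences with log-odds position weight
    matrices reporting ATG-relative coordinates. A synthetic-data module
    generates cohorts, UTR/promoter sequences and dose-response series
    with known ground truth so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
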