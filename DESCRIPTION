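Package: sciserum
Title: Serum TMT Proteomics Analysis of Neurological Recovery After
    Spinal Cord Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Re-implements, as a tested and reusable pipeline, an
    untargeted serum TMT 11-plex proteomics analysis comparing spinal
    cord injury patients with strong versus no neurological recovery:
    PSM-to-peptide data assembly (isolation-interference filtering,
    isotope impurity correction, median scaling, reference-pool log2
    ratios), preprocessing (group-wise missingness filtering, iterative
    PCA imputation, quantile normalization, batch correction,
    trimmed-mean protein roll-up), covariate-adjusted empirical-Bayes
    moderated differential abundance with a variance-adaptive
    fold-change threshold, FDR-controlled power analysis via a
    noncentral-t fixed point, Fisher-exact functional enrichment, and
    ELISA standard-curve calibration with limit-of-blank/detection
    statistics.  A synthetic-data module generates study-like TMT
    designs and ELISA plates so that every stage is testable without
    access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    limma,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
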