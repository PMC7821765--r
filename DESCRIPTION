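Package: vtburden
Title: Rare-Variant Prioritization and Molecular Burden for Cardiac Gene-Panel Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prioritizing rare variants from targeted cardiac
    gene-panel sequencing of ventricular-tachycardia cohorts: a stepwise
    filtering cascade (common-variant removal against reference databases,
    synonymous removal, control-cohort subtraction, curation exclusions),
    consensus pathogenicity classing from ten in-silico predictor calls
    (classes I-IV), ACMG/AMP five-tier evidence combination, per-subgroup
    molecular-burden and functional-category tables, and nonparametric
    subgroup statistics (Shapiro-Wilk gate, Kruskal-Wallis with Dunn
    pairwise comparisons, chi-square/Fisher carrier tests). A seeded
    synthetic-cohort generator emulates the statistical structure of a
    three-arm ventricular-tachycardia case series with a population control
    group, so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
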