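Package: cvhmr
Title: Mendelian Randomization of Cardiovascular Health on Epigenetic Age
    Acceleration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for estimating causal effects of composite
    cardiovascular-health (CVH) scores on epigenetic age acceleration (EAA)
    with Mendelian randomization. Implements the 12-point six-metric CVH
    score, genotype quality control (exact Hardy-Weinberg test, call rate,
    minor allele frequency), additive per-SNP association scans with
    covariate adjustment, greedy LD clumping, weighted genetic-risk-score
    instruments with an auditable assumption-checking and SNP-pruning
    workflow, one-sample two-stage least-squares estimation, and a
    two-sample estimator suite (inverse-variance weighted, weighted median,
    MR-Egger, MR-PRESSO, Cochran's Q, multivariable IVW) over harmonized
    summary statistics. A synthetic-cohort generator with known ground
    truth makes every stage testable without access to individual-level
    biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    withr
Config/testthat/edition: 3
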