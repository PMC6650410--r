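Package: pepage
Title: Urinary Peptidome Age-Score Pipeline for CE-MS Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for capillary electrophoresis mass spectrometry (CE-MS)
    urinary peptidomics aging studies: internal-standard normalization of
    migration time and signal amplitude, mass- and migration-tolerance
    matching of peptide lists across samples into a master matrix,
    per-peptide Wilcoxon rank-sum screening with Westfall-Young maxT
    step-down permutation adjustment, consensus peptide selection across
    pairwise age comparisons, a support-vector-machine age score (signed
    kernel-space distance to the maximal-margin hyperplane) with
    take-one-out panel reduction, and downstream renal quantifications
    (Weibel stereological glomerular volume, qPCR relative expression with
    genomic-contamination correction, albumin/creatinine ratio,
    area-fraction summaries, two-way ANOVA with Tukey post test).  A
    synthetic-cohort generator with planted age effects provides ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
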