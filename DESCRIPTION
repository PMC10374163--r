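Package: camMR
Title: Alpha-Angle Morphometry, GWAS Meta-Analysis and Mendelian
    Randomization for Cam-Type Hip Shape
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline linking femoral head shape to hip
    osteoarthritis: alpha-angle measurement from hip outline point sets
    (osteophyte-excluding circle of best fit), observational association
    models, quality control and fixed-effects inverse-variance meta-analysis
    of GWAS summary statistics with heterogeneity and genomic-inflation
    diagnostics, LD clumping with proxy substitution, Bayesian colocalization
    via approximate Bayes factors, and bidirectional two-sample Mendelian
    randomization (inverse-variance weighted, Egger, weighted median, and
    mode estimators with single-SNP and leave-one-out sensitivity analyses).
    A synthetic-data module generates hip outlines with known ground-truth
    alpha angles, toy genotype cohorts, multi-cohort summary statistics with
    configurable causal and pleiotropic architecture, and block-structured
    LD matrices, so the whole chain is testable without restricted cohort
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    withr
Config/testthat/edition: 3
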