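Package: statinpgx
Title: Simulation and Candidate-Gene Pharmacogenetic Analysis of
    Atorvastatin Pharmacokinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for candidate-gene pharmacogenetic studies of
    atorvastatin exposure in healthy-volunteer bioequivalence cohorts.
    Simulates cohorts with genotype-dependent one-compartment oral
    pharmacokinetics, computes non-compartmental parameters (AUC,
    terminal slope, half-life, apparent clearance and volume of
    distribution), translates per-variant genotype calls into
    star-allele diplotypes and gene-level phenotypes (SLCO1B1 transporter
    function, CYP3A5 expresser status, CYP2D6 activity score and others)
    from data-driven definition tables, and runs a two-stage
    univariate/multivariate statistical pipeline with dose/weight
    normalisation, Bonferroni-corrected inference, Hardy-Weinberg
    equilibrium testing and adverse-drug-reaction analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    glmnet,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
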