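Package: ccorganotrait
Title: Organ-Weight and Glucose-Tolerance Phenotype Analysis for Collaborative Cross Diet-Challenge Cohorts
Version: 0.1.0
Authors@R:
    person("CC", "Phenomics Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for diet-challenge phenotyping
    studies in Collaborative Cross (CC) mouse panels. Generates synthetic
    cohorts with additive line, sex, diet and line-by-diet effects at a
    configurable study design (bi-weekly body weights, intraperitoneal
    glucose tolerance test curves, terminal organ weights); derives the
    standard phenotypes (trapezoidal glucose AUC, body-weight change,
    percent organ weights, group-level delta-organ/delta-BW ratios);
    estimates broad-sense heritability and the genetic coefficient of
    variation per line stratum from one-way random-effects ANOVA with the
    unbalanced effective-sample-size correction; computes Pearson trait
    correlation matrices and Welch diet contrasts with star annotations;
    and runs per-line cross-validated classification (decision tree,
    random forest, Gaussian naive Bayes, k-nearest neighbours) and
    repeated-split regression (linear, kNN) of adjusted organ weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    pheatmap,
    stats,
    tools,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
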