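Package: genemeta
Title: Meta-Analysis of Case-Control Genetic Association Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for meta-analysis of case-control single-nucleotide
    polymorphism association studies reported as genotype counts. Collapses
    genotype triples into 2x2 exposure tables under additive (homozygote
    contrast), dominant and recessive inheritance models; computes per-study
    odds ratios with Woolf confidence intervals; tests Hardy-Weinberg
    equilibrium in control arms (chi-square goodness of fit and exact test);
    quantifies between-study heterogeneity (Cochran Q, I-squared, the
    DerSimonian-Laird tau-squared moment estimator); pools effects by
    Mantel-Haenszel fixed effects or DerSimonian-Laird random effects with
    automatic model selection on the Q-test; and provides funnel-plot
    coordinates, Egger's regression test for funnel asymmetry, leave-one-out
    sensitivity analysis, stratified subgroup analysis and a seeded synthetic
    study generator for estimator validation. Ships the 11-study MDM2 T309G
    (rs2279744) lung-cancer dataset as a worked example.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
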