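Package: pairsig
Title: Two-Gene High/Low Signature Discovery from Pathway-Panel Tumor Subtyping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discovery and evaluation of a two-gene high/low expression
    signature for tumor cohorts. Samples are stratified by unsupervised
    hierarchical clustering on a pathway gene panel, the worst-prognosis
    cluster is identified by Kaplan-Meier median survival, and an
    (up-regulated, down-regulated) gene pair is elected by maximizing
    concordance of its median-dichotomized high/low call with the
    worst-prognosis cluster. Downstream evaluation covers survival
    (Kaplan-Meier, log-rank, forward stepwise likelihood-ratio Cox),
    treatment response (exact Fisher and Freeman-Halton contingency tests,
    binary-predictor ROC/AUC), mutation-derived features (tumor mutational
    burden, MATH intratumor heterogeneity, 96-context mutational-signature
    refitting by non-negative least squares), and marker-based immune
    profiling (population scores, clonotype richness and Shannon diversity).
    A seeded synthetic-cohort generator reproduces the statistical structure
    the analysis assumes so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
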