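Package: apoptonet
Title: Drug-Induced Apoptosis Network Reconstruction from Perturbation
    Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs a drug-induced apoptosis gene subnetwork from pooled
    drug-perturbed versus control expression data. Provides moderated-t
    differential expression with Bonferroni adjustment, apoptosis gene-set
    enrichment (hypergeometric over-representation and an absolute-mean
    permutation enrichment test), Gaussian Bayesian network structure learning
    with a score-equivalent conjugate marginal-likelihood score and hill
    climbing with random restarts, bootstrap model averaging with edge
    confidence thresholds, and validation of predicted edges against a curated
    reference interaction network. A synthetic-data generator with a known
    linear-Gaussian ground-truth network makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    limma,
    fgsea,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
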