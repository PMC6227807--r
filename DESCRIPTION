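Package: entroscape
Title: Entropy Landscapes of Single-Cell Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Binary Shannon entropy analysis of single-cell gene expression
    along differentiation trajectories. Expression is binarized into
    detected/undetected calls, per-population marginal and pairwise-joint
    entropies are estimated (maximum-likelihood, Miller-Madow and
    James-Stein shrinkage estimators) with jackknife standard errors, and
    entropy is traced along a user-supplied population ordering to locate
    commitment-associated entropy peaks. Includes transformations for two
    published qPCR Ct conventions and a seeded synthetic-data generator in
    which populations are mixtures of discrete gene-regulatory-network
    substates, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
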