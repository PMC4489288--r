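Package: cofunet
Title: Probabilistic Functional Gene Networks: Construction, Assessment and
    Gene Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and using probabilistic functional gene
    networks. Constructs gold-standard co-functional gene pairs from pathway
    annotations (GMT), calibrates raw evidence pair-scores into log-likelihood
    scores under a naive Bayes framework, integrates evidence layers by the
    weighted-sum method, and assesses networks with cumulative odds-ratio
    precision-recall curves and per-term guilt-by-association ROC/AUC.
    Provides two complementary gene-prioritization algorithms (direct
    network neighborhood of guide genes, and context-associated hub scanning
    against differentially expressed gene sets via one-sided Fisher tests),
    reciprocal-best-hit orthology translation of cross-species guide genes,
    and seeded synthetic-data generators with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'gene-ids.R'
    'AllGenerics.R'
    'AllClasses.R'
    'network.R'
    'annotation.R'
    'io.R'
    'goldstandard.R'
    'lls.R'
    'integrate.R'
    'prioritize.R'
    'benchmark.R'
    'ortho.R'
    'synth.R'
    'cofunet-package.R'
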