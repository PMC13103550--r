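Package: dimorphix
Title: Multi-Omic Sex-Dimorphism Analysis with X-Inactivation Signature Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for factorial (sex-by-disease) differential analysis across
    methylome, transcriptome and proteome feature matrices, with empirical-Bayes
    variance moderation; bimodality testing and kernel-density trough
    classification of XIST expression; chromosome-level (pseudoautosomal-aware)
    gene-set enrichment for X-inactivation signatures; reference-based immune
    cell deconvolution benchmarking; and clinical covariate screens. Includes a
    synthetic multi-omic cohort generator that plants known effect structure for
    end-to-end recovery testing, and a single-call pipeline orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    limma,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    boot,
    car,
    fgsea,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
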