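Package: vafclust
Title: Subclone Deconvolution from Variant Allele Frequencies in Bulk Tumor
    Sequencing
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Decomposes bulk tumor sequencing data into subclones by
    clustering variant allele frequencies (VAFs) under a beta error model
    that accounts for the dependence of within-cluster VAF variance on
    sequencing depth and on mean VAF. Variants are merged agglomeratively
    under a weighted negative log-likelihood distance and the resulting tree
    is partitioned adaptively with a parametric-bootstrap variance test.
    Supports single- and multi-sample tumors, assignment of copy-number
    affected variants with mutant-copy multiplicity inference, tumor purity
    and cellular prevalence estimation, read-count simulators for two-subclone
    and multi-sample tumors, and a pairwise precision/recall accuracy score.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
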