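Package: clonalspread
Title: Multi-Region Tumor Phylogenetics and Clonal Deconvolution from
    RNA-Seq Variant Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reusable pipeline for reconstructing the clonal spread of
    pelvic high-grade serous carcinoma from multi-region RNA-seq variant
    calls. Merges per-caller VCFs into consensus somatic variants through a
    defined filter cascade (caller agreement, germline subtraction,
    tumor/normal coverage, population-variant and RNA-editing-site
    removal), quantifies intratumor heterogeneity under a joint coverage
    constraint, infers maximum-likelihood sample phylogenies from
    concatenated SNV pseudo-alignments with bootstrap consensus support,
    and deconvolves clone trees with per-sample clone frequencies from
    variant allele frequencies by exhaustive rooted-tree enumeration and
    constrained least squares. A clonal-evolution simulator with
    ground-truth output makes every stage testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    phangorn,
    phytools,
    vcfR,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
LinkingTo:
    Rcpp,
    RcppArmadillo
Config/testthat/edition: 3
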