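Package: clonepitope
Title: Clonal Mutation Analysis and MHC Class II Neoantigen Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for predicting HLA class II
    restricted neoantigen candidates from somatic mutation calls in tumor
    cohorts. Implements mutation-level quality filters (panel of normals,
    germline databases, read depth), sample-level purity and ploidy gates,
    cancer cell fraction posteriors from a beta model on allele read counts
    with clonal/subclonal classification and a grid maximum-likelihood purity
    estimator, RNA expression gating, mutant protein construction from HGVS-p
    descriptions (missense, in-frame indels, frameshift translation),
    enumeration of mutation-overlapping peptide windows for MHC class I and
    II, a pluggable binding-affinity predictor interface with a deterministic
    built-in scorer and IC50 binder categories, and cohort-level burden,
    gene-frequency and HLA-allele enrichment statistics. A synthetic cohort
    generator with a ground-truth manifest makes every stage testable without
    external data or binaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
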