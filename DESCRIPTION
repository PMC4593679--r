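Package: cladophylo
Title: Phylotranscriptomic Supermatrix Construction and Maximum-Likelihood
    Inference for Sea-Slug Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained phylotranscriptomic pipeline: construction of a
    custom amino-acid log-odds substitution matrix from conserved gap-free
    alignment blocks, assembly of a core-orthologue database anchored on a
    reference taxon, assignment of six-frame-translated transcript fragments
    to orthogroups by profile search with E-value and top-quartile filters
    plus reciprocal-best-hit confirmation, gene-tree based paralogy filtering
    (out-paralogue discard, in-paralogue consensus), nucleotide supermatrix
    assembly with occupancy-filtered and degeneracy-coded variants, and
    GTR+I+G maximum-likelihood tree inference with stepwise-addition starting
    trees, NNI search, nonparametric bootstrap and majority-rule consensus.
    Includes a synthetic-data generator with known ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    ape,
    withr,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    Matrix,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'RcppExports.R'
    'cladophylo-package.R'
    'degen.R'
    'gtr.R'
    'likelihood.R'
    'matrixgen.R'
    'orthology.R'
    'paralogy.R'
    'simulate.R'
    'pipeline.R'
    'search.R'
    'supermatrix.R'
    'utils.R'
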