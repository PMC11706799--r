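Package: barcodeplace
Title: Phylogenetic Placement Accuracy Experiments with DNA Barcodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking the accuracy of phylogenetic placement of
    short DNA barcode (COI) sequences onto multigene backbone trees. Provides
    a rooted tree data model with Newick and jplace v3 input/output, pruning
    and grafting; a synthetic-data generator for family-structured trees,
    GTR+Gamma multigene alignments and missing-gene masks; quality-control
    filters for gappy and short gene sequences; nested random, stratified and
    biased backbone subsampling; desk-scale likelihood (EPA-style, with
    likelihood weight ratios) and distance (APPLES-style, least-squares)
    placement engines; the sister-clade correctness metric (PCP, CP, PCP-CP);
    aligned rank transform factorial ANOVA with pairwise contrasts; and an
    orchestrated experiment pipeline with reproducible seeding.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
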