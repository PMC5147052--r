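Package: clonemapr
Title: Mapping Single-Cell Expression onto Clonal Copy-Number Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for genotyping bulk-called copy-number alterations in
    individual cells from single-cell RNA-seq, building rooted clone
    phylogenies from binary CNV genotypes by Fitch-Margoliash least-squares
    fitting, and analysing expression along the resulting clonal pseudotime:
    empirical-threshold presence/absence calls with Benjamini-Hochberg
    control and cross-validated error estimation, Jaccard-distance genotype
    collapsing and out-group rooting, backbone-path early/mid/late binning
    with monotone gene detection, receptor dose-response gene ranking,
    molecular subtype classification, and an exon-level read-depth test for
    intragenic in-frame deletions. Includes a negative-binomial clone-tree
    simulator so the whole pipeline is exercisable end-to-end on synthetic
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    ape,
    pracma,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
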