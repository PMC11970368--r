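Package: vcfpdist
Title: Pairwise p-Distance Matrices and Distance-Based Phylogenies from VCF
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes pairwise p-distance matrices directly from Variant Call
    Format (VCF) files, or from aligned FASTA/Phylip alignments, in a single
    streaming pass with per-pair missing-data accounting. Builds
    neighbor-joining and UPGMA phylogenies from the resulting matrices,
    writes Phylip-format matrices and Newick trees, and supports
    site-resampling bootstrap with majority-rule consensus support values.
    Includes a synthetic-population fixture generator with closed-form
    expected distances for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
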