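Package: afphylo
Title: Alignment-Free Phylogenomics with Genome Evolution Simulation and
    Jackknife Support
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating alignment-free (AF) phylogenomic methods
    on whole microbial genomes. Simulates genome sets under birth-death
    trees with GTR+Gamma nucleotide substitution, lateral genetic transfer
    and inverted-translocation rearrangement; computes nine AF pairwise
    distances (d2, cvt, ffp, spaced words, co-phylog, acs, kmacs, gram, kr)
    plus shared k-mer fractions; builds neighbour-joining trees; scores
    them against reference topologies with the normalized Robinson-Foulds
    distance; and attaches fragment-deletion jackknife support values to
    AF trees.
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
    Matrix,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
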