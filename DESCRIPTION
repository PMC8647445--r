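Package: lincr
Title: Linear-Time Common Refinement of Rooted Phylogenetic Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decides whether k rooted phylogenetic trees on a common leaf
    set admit a common refinement and, when they do, constructs the unique
    least-resolved refinement whose cluster set is the union of the input
    cluster sets. The core is a bottom-up O(k|L|) algorithm that assembles
    the parent function of the candidate refinement directly and then
    verifies the result. Independent reference algorithms (brute-force
    hierarchy union and Aho's BUILD on rooted triples), Newick input and
    output, a compatible-instance simulator, and a command-line interface
    are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    optparse,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
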