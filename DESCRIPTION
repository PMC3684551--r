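Package: mobscan
Title: Anchor-Based Detection of Putative Mobile Elements in Homologous Chromosomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fast exact L-gram anchoring of homologous chromosomes using a
    cyclic-polynomial rolling hash, greedy colinear chaining of common L-grams
    into conserved segment pairs, classification of the remaining non-conserved
    regions into putative mobile-element events (transposon-sized insertions
    and deletions, solo-LTR-sized events, unresolved segments), and
    multi-strain mobilome analysis: intersection of conserved segments across
    strains, binary presence/absence profiles, Hamming distances and a UPGMA
    mobilome tree. Includes a synthetic strain-set simulator with a
    machine-readable truth log so the whole pipeline can be exercised and
    validated without real genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    rtracklayer,
    jsonlite,
    ape,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
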