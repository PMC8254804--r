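Package: ldthgt
Title: Indirect Horizontal Gene Transfer Inference from Later-Divergence-Time Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the indirect (tree-free) detection of horizontal gene
    transfer from later-divergence-time (LDT) graphs, i.e., graphs on genes
    with an edge whenever two genes diverged strictly later than the species
    in which they reside.  Provides planted phylogenetic trees with time
    maps, rooted-triple sets with the Aho/BUILD machinery, cograph and
    cotree utilities, relaxed duplication-transfer-loss scenarios with
    validity checks, polynomial-time recognition of LDT graphs and rs-Fitch
    graphs, construction of a relaxed scenario explaining a given LDT graph,
    greedy minimum edge completion of LDT graphs to complete multipartite
    (Fitch) graphs, and an event-based simulator of gene family evolution
    along species trees for benchmarking the recall, precision and accuracy
    of the resulting transfer predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
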