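Package: nanuq
Title: Species Network Inference from Gene Tree Quartets Under the
    Network Multispecies Coalescent
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the NANUQ algorithm for inferring topological
    features of a level-1 hybridization network from a collection of
    unrooted topological gene trees under the network multispecies
    coalescent (NMSC).  Gene tree quartets are tallied into quartet count
    concordance factors, tested per 4-taxon set for resolution and
    tree-likeness by trinomial likelihood-ratio tests, and converted into
    a network quartet distance.  A circular split system is fitted to the
    distance by NeighborNet, and a frontier-minimal splits graph is
    constructed and interpreted to report the network's tree of blobs,
    cycles, and the hybrid nodes of cycles of size five or more.  Also
    provides an extended-Newick parser for metric level-1 networks, a
    coalescent gene tree simulator on such networks, and exact
    combinatorial oracles (displayed-tree groves, split systems, quartet
    weight functions and theoretical distances) used to validate the
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    jsonlite,
    phangorn,
    pracma,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
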