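Package: btcnets
Title: Reduction, Generation and Counting of Binary Tree-Child Phylogenetic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Tools for the combinatorial calculus of binary tree-child (BTC)
    phylogenetic networks: leaf-by-leaf reduction of any BTC network to the
    trivial one-node network via TH-paths, the inverse augmentation operations
    parameterized by feasible recovering pairs, exhaustive generation of all
    BTC networks over {1..n} with no isomorphism filtering, a recursive
    arbitrary-precision upper bound on their number, seeded random generation,
    a sampling estimator for the next level's count, and a greedy heuristic
    that places a new sequence into a sequenced BTC network by choosing an
    attachment point and then adding hybridizations while they improve the
    explanatory probability. Networks are exchanged as extended Newick or
    edge-list text; mu-vector canonical keys provide the isomorphism test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, jsonlite
Suggests: testthat (>= 3.0.0), igraph, ape, Biostrings, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'bignum.R'
    'AllClasses.R'
    'network-core.R'
    'mu.R'
    'reduction.R'
    'augmentation.R'
    'generation.R'
    'counting.R'
    'placement.R'
    'io-enewick.R'
    'io-edgelist.R'
    'cli.R'
    'examples.R'
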