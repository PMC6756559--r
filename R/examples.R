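## Small built-in example objects used in the documentation and tests.

#' Example network with one hybrid node on four taxa
#'
#' A binary tree-child network over `{1..4}` with a single hybrid node:
#' the root's two children are both ancestors of the hybrid, whose child
#' leads to leaf 2; the remaining leaves hang off the tree part. Useful as
#' a small non-tree test case.
#'
#' @return a [PhyloNetwork-class].
#' @export
exampleHybridNetwork <- function() {
  ## u: root; v, w its children; x hybrid with parents v, w; y below w
  ## ids: u=5, v=6, w=7, x=8, y=9; leaves 1..4 carry taxa 1..4
  edges <- rbind(
    c(5, 6), c(5, 7),          # root -> v, w
    c(6, 1), c(6, 8),          # v -> leaf 1, v -> hybrid x
    c(7, 8), c(7, 9),          # w -> hybrid x, w -> y
    c(8, 2),                   # x -> leaf 2
    c(9, 3), c(9, 4))          # y -> leaves 3, 4
  phyloNetwork(edges, stats::setNames(1:4, as.character(1:4)))
}

#' Example sequenced three-taxon tree
#'
#' The worked placement example: a rooted tree over three taxa carrying
#' length-4 sequences over the alphabet {A, B, C} -- leaves AAAC, BBCC and
#' BBBB, the internal ancestor of taxa 2 and 3 carrying BBBB and the root
#' AAAA. Placing the new sequence AACC into it with the toy model selects
#' a speciation attachment above taxon 1 (inferred sequence AAAC) and then
#' one hybridization feeding taxon 2's lineage (inferred sequence AACC)
#' for any mutation rate below 1/(2 + sqrt(2)).
#'
#' @return a [SequencedNetwork-class].
#' @export
exampleSequencedNetwork <- function() {
  ## 4 = root, 5 = ancestor of taxa 2 and 3
  edges <- rbind(c(4, 1), c(4, 5), c(5, 2), c(5, 3))
  net <- phyloNetwork(edges, stats::setNames(1:3, as.character(1:3)))
  sequencedNetwork(net, c(`1` = "AAAC", `2` = "BBCC", `3` = "BBBB",
                          `4` = "AAAA", `5` = "BBBB"))
}
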