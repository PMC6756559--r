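## Leaf reduction: TH-path computation, the reduction R(N, l) with its
## recovering data, and the full reduction chain down to the trivial
## network.

#' Compute the TH-path of a leaf
#'
#' The TH-path of a leaf is the unique maximal path of tree nodes ending at
#' the leaf in which the off-path child of every non-terminal node is a
#' hybrid node, and those hybrid nodes are pairwise distinct. Starting from
#' the leaf alone, the path is extended by prepending the parent of its
#' head while the pre-TH-path conditions keep holding; extension stops when
#' the head's parent is a hybrid node (the leaf is then of type H), is a
#' tree node whose other child is a tree node, or is a tree node whose
#' other (hybrid) child is already one of the path's off-path hybrids (type
#' T in both latter cases). The head of the path is never the root of a
#' non-trivial network.
#'
#' @param net a valid, non-trivial [PhyloNetwork-class].
#' @param leaf a leaf node id.
#' @return a list of class `"THPath"` with elements `leaf`, `path`
#'   (node ids, head first, ending at `leaf`), `r` (its length), `type`
#'   (`"T"` or `"H"`), `extended` (the path with the hybrid parent
#'   prepended when type H), `v`, `x`, `y` (off-path hybrid children, their
#'   other parents and their single children, for positions 1..r-1), `u0`
#'   (head of the extended path), `w` (parents of `u0`: one node for T, two
#'   for H), `t` (children of the `w` nodes other than `u0`) and `z`
#'   (parents of the `w` nodes, `NA` when absent).
#' @export
computeTHPath <- function(net, leaf) {
  leaf <- as.integer(leaf)
  if (nLeaves(net) == 1L && nrow(net@edges) == 0L)
    stop("the trivial network has no TH-path")
  kinds <- nodeKinds(net)
  if (!leaf %in% net@nodes || kinds[as.character(leaf)] != "leaf")
    stop("node ", leaf, " is not a leaf of the network")

  path <- leaf
  vs <- integer(0)            # off-path hybrids, head-to-leaf order
  repeat {
    head <- path[1]
    par <- nodeParents(net, head)
    if (length(par) == 0L)
      stop("internal error: TH-path head reached the root")   # Lemma-1 guard
    par <- par[1]
    if (kinds[as.character(head)] == "hybrid") break          # unreachable
    if (kinds[as.character(par)] == "hybrid") break           # type H stop
    other <- setdiff(nodeChildren(net, par), head)
    if (kinds[as.character(other)] != "hybrid") break         # both tree
    if (other %in% vs) break                                  # hybrid reused
    path <- c(par, path)
    vs <- c(other, vs)
  }

  r <- length(path)
  v <- x <- y <- integer(0)
  if (r > 1L) {
    v <- vapply(seq_len(r - 1L), function(i)
      setdiff(nodeChildren(net, path[i]), path[i + 1L]), integer(1))
    x <- vapply(seq_len(r - 1L), function(i)
      setdiff(nodeParents(net, v[i]), path[i]), integer(1))
    y <- vapply(v, function(vi) nodeChildren(net, vi), integer(1))
  }
  headPar <- nodeParents(net, path[1])[1]
  type <- if (kinds[as.character(headPar)] == "hybrid") "H" else "T"
  u0 <- if (type == "H") headPar else path[1]
  extended <- if (type == "H") c(u0, path) else path
  w <- nodeParents(net, u0)
  t_ <- vapply(w, function(wj) setdiff(nodeChildren(net, wj), u0), integer(1))
  z <- vapply(w, function(wj) {
    p <- nodeParents(net, wj)
    if (length(p)) p[1] else NA_integer_
  }, integer(1))
  structure(list(leaf = leaf, path = path, r = r, type = type,
                 extended = extended, v = v, x = x, y = y, u0 = u0,
                 w = w, t = t_, z = z),
            class = "THPath")
}

#' Reduce a network with respect to a leaf
#'
#' Deletes all nodes of the extended TH-path of the leaf (with incident
#' arcs) and eliminates the elementary nodes this creates -- which are
#' exactly the off-path hybrids and the parents of the path's head. The
#' result is a valid binary tree-child network with the leaf's taxon
#' removed, together with the recovering data (S1, S2) that parameterizes
#' the inverse augmentation: S1 is the multiset of heirs of the deleted
#' w-nodes (its two members are equal exactly when the two w-nodes were
#' linked by an arc) and S2 the tuple of heirs of the deleted hybrids, in
#' path order. The node counts satisfy `t' = t - |extended path| - 1` and
#' `h' = h - |extended path| + 1`.
#'
#' @param net a valid non-trivial [PhyloNetwork-class].
#' @param leaf a leaf node id, or a taxon via `taxon = TRUE` in
#'   [reduceToTrivial()].
#' @return list with `network` (the reduced [PhyloNetwork-class]) and
#'   `data` (a [RecoveringData-class] whose node references live in the
#'   reduced network).
#' @export
reduceLeaf <- function(net, leaf) {
  if (nLeaves(net) == 1L)
    stop("cannot reduce the trivial network")
  th <- computeTHPath(net, leaf)
  bar <- th$extended
  nOld <- nLeaves(net); tOld <- nTreeNodes(net); hOld <- nHybridNodes(net)

  keep <- setdiff(net@nodes, bar)
  edges <- net@edges[!(net@edges[, 1] %in% bar | net@edges[, 2] %in% bar), ,
                     drop = FALSE]
  labels <- net@labels[names(net@labels) != as.character(th$leaf)]
  stripped <- new("PhyloNetwork", nodes = keep, edges = edges,
                  labels = labels)

  ## the elementary nodes must be exactly {v_i} union {w_j}
  idx <- match(stripped@edges, keep)
  ne <- nrow(stripped@edges)
  indeg <- tabulate(idx[seq_len(ne) + ne], length(keep))
  outdeg <- tabulate(idx[seq_len(ne)], length(keep))
  elem <- keep[indeg <= 1L & outdeg == 1L]
  expected <- sort(unique(c(th$v, th$w)))
  if (!identical(sort(elem), expected))
    stop("internal error: unexpected elementary nodes after path removal")

  heirOf <- function(u) {
    repeat {
      ch <- stripped@edges[stripped@edges[, 1] == u, 2]
      u <- ch[1]
      if (!u %in% elem) return(u)
    }
  }
  S1 <- sort(unname(vapply(th$w, heirOf, integer(1))))
  S2 <- if (th$r > 1L) unname(vapply(th$v, heirOf, integer(1)))
        else integer(0)

  reduced <- eliminateElementary(stripped)
  assertNetworkLaws(reduced, "reduceLeaf")
  if (nTreeNodes(reduced) != tOld - length(bar) - 1L ||
      nHybridNodes(reduced) != hOld - length(bar) + 1L)
    stop("internal error: reduction broke the node-count deltas")

  mu <- muVectors(reduced)
  muOf <- function(u) unname(mu[as.character(u), ])
  data <- new("RecoveringData", kind = th$type, S1 = S1, S2 = S2,
              S1mu = lapply(S1, muOf), S2mu = lapply(S2, muOf),
              label = unname(net@labels[as.character(th$leaf)]))
  feas <- checkFeasible(reduced, S1, S2)
  if (!identical(feas$kind, th$type))
    stop("internal error: recovering data is not ", th$type, "-feasible")
  list(network = reduced, data = data)
}

#' Reduce a network to the trivial one, recording every step
#'
#' Removes the leaves labeled n, n-1, ..., 2 in that order, returning the
#' recovering data of each step. Replaying the list with
#' [augmentNetwork()] (resolving node references through their mu-vectors)
#' reconstructs a network isomorphic to the input; the reduction sequence
#' is the exact inverse of the generation order, which adds leaves
#' 2, 3, ..., n.
#'
#' @param net a valid [PhyloNetwork-class] whose taxa are exactly `1:n`.
#' @return a list of [RecoveringData-class], for leaves n down to 2
#'   (empty for the trivial network).
#' @seealso [replayAugmentations()]
#' @export
reduceToTrivial <- function(net) {
  n <- nLeaves(net)
  if (!identical(sort(unname(net@labels)), seq_len(n)))
    stop("taxa must be exactly 1..n")
  out <- vector("list", n - 1L)
  for (lab in rev(seq_len(n)[-1])) {
    node <- as.integer(names(net@labels)[net@labels == lab])
    step <- reduceLeaf(net, node)
    out[[n - lab + 1L]] <- step$data
    net <- step$network
  }
  out
}

#' Replay a list of recovering data from the trivial network
#'
#' Inverse of [reduceToTrivial()]: starting from the trivial network over
#' `{1}`, applies the recorded augmentations for leaves 2, 3, ..., n,
#' resolving each step's node references by their mu-vectors in the
#' network reconstructed so far.
#'
#' @param datas list of [RecoveringData-class] as returned by
#'   [reduceToTrivial()] (leaf n first).
#' @return a [PhyloNetwork-class] isomorphic to the original input.
#' @export
replayAugmentations <- function(datas) {
  net <- trivialNetwork(1L)
  for (d in rev(datas)) {
    mu <- muVectors(net)
    kinds <- nodeKinds(net)
    S1 <- vapply(d@S1mu, resolveMuNode, integer(1), net = net, mu = mu,
                 kinds = kinds)
    S2 <- if (length(d@S2mu))
      vapply(d@S2mu, resolveMuNode, integer(1), net = net, mu = mu,
             kinds = kinds) else integer(0)
    net <- augmentNetwork(net, d@label, S1, S2)
  }
  net
}

#' @export
print.THPath <- function(x, ...) {
  cat(sprintf("TH-path of leaf %d (type %s, r = %d): %s\n", x$leaf, x$type,
              x$r, paste(x$path, collapse = " -> ")))
  invisible(x)
}
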