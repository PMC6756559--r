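## Feasibility of recovering pairs, the two augmentation operations, and
## the deterministic enumeration of all feasible pairs of a network.

#' Check a recovering pair for feasibility
#'
#' A pair (S1, S2) of tree nodes is a valid parameterization of an
#' augmentation when: (1) the S2 members are pairwise distinct, and two of
#' them may be siblings only if one of the two belongs to S1; (2) any S2
#' member that is the child of a hybrid node, or has a hybrid sibling,
#' belongs to S1; (3) no S1 member is a proper descendant of an S2 member
#' ("proper" means reachable by a directed path of length at least one, so
#' a node is never a proper descendant of itself -- which is what permits
#' the single S1 node of a T-pair to also appear in S2); and the kind
#' condition: |S1| = 1 for a T-pair, or |S1| = 2 (as a multiset, the two
#' members may coincide) with S1 and S2 disjoint for an H-pair.
#'
#' @param net a valid [PhyloNetwork-class].
#' @param S1 integer vector of node ids, length 1 or 2 (a multiset: repeats
#'   allowed for length 2).
#' @param S2 integer vector of node ids (ordered tuple, possibly empty).
#' @return a list with `kind` (`"T"`, `"H"`, or `NA` when infeasible) and
#'   `violated` (character vector of violated condition names, empty when
#'   feasible).
#' @export
checkFeasible <- function(net, S1, S2 = integer(0)) {
  S1 <- as.integer(S1); S2 <- as.integer(S2)
  if (!all(c(S1, S2) %in% net@nodes))
    stop("pair refers to nodes not in the network")
  tab <- networkTables(net)
  i1 <- match(S1, tab$nodes); i2 <- match(S2, tab$nodes)
  bad <- character(0)
  if (any(tab$kind[c(i1, i2)] == "hybrid")) bad <- c(bad, "tree-nodes")
  if (anyDuplicated(i2)) bad <- c(bad, "1")
  if (length(i2) > 1L) {
    for (a in seq_along(i2)) for (b in seq_along(i2)) {
      if (a < b && !is.na(tab$sib[i2[a]]) && tab$sib[i2[a]] == i2[b] &&
          !(S2[a] %in% S1 || S2[b] %in% S1))
        bad <- c(bad, "1")
    }
  }
  if (any(tab$hybAdj[i2] & !(S2 %in% S1))) bad <- c(bad, "2")
  if (length(i2) && any(tab$reach[i2, i1])) bad <- c(bad, "3")
  kind <- NA_character_
  if (length(S1) == 1L) kind <- "T"
  else if (length(S1) == 2L) {
    if (any(S1 %in% S2)) bad <- c(bad, "4H")
    kind <- "H"
  } else bad <- c(bad, "4T/4H")
  bad <- unique(bad)
  list(kind = if (length(bad)) NA_character_ else kind, violated = bad)
}

## Augmentation with bookkeeping about the created nodes (used by the
## placement heuristic, which must attach sequences to them).
augmentInternal <- function(net, label, S1, S2 = integer(0)) {
  label <- as.integer(label)
  if (label %in% net@labels) stop("label ", label, " is already a taxon")
  feas <- checkFeasible(net, S1, S2)
  if (is.na(feas$kind))
    stop("pair is not feasible (violated: ",
         paste(feas$violated, collapse = ", "), ")")
  S1 <- as.integer(S1); S2 <- as.integer(S2)
  hOld <- nHybridNodes(net)
  r <- length(S2) + 1L
  nextId <- max(net@nodes) + 1L
  nodes <- net@nodes
  edges <- net@edges
  labels <- net@labels

  addNode <- function() {
    id <- nextId; nextId <<- nextId + 1L
    nodes <<- c(nodes, id)
    id
  }
  split <- function(u) {
    id <- addNode()
    into <- edges[, 2] == u
    edges[into, 2] <<- id
    edges <<- rbind(edges, c(id, u))
    id
  }

  if (feas$kind == "T") {
    u <- vapply(seq_len(r), function(i) addNode(), integer(1))
    if (r > 1L)
      edges <- rbind(edges, cbind(u[-r], u[-1]))
    w1 <- split(S1[1])
    edges <- rbind(edges, c(w1, u[1]))
    v <- integer(0)
    for (i in seq_along(S2)) {            # split order matters when S1 is in S2
      vi <- split(S2[i])
      edges <- rbind(edges, c(u[i], vi))
      v <- c(v, vi)
    }
    info <- list(kind = "T", path = u, u0 = NA_integer_, w = w1, v = v,
                 leaf = u[r])
    hExpect <- hOld + r - 1L
  } else {
    u0 <- addNode()
    u <- vapply(seq_len(r), function(i) addNode(), integer(1))
    edges <- rbind(edges, cbind(c(u0, u[-r]), u))
    w1 <- split(S1[1])
    edges <- rbind(edges, c(w1, u0))
    w2 <- split(S1[2])
    edges <- rbind(edges, c(w2, u0))
    v <- integer(0)
    for (i in seq_along(S2)) {
      vi <- split(S2[i])
      edges <- rbind(edges, c(u[i], vi))
      v <- c(v, vi)
    }
    info <- list(kind = "H", path = u, u0 = u0, w = c(w1, w2), v = v,
                 leaf = u[r])
    hExpect <- hOld + r
  }
  labels <- c(labels, stats::setNames(label, as.character(u[r])))
  out <- new("PhyloNetwork", nodes = sort(nodes), edges = edges,
             labels = labels)
  assertNetworkLaws(out, "augmentNetwork")
  if (nHybridNodes(out) != hExpect)
    stop("internal error: augmentation broke the hybrid-count delta")
  list(network = out, info = info)
}

#' Augment a network with a new leaf
#'
#' The inverse of [reduceLeaf()]. A T-pair (|S1| = 1) inserts a new path
#' of r = |S2| + 1 tree nodes ending in the new leaf: the single S1 node is
#' split first (its new elementary parent becomes the parent of the path's
#' head), then each S2 node is split in order and the resulting node --
#' hybrid in the output -- is fed from the corresponding path node. An
#' H-pair (|S1| = 2) additionally creates a hybrid node above the path's
#' head, fed by the split parents of the two S1 nodes. The split order is
#' significant in the coincidence cases: when the S1 node of a T-pair also
#' appears in S2 the two created nodes end up linked by an arc, and when
#' the two S1 members of an H-pair coincide two consecutive elementary
#' nodes are created. The result is a valid binary tree-child network with
#' one more leaf and h + r - 1 (type T) or h + r (type H) hybrid nodes.
#'
#' @inheritParams checkFeasible
#' @param label the new taxon label (an integer not already used).
#' @return the augmented [PhyloNetwork-class].
#' @examples
#' net <- augmentNetwork(trivialNetwork(), 2, S1 = c(1, 1))  # one hybrid
#' nHybridNodes(net)
#' @export
augmentNetwork <- function(net, label, S1, S2 = integer(0)) {
  augmentInternal(net, label, S1, S2)$network
}

## Depth-first walk over all feasible pairs of a network, shared by the
## enumerator, the pair counter and the per-hybrid-count tally. Conditions
## are checked incrementally: every prefix of a feasible tuple is feasible,
## so the walk visits exactly one node per feasible pair.
walkFeasiblePairs <- function(net, visit) {
  tab <- networkTables(net)
  tn <- tab$treeIdx                      # ascending creation order
  m <- length(tab$nodes)
  extend <- function(kind, s1idx, s2idx) {
    visit(kind, tab$nodes[s1idx], tab$nodes[s2idx])
    for (y in tn) {
      if (y %in% s2idx) next
      if (kind == "H" && y %in% s1idx) next
      if (tab$hybAdj[y] && !(y %in% s1idx)) next
      ok <- TRUE
      for (prev in s2idx) {
        if (!is.na(tab$sib[y]) && tab$sib[y] == prev &&
            !(y %in% s1idx || prev %in% s1idx)) { ok <- FALSE; break }
      }
      if (!ok) next
      if (any(tab$reach[y, s1idx])) next
      extend(kind, s1idx, c(s2idx, y))
    }
  }
  for (t1 in tn) extend("T", t1, integer(0))
  for (a in seq_along(tn)) for (b in a:length(tn))
    extend("H", c(tn[a], tn[b]), integer(0))
  invisible(NULL)
}

#' Enumerate all feasible pairs of a network
#'
#' Every feasible pair appears exactly once, in a deterministic order:
#' T-pairs before H-pairs; within a kind, by increasing S2 length; within a
#' length, lexicographically by the node ids of S1 then S2. Since every
#' feasible pair yields a distinct network (up to isomorphism) and
#' different networks have disjoint offspring, the number of feasible
#' pairs of a network is exactly the number of its offspring.
#'
#' @param net a valid [PhyloNetwork-class].
#' @return a list of `list(kind, S1, S2)` entries.
#' @export
enumerateFeasiblePairs <- function(net) {
  acc <- list()
  walkFeasiblePairs(net, function(kind, S1, S2) {
    acc[[length(acc) + 1L]] <<- list(kind = kind, S1 = S1, S2 = S2)
  })
  key <- vapply(acc, function(p) {
    sprintf("%s|%04d|%s|%s", if (p$kind == "T") "A" else "B", length(p$S2),
            paste(sprintf("%08d", p$S1), collapse = ","),
            paste(sprintf("%08d", p$S2), collapse = ","))
  }, "")
  acc[order(key, method = "radix")]
}

#' Count the feasible pairs of a network
#'
#' @param net a valid [PhyloNetwork-class].
#' @param byOffspringHybrids if `TRUE`, return a named numeric vector
#'   tallying the pairs by the hybrid-node count of the network each pair
#'   would produce (h + |S2| for a T-pair, h + |S2| + 1 for an H-pair);
#'   otherwise a single number.
#' @export
countFeasiblePairs <- function(net, byOffspringHybrids = FALSE) {
  if (!byOffspringHybrids) {
    count <- 0
    walkFeasiblePairs(net, function(kind, S1, S2) count <<- count + 1)
    return(count)
  }
  h <- nHybridNodes(net)
  n <- nLeaves(net)
  tally <- numeric(n + 1L)               # offspring h ranges 0..n (<= (n+1)-1)
  walkFeasiblePairs(net, function(kind, S1, S2) {
    hh <- h + length(S2) + (kind == "H")
    tally[hh + 1L] <<- tally[hh + 1L] + 1
  })
  stats::setNames(tally, 0:n)
}
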