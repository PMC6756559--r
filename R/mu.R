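## mu-vectors and the canonical isomorphism key.
##
## The mu-vector of a node u is the length-n integer vector whose i-th entry
## is the number of distinct directed paths from u to the leaf with the i-th
## smallest taxon label. The sorted multiset of node mu-vectors, together
## with the sorted multiset of arc pairs (mu(parent), mu(child)), is a
## canonical key: two binary tree-child networks over the same taxa are
## isomorphic exactly when their keys coincide. Path counts stay tiny here
## (bounded by 2^h with h <= n - 1 at the sizes this package targets), so
## plain doubles hold them exactly.

#' Per-node path-count vectors
#'
#' @param net a valid [PhyloNetwork-class] over taxa `X`.
#' @return integer matrix, one row per node (rownames are node ids), one
#'   column per taxon in increasing label order; entry = number of distinct
#'   directed paths from the node to that leaf.
#' @export
muVectors <- function(net) {
  tab <- networkTables(net)
  m <- length(tab$nodes)
  taxa <- sort(net@labels)
  n <- length(taxa)
  mu <- matrix(0, m, n, dimnames = list(tab$ids, names(taxa) <- NULL))
  leafPos <- match(names(sort(net@labels)), tab$ids)
  for (j in seq_len(n)) mu[leafPos[j], j] <- 1
  ord <- topoOrder(tab$children, m)
  for (i in rev(ord)) {
    for (ch in tab$children[[i]]) mu[i, ] <- mu[i, ] + mu[ch, ]
  }
  storage.mode(mu) <- "integer"
  rownames(mu) <- tab$ids
  colnames(mu) <- as.character(sort(net@labels))
  mu
}

#' Canonical key of a network
#'
#' An order-independent textual key built from the sorted multiset of node
#' mu-vectors and the sorted multiset of arc mu-pairs. Equal keys are
#' equivalent to isomorphism of leaf-labeled networks within the tree-child
#' class; the arc pairs are included as a belt-and-braces guard, validated
#' against a brute-force isomorphism search at small sizes in the test
#' suite.
#'
#' @param net a valid [PhyloNetwork-class].
#' @return a single character string.
#' @seealso [isIsomorphic()]
#' @export
muRepresentation <- function(net) {
  v <- validateNetwork(net)
  if (!v$ok)
    stop("cannot compute the canonical key of an invalid network (",
         paste(vapply(v$violations, `[[`, "", "rule"), collapse = ", "), ")")
  mu <- muVectors(net)
  nodeStr <- apply(mu, 1, paste, collapse = ",")
  arcs <- net@edges
  arcStr <- if (nrow(arcs)) {
    pa <- nodeStr[as.character(arcs[, 1])]
    ch <- nodeStr[as.character(arcs[, 2])]
    paste(pa, ch, sep = ">")
  } else character(0)
  paste(paste(sort(unname(nodeStr), method = "radix"), collapse = "|"),
        paste(sort(arcStr, method = "radix"), collapse = "|"),
        sep = "||")
}

#' Test two networks for isomorphism
#'
#' True exactly when the two networks have the same taxon set and equal
#' canonical keys (see [muRepresentation()]).
#'
#' @param n1,n2 valid [PhyloNetwork-class] objects.
#' @export
isIsomorphic <- function(n1, n2) {
  if (!identical(sort(unname(n1@labels)), sort(unname(n2@labels))))
    return(FALSE)
  identical(muRepresentation(n1), muRepresentation(n2))
}

## Resolve a (kind, mu-vector) reference to a node id in `net`. Within a
## tree-child network a mu-vector is shared by at most a hybrid node and its
## single (tree) child, so restricting to tree nodes makes the lookup
## unambiguous (the unique-automorphism property guarantees stability).
resolveMuNode <- function(net, muvec, mu = muVectors(net),
                          kinds = nodeKinds(net)) {
  target <- paste(muvec, collapse = ",")
  str <- apply(mu, 1, paste, collapse = ",")
  hits <- which(str == target & kinds != "hybrid")
  if (length(hits) != 1L)
    stop("mu-vector does not resolve to a unique tree node")
  net@nodes[hits]
}
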