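## Core data structure and primitives: constructors, accessors, degree
## classification, the diagnostic validator, split / eliminate, and the
## static adjacency tables the combinatorial routines build on.

#' Construct a phylogenetic network from an arc list
#'
#' @param edges two-column matrix (or data.frame) of arcs (parent, child),
#'   integer node identifiers. May have zero rows.
#' @param labels named integer vector mapping leaf node ids (names, as
#'   characters) to taxon labels.
#' @param nodes optional integer vector of node identifiers; defaults to the
#'   ids occurring in `edges` and `labels`.
#' @return a [PhyloNetwork-class].
#' @examples
#' cherry <- phyloNetwork(rbind(c(3, 1), c(3, 2)), c(`1` = 1, `2` = 2))
#' @export
phyloNetwork <- function(edges, labels, nodes = NULL) {
  edges <- matrix(as.integer(as.matrix(edges)), ncol = 2)
  labels <- stats::setNames(as.integer(labels), names(labels))
  if (is.null(nodes))
    nodes <- unique(c(as.integer(edges), as.integer(names(labels))))
  new("PhyloNetwork", nodes = sort(as.integer(nodes)), edges = edges,
      labels = labels)
}

#' The trivial one-node network
#'
#' The degenerate network whose single node is simultaneously root and leaf,
#' with degree pair (0, 0). It is the base case of every reduction chain and
#' the seed of the generation procedure.
#'
#' @param label taxon label of the single node (default 1).
#' @export
trivialNetwork <- function(label = 1L) {
  phyloNetwork(matrix(integer(0), ncol = 2),
               stats::setNames(as.integer(label), "1"), nodes = 1L)
}

## ---- accessors -------------------------------------------------------------

#' Network accessors
#'
#' Small accessors over a [PhyloNetwork-class]: its arcs, node identifiers,
#' degree-derived node kinds, the root, the leaves and their taxon labels.
#'
#' @param x a [PhyloNetwork-class].
#' @return `networkEdges`: two-column integer matrix. `networkNodes`:
#'   integer vector. `nodeKinds`: character vector parallel to
#'   `networkNodes(x)` with values `"root"`, `"internal"`, `"leaf"`,
#'   `"hybrid"` or `"trivial"`. `rootNode`, `leafNodes`: integer.
#'   `leafTaxa`: named integer vector (names are node ids). `nLeaves`,
#'   `nTreeNodes`, `nHybridNodes`: integer counts.
#' @name accessors
NULL

#' @rdname accessors
#' @export
networkEdges <- function(x) x@edges

#' @rdname accessors
#' @export
networkNodes <- function(x) x@nodes

#' @rdname accessors
#' @export
nodeKinds <- function(x) {
  nodes <- x@nodes
  idx <- match(x@edges, nodes)
  m <- length(nodes)
  indeg <- tabulate(idx[seq_len(nrow(x@edges)) + nrow(x@edges)], m)
  outdeg <- tabulate(idx[seq_len(nrow(x@edges))], m)
  kind <- character(m)
  kind[indeg == 2L & outdeg == 1L] <- "hybrid"
  kind[indeg <= 1L & outdeg == 0L] <- "leaf"
  kind[indeg == 0L & outdeg == 2L] <- "root"
  kind[indeg == 1L & outdeg == 2L] <- "internal"
  kind[indeg == 0L & outdeg == 0L] <- "trivial"
  kind[kind == ""] <- "invalid"
  names(kind) <- as.character(nodes)
  kind
}

#' @rdname accessors
#' @export
rootNode <- function(x) {
  tgt <- unique(x@edges[, 2])
  r <- setdiff(x@nodes, tgt)
  if (length(r) != 1L) stop("network does not have a single root")
  r
}

#' @rdname accessors
#' @export
leafNodes <- function(x) as.integer(names(x@labels))

#' @rdname accessors
#' @export
leafTaxa <- function(x) x@labels

#' @rdname accessors
#' @export
nLeaves <- function(x) length(x@labels)

#' @rdname accessors
#' @export
nTreeNodes <- function(x) sum(nodeKinds(x) != "hybrid")

#' @rdname accessors
#' @export
nHybridNodes <- function(x) sum(nodeKinds(x) == "hybrid")

## children / parents as plain integer vectors (creation-order sorted)
nodeChildren <- function(x, u) sort(x@edges[x@edges[, 1] == u, 2])

nodeParents <- function(x, u) sort(x@edges[x@edges[, 2] == u, 1])

## ---- static tables used by the combinatorial routines ---------------------

## A list of per-node tables keyed by position in net@nodes:
##   kind, parents/children adjacency, the (unique, binary) tree sibling of
##   each node or NA, whether a tree node has a hybrid parent or sibling,
##   and the proper-descendant relation as a logical matrix reach[a, b]
##   (TRUE iff b is a proper descendant of a).
networkTables <- function(net) {
  nodes <- net@nodes
  m <- length(nodes)
  ids <- as.character(nodes)
  kind <- nodeKinds(net)
  children <- rep(list(integer(0)), m)
  parents <- rep(list(integer(0)), m)
  if (nrow(net@edges)) {
    pi <- match(net@edges[, 1], nodes)
    ci <- match(net@edges[, 2], nodes)
    for (e in seq_len(nrow(net@edges))) {
      children[[pi[e]]] <- c(children[[pi[e]]], ci[e])
      parents[[ci[e]]] <- c(parents[[ci[e]]], pi[e])
    }
  }
  sib <- rep(NA_integer_, m)
  hybAdj <- logical(m)
  for (i in seq_len(m)) {
    if (kind[i] == "hybrid") next
    ps <- parents[[i]]
    if (length(ps) == 1L && kind[ps] != "hybrid") {
      other <- setdiff(children[[ps]], i)
      if (length(other) == 1L) {
        if (kind[other] == "hybrid") hybAdj[i] <- TRUE else sib[i] <- other
      }
    }
    if (length(ps) == 1L && kind[ps] == "hybrid") hybAdj[i] <- TRUE
  }
  reach <- matrix(FALSE, m, m)
  ord <- topoOrder(children, m)
  for (i in rev(ord)) {          # children processed before parents
    for (ch in children[[i]]) {
      reach[i, ch] <- TRUE
      reach[i, ] <- reach[i, ] | reach[ch, ]
    }
  }
  list(nodes = nodes, ids = ids, kind = kind, children = children,
       parents = parents, sib = sib, hybAdj = hybAdj, reach = reach,
       treeIdx = which(kind != "hybrid"))
}

## Kahn topological order over index-based adjacency; errors on cycles.
topoOrder <- function(children, m) {
  indeg <- integer(m)
  for (i in seq_len(m)) for (ch in children[[i]]) indeg[ch] <- indeg[ch] + 1L
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    ord <- c(ord, u)
    for (ch in children[[u]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) != m) stop("graph contains a cycle")
  ord
}

isAcyclic <- function(net) {
  tab <- tryCatch(networkTables(net), error = function(e) NULL)
  !is.null(tab)
}

## ---- validation ------------------------------------------------------------

#' Diagnose the network axioms
#'
#' Checks, and reports separately, each axiom of a binary tree-child
#' network: acyclicity, a single root, the degree table (leaves (1,0) or
#' the trivial (0,0), roots (0,2), internal tree nodes (1,2), hybrid nodes
#' (2,1)), the tree-child condition (every non-leaf node has at least one
#' child of indegree at most 1), and the bijectivity of the leaf labeling.
#' Diagnoses rather than throws: invalid graphs yield a report, not an
#' error.
#'
#' @param net a [PhyloNetwork-class] (possibly violating the axioms).
#' @return a list with `ok` (logical) and `violations`, a list of
#'   `(rule, nodes)` entries.
#' @examples
#' validateNetwork(trivialNetwork())$ok
#' @export
validateNetwork <- function(net) {
  violations <- list()
  addv <- function(rule, nodes)
    violations[[length(violations) + 1L]] <<- list(rule = rule, nodes = nodes)

  nodes <- net@nodes
  m <- length(nodes)
  idx <- match(net@edges, nodes)
  ne <- nrow(net@edges)
  indeg <- tabulate(idx[seq_len(ne) + ne], m)
  outdeg <- tabulate(idx[seq_len(ne)], m)

  if (!isAcyclic(net)) addv("acyclic", integer(0))

  roots <- nodes[indeg == 0L]
  if (length(roots) != 1L) addv("single-root", roots)

  trivialOK <- m == 1L & indeg == 0L & outdeg == 0L
  degOK <- (indeg == 1L & outdeg == 0L) |       # leaf
           (indeg == 0L & outdeg == 2L) |       # root
           (indeg == 1L & outdeg == 2L) |       # internal tree node
           (indeg == 2L & outdeg == 1L) |       # hybrid
           trivialOK
  if (!all(degOK)) addv("degree-table", nodes[!degOK])

  ## tree-child: every non-leaf has a child with indegree <= 1
  bad <- integer(0)
  for (i in which(outdeg > 0L)) {
    ch <- idx[which(idx[seq_len(ne)] == i) + ne]
    if (all(indeg[ch] >= 2L)) bad <- c(bad, nodes[i])
  }
  if (length(bad)) addv("tree-child", bad)

  leaves <- nodes[outdeg == 0L]
  labeled <- sort(as.integer(names(net@labels)))
  if (!identical(sort(leaves), labeled))
    addv("label-bijection", setdiff(leaves, labeled))
  if (anyDuplicated(net@labels))
    addv("label-bijection", as.integer(names(net@labels))[duplicated(net@labels)])

  list(ok = length(violations) == 0L, violations = violations)
}

## ---- split and eliminate ---------------------------------------------------

#' Split a node
#'
#' Adds a new node above `u`: every arc (v, u) is redirected to the new
#' node, and an arc (new, u) is added. The new node is elementary (degree
#' (1,1), or (0,1) when `u` was the root) and its elimination recovers the
#' original network.
#'
#' @param net a [PhyloNetwork-class].
#' @param u a node of the network.
#' @return a list with `network` (the split network) and `node` (the new
#'   node's identifier).
#' @seealso [eliminateElementary()]
#' @export
splitNode <- function(net, u) {
  u <- as.integer(u)
  if (!u %in% net@nodes) stop("node ", u, " is not in the network")
  newId <- max(net@nodes) + 1L
  edges <- net@edges
  into <- edges[, 2] == u
  edges[into, 2] <- newId
  edges <- rbind(edges, c(newId, u))
  list(network = new("PhyloNetwork", nodes = sort(c(net@nodes, newId)),
                     edges = edges, labels = net@labels),
       node = newId)
}

#' Eliminate all elementary nodes
#'
#' Removes every maximal path of elementary nodes (degree (1,1) or (0,1)),
#' adding an arc from the path's grantor (the parent above, when it exists)
#' to its heir (the child below). When the root is elementary its heir is
#' promoted, repeatedly if the elementary nodes form a chain at the top.
#' Nodes must be tree, hybrid or elementary; anything else is an error.
#'
#' @param net a [PhyloNetwork-class] whose nodes may include elementary ones.
#' @return the network with no elementary node.
#' @export
eliminateElementary <- function(net) {
  repeat {
    nodes <- net@nodes
    m <- length(nodes)
    idx <- match(net@edges, nodes)
    ne <- nrow(net@edges)
    indeg <- tabulate(idx[seq_len(ne) + ne], m)
    outdeg <- tabulate(idx[seq_len(ne)], m)
    elem <- (indeg <= 1L & outdeg == 1L)
    known <- elem |
      (indeg == 1L & outdeg == 0L) | (indeg == 0L & outdeg == 2L) |
      (indeg == 1L & outdeg == 2L) | (indeg == 2L & outdeg == 1L) |
      (m == 1L & indeg == 0L & outdeg == 0L)
    if (!all(known))
      stop("node with degree outside the tree/hybrid/elementary table: ",
           paste(nodes[!known], collapse = " "))
    w <- which(elem)
    if (!length(w)) return(net)
    e <- nodes[w[1]]
    child <- net@edges[net@edges[, 1] == e, 2]
    par <- net@edges[net@edges[, 2] == e, 1]
    edges <- net@edges[net@edges[, 1] != e & net@edges[, 2] != e, ,
                       drop = FALSE]
    if (length(par)) edges <- rbind(edges, c(par, child))
    net <- new("PhyloNetwork", nodes = setdiff(nodes, e), edges = edges,
               labels = net@labels)
  }
}

## Assert the structural laws every constructed network must satisfy:
## validator-clean plus the node-count identities t - h = 2n - 1 and
## h <= n - 1. Used after every reduce/augment.
assertNetworkLaws <- function(net, where = "operation") {
  v <- validateNetwork(net)
  if (!v$ok)
    stop("internal error: ", where, " produced an invalid network (",
         paste(vapply(v$violations, `[[`, "", "rule"), collapse = ", "), ")")
  n <- nLeaves(net); t <- nTreeNodes(net); h <- nHybridNodes(net)
  if (t - h != 2L * n - 1L || h > n - 1L)
    if (!(n == 1L && t == 1L && h == 0L))
      stop("internal error: ", where, " broke the node-count identities")
  invisible(net)
}
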