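#' @import methods
NULL

#' Binary tree-child phylogenetic network
#'
#' A rooted, binary, leaf-labeled directed acyclic graph in which every node
#' is either a tree node (indegree at most 1) or a hybrid node (indegree 2,
#' outdegree 1), and every non-leaf node has at least one tree-node child.
#' Node identifiers are opaque integers assigned in creation order; every
#' iteration order in the package derives from them, so results are
#' reproducible across runs. The trivial network is a single node of degree
#' (0, 0) that is simultaneously root and leaf.
#'
#' Only cheap structural coherence is enforced by the validity method
#' (identifiers, arc endpoints, label map); the full set of network axioms
#' (acyclicity, single root, degree table, tree-child condition, label
#' bijection) is diagnosed by [validateNetwork()], which reports violations
#' instead of throwing.
#'
#' @slot nodes integer vector of node identifiers (sorted, unique).
#' @slot edges two-column integer matrix of arcs (parent, child).
#' @slot labels named integer vector: names are leaf node identifiers (as
#'   characters), values are taxon labels, canonically `1:n`.
#'
#' @seealso [phyloNetwork()], [trivialNetwork()], [validateNetwork()]
#' @export
setClass("PhyloNetwork",
  representation(nodes = "integer", edges = "matrix", labels = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicated node ids")
    if (ncol(object@edges) != 2L) msg <- c(msg, "edges must have two columns")
    if (length(object@edges) && !all(object@edges %in% object@nodes))
      msg <- c(msg, "arc endpoint is not a node")
    if (length(object@labels)) {
      if (is.null(names(object@labels)))
        msg <- c(msg, "labels must be named by node id")
      else if (!all(as.integer(names(object@labels)) %in% object@nodes))
        msg <- c(msg, "labeled node is not a node")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Recovering data of a leaf reduction
#'
#' The pair (S1, S2) that, together with the removed leaf's label,
#' parameterizes the inverse augmentation. `S1` is the multiset of heirs of
#' the deleted w-nodes (one node for a type-T reduction, two -- possibly
#' equal -- for type H); `S2` is the ordered tuple of heirs of the deleted
#' hybrid v-nodes. Node references are identifiers in the *reduced* network;
#' `S1mu`/`S2mu` carry the corresponding mu-vectors, which are stable across
#' serialization (node names are not).
#'
#' @slot kind `"T"` or `"H"`.
#' @slot S1 integer vector of node ids (length 1 or 2, sorted for H).
#' @slot S2 integer vector of node ids (possibly empty), in path order.
#' @slot S1mu,S2mu lists of integer mu-vectors parallel to `S1`/`S2`.
#' @slot label integer taxon label of the removed leaf.
#' @export
setClass("RecoveringData",
  representation(kind = "character", S1 = "integer", S2 = "integer",
                 S1mu = "list", S2mu = "list", label = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (!object@kind %in% c("T", "H")) msg <- c(msg, "kind must be T or H")
    if (object@kind == "T" && length(object@S1) != 1L)
      msg <- c(msg, "T data needs |S1| = 1")
    if (object@kind == "H" && length(object@S1) != 2L)
      msg <- c(msg, "H data needs |S1| = 2")
    if (length(msg)) msg else TRUE
  }
)

#' Network with sequences attached to its tree nodes
#'
#' Couples a [PhyloNetwork-class] with a map from tree nodes to fixed-length
#' strings over a finite alphabet. Hybrid nodes carry no sequence (their
#' single child, a tree node, does).
#'
#' @slot network a [PhyloNetwork-class].
#' @slot sequences named character vector; names are tree-node identifiers.
#' @export
setClass("SequencedNetwork",
  representation(network = "PhyloNetwork", sequences = "character"),
  validity = function(object) {
    msg <- character(0)
    kinds <- nodeKinds(object@network)
    tn <- object@network@nodes[kinds != "hybrid"]
    if (!all(as.character(tn) %in% names(object@sequences)))
      msg <- c(msg, "every tree node needs a sequence")
    if (length(object@sequences) &&
        length(unique(nchar(object@sequences))) > 1L)
      msg <- c(msg, "sequences must have equal length")
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "PhyloNetwork", function(object) {
  k <- nodeKinds(object)
  cat(sprintf(
    "PhyloNetwork: %d leaves, %d tree nodes, %d hybrid nodes, %d arcs\n",
    length(object@labels), sum(k != "hybrid"), sum(k == "hybrid"),
    nrow(object@edges)))
  cat("  taxa:", paste(sort(object@labels), collapse = " "), "\n")
  cat(" ", writeENewick(object), "\n")
})

setMethod("show", "RecoveringData", function(object) {
  cat(sprintf("RecoveringData (type %s) for leaf %d\n", object@kind,
              object@label))
  cat("  S1:", paste(object@S1, collapse = " "), "\n")
  cat("  S2:", if (length(object@S2)) paste(object@S2, collapse = " ")
               else "()", "\n")
})

setMethod("show", "SequencedNetwork", function(object) {
  cat(sprintf("SequencedNetwork: %d sequenced tree nodes, length %d\n",
              length(object@sequences),
              if (length(object@sequences)) nchar(object@sequences[[1]])
              else 0L))
  show(object@network)
})
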