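## Extended Newick text format. Dialect: every hybrid node appears exactly
## twice under a shared tag #H1, #H2, ... (numbered by ascending node id);
## its single-child subtree is written at the first occurrence in the
## deterministic traversal order, the other occurrence is the bare tag.
## Children are written in ascending node-id order, so output is
## byte-stable for a given network object.

#' Write a network as extended Newick
#'
#' @param net a valid [PhyloNetwork-class].
#' @return a single eNewick string, terminated by `";"`.
#' @examples
#' writeENewick(trivialNetwork())                 # "1;"
#' @export
writeENewick <- function(net) {
  v <- validateNetwork(net)
  if (!v$ok)
    stop("refusing to serialize an invalid network (",
         paste(vapply(v$violations, `[[`, "", "rule"), collapse = ", "), ")")
  kinds <- nodeKinds(net)
  hybrids <- net@nodes[kinds == "hybrid"]
  tag <- stats::setNames(paste0("#H", seq_along(hybrids)),
                         as.character(hybrids))
  seen <- character(0)
  render <- function(u) {
    uc <- as.character(u)
    if (kinds[uc] == "hybrid") {
      if (uc %in% seen) return(tag[[uc]])
      seen <<- c(seen, uc)
      return(paste0("(", render(nodeChildren(net, u)), ")", tag[[uc]]))
    }
    ch <- nodeChildren(net, u)
    if (!length(ch)) return(as.character(net@labels[[uc]]))
    paste0("(", paste(vapply(ch, render, ""), collapse = ","), ")")
  }
  start <- if (nrow(net@edges)) rootNode(net) else net@nodes[1]
  paste0(render(start), ";")
}

#' Read a network from extended Newick
#'
#' Parses an eNewick string in which hybrid nodes appear as repeated
#' `#Hk` tags (one occurrence carrying the node's subtree, the other(s)
#' bare), merges the occurrences into a DAG, and checks the network
#' axioms. Node identifiers are assigned in traversal (pre-)order. Taxa
#' must be integers, or arbitrary strings which are then mapped to `1..n`
#' in sorted order; the dictionary is attached as attribute
#' `"taxonNames"`.
#'
#' @param text an eNewick string (or a file path when `isFile = TRUE`).
#' @param strict error on networks violating the axioms (default); when
#'   `FALSE`, return the parsed network with a warning carrying the
#'   validation report.
#' @param isFile treat `text` as a path and read the first line.
#' @return a [PhyloNetwork-class].
#' @export
readENewick <- function(text, strict = TRUE, isFile = FALSE) {
  if (isFile) text <- paste(readLines(text, warn = FALSE), collapse = "")
  s <- gsub("[[:space:]]", "", text)
  if (!nzchar(s) || substring(s, nchar(s)) != ";")
    stop("eNewick parse error: input must end with ';'")
  chars <- strsplit(substr(s, 1L, nchar(s) - 1L), "")[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(chars)) chars[pos] else ""
  readName <- function() {
    out <- character(0)
    while (pos <= length(chars) && !(chars[pos] %in% c("(", ")", ",", ";"))) {
      out <- c(out, chars[pos]); pos <<- pos + 1L
    }
    paste(out, collapse = "")
  }
  parseNode <- function() {
    if (peek() == "(") {
      pos <<- pos + 1L
      kids <- list(parseNode())
      while (peek() == ",") { pos <<- pos + 1L; kids <- c(kids, list(parseNode())) }
      if (peek() != ")")
        stop("eNewick parse error: expected ')' at position ", pos)
      pos <<- pos + 1L
      list(name = readName(), children = kids)
    } else {
      nm <- readName()
      if (!nzchar(nm))
        stop("eNewick parse error: empty node at position ", pos)
      list(name = nm, children = list())
    }
  }
  tree <- parseNode()
  if (pos <= length(chars))
    stop("eNewick parse error: trailing characters at position ", pos)

  ## flatten, assigning pre-order ids
  nodes <- list()
  edges <- matrix(integer(0), ncol = 2)
  walk <- function(nd) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- nd$name
    for (k in nd$children) {
      cid <- walk(k)
      edges <<- rbind(edges, c(id, cid))
    }
    id
  }
  walk(tree)

  names <- unlist(nodes)
  tagOf <- ifelse(grepl("#", names), sub("^.*#", "#", names), NA)
  labelOf <- sub("#.*$", "", names)

  ## merge hybrid occurrences
  for (tg in unique(stats::na.omit(tagOf))) {
    occ <- which(tagOf == tg)
    if (length(occ) < 2L)
      stop("eNewick parse error: hybrid tag ", tg, " appears only once")
    withKids <- occ[occ %in% edges[, 1]]
    if (length(withKids) > 1L)
      stop("eNewick parse error: hybrid tag ", tg,
           " has subtrees at several occurrences")
    keep <- if (length(withKids)) withKids else occ[1]
    for (o in setdiff(occ, keep)) edges[edges[, 2] == o, 2] <- keep
  }
  used <- sort(unique(c(1L, as.integer(edges))))
  leaves <- used[vapply(used, function(i) sum(edges[, 1] == i) == 0L,
                        logical(1))]
  lab <- labelOf[leaves]
  if (any(!nzchar(lab)))
    stop("eNewick parse error: unlabeled leaf")
  taxonNames <- NULL
  if (all(grepl("^[0-9]+$", lab))) {
    taxa <- as.integer(lab)
  } else {
    taxonNames <- sort(unique(lab), method = "radix")
    taxa <- match(lab, taxonNames)
  }
  net <- phyloNetwork(edges, stats::setNames(taxa, as.character(leaves)),
                      nodes = used)
  v <- validateNetwork(net)
  if (!v$ok) {
    msg <- paste("parsed network violates:",
                 paste(vapply(v$violations, `[[`, "", "rule"),
                       collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  if (!is.null(taxonNames)) attr(net, "taxonNames") <- taxonNames
  net
}
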