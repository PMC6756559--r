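## Lossless tab-separated interchange: eNewick anonymizes node identifiers,
## the edge list preserves them. One record per line:
##   node <TAB> id                (every node, so isolated nodes survive)
##   edge <TAB> parent <TAB> child
##   leaf <TAB> id <TAB> taxon

#' Write a network as a tab-separated edge list
#'
#' @param net a [PhyloNetwork-class].
#' @param file optional path; when missing the lines are returned.
#' @return (invisibly) the character vector of lines.
#' @export
writeEdgeList <- function(net, file = NULL) {
  lines <- c(
    paste("node", net@nodes, sep = "\t"),
    if (nrow(net@edges))
      paste("edge", net@edges[, 1], net@edges[, 2], sep = "\t"),
    paste("leaf", names(net@labels), unname(net@labels), sep = "\t"))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Read a network from a tab-separated edge list
#'
#' @param lines character vector of lines, or a path via `isFile = TRUE`.
#' @param isFile treat `lines` as a file path.
#' @return a [PhyloNetwork-class].
#' @export
readEdgeList <- function(lines, isFile = FALSE) {
  if (isFile) lines <- readLines(lines, warn = FALSE)
  parts <- strsplit(lines[nzchar(lines)], "\t", fixed = TRUE)
  kind <- vapply(parts, `[[`, "", 1)
  nodes <- as.integer(vapply(parts[kind == "node"], `[[`, "", 2))
  ed <- parts[kind == "edge"]
  edges <- if (length(ed))
    matrix(as.integer(unlist(lapply(ed, `[`, 2:3))), ncol = 2, byrow = TRUE)
  else matrix(integer(0), ncol = 2)
  lf <- parts[kind == "leaf"]
  labels <- stats::setNames(as.integer(vapply(lf, `[[`, "", 3)),
                            vapply(lf, `[[`, "", 2))
  phyloNetwork(edges, labels, nodes = nodes)
}
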