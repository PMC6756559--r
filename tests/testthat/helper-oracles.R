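## Independent oracles and small builders shared across the suite.

## Leaf-label-preserving digraph isomorphism by VF2 (igraph), independent
## of the mu-vector machinery it cross-checks.
bruteIso <- function(n1, n2) {
  toIg <- function(net) {
    ids <- as.character(networkNodes(net))
    g <- igraph::graph_from_edgelist(
      cbind(as.character(networkEdges(net)[, 1]),
            as.character(networkEdges(net)[, 2])), directed = TRUE)
    miss <- setdiff(ids, igraph::V(g)$name)
    if (length(miss)) g <- igraph::add_vertices(g, length(miss), name = miss)
    col <- rep(0L, length(igraph::V(g)))
    lt <- leafTaxa(net)
    col[match(names(lt), igraph::V(g)$name)] <- unname(lt)
    list(g = g, col = col)
  }
  a <- toIg(n1); b <- toIg(n2)
  igraph::isomorphic(a$g, b$g, method = "vf2",
                     vertex.color1 = a$col, vertex.color2 = b$col)
}

## Brute-force count of pairs satisfying the feasibility conditions with
## the descendant condition dropped, split by kind and |S2|. Enumerates
## distinct-entry tuples directly from the definitions (no shared code
## with the package's pruned walk). kMax bounds the tuple length.
cond3FreePairCounts <- function(net, kMax = 5L) {
  kinds <- nodeKinds(net)
  nodes <- networkNodes(net)
  tn <- nodes[kinds != "hybrid"]
  parentOf <- function(u) {
    p <- networkEdges(net)[networkEdges(net)[, 2] == u, 1]
    if (length(p) == 1L) p else NA_integer_
  }
  sibOf <- function(u) {
    p <- parentOf(u)
    if (is.na(p) || kinds[as.character(p)] == "hybrid") return(NA_integer_)
    s <- setdiff(networkEdges(net)[networkEdges(net)[, 1] == p, 2], u)
    if (length(s) == 1L) s else NA_integer_
  }
  hybAdjOf <- function(u) {
    p <- parentOf(u)
    if (is.na(p)) return(FALSE)
    if (kinds[as.character(p)] == "hybrid") return(TRUE)
    s <- setdiff(networkEdges(net)[networkEdges(net)[, 1] == p, 2], u)
    length(s) == 1L && kinds[as.character(s)] == "hybrid"
  }
  sib <- vapply(tn, sibOf, integer(1))
  hybAdj <- vapply(tn, hybAdjOf, logical(1))
  ok12 <- function(S1, S2) {
    for (a in seq_along(S2)) {
      ia <- match(S2[a], tn)
      if (hybAdj[ia] && !(S2[a] %in% S1)) return(FALSE)
      for (b in seq_along(S2)) {
        if (a < b && !is.na(sib[ia]) && sib[ia] == S2[b] &&
            !(S2[a] %in% S1 || S2[b] %in% S1)) return(FALSE)
      }
    }
    TRUE
  }
  kMax <- min(kMax, length(tn))
  cntT <- cntH <- numeric(kMax + 1L)
  tuplesK <- function(k) {
    out <- list()
    rec <- function(cur) {
      if (length(cur) == k) { out[[length(out) + 1L]] <<- cur; return() }
      for (y in setdiff(tn, cur)) rec(c(cur, y))
    }
    rec(integer(0))
    out
  }
  for (k in 0:kMax) {
    for (S2 in tuplesK(k)) {
      for (t1 in tn) if (ok12(t1, S2)) cntT[k + 1L] <- cntT[k + 1L] + 1
      for (a in seq_along(tn)) for (b in a:length(tn)) {
        S1 <- c(tn[a], tn[b])
        if (any(S1 %in% S2)) next
        if (ok12(S1, S2)) cntH[k + 1L] <- cntH[k + 1L] + 1
      }
    }
  }
  list(T = cntT, H = cntH)
}

## First generated network over 1..n with exactly h hybrid nodes.
netWithParams <- function(n, h, pool = NULL) {
  if (is.null(pool)) pool <- generateAll(n)
  for (net in pool) if (nHybridNodes(net) == h) return(net)
  stop("no network with these parameters")
}

## A cherry over the two given taxa, built directly.
cherryNetwork <- function(t1 = 1L, t2 = 2L) {
  phyloNetwork(rbind(c(3L, 1L), c(3L, 2L)),
               stats::setNames(c(t1, t2), c("1", "2")))
}
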