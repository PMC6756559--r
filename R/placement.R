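## Greedy placement of a new sequence into a sequenced network: choose the
## best attachment (speciation or hybridization), then keep adding
## hybridization events feeding existing nodes while they improve the
## explanatory probability.

#' Attach sequences to a network's tree nodes
#'
#' @param network a valid [PhyloNetwork-class].
#' @param sequences named character vector; names are tree-node ids, values
#'   equal-length strings over the model's alphabet. Hybrid nodes carry no
#'   sequence.
#' @return a [SequencedNetwork-class].
#' @export
sequencedNetwork <- function(network, sequences) {
  new("SequencedNetwork", network = network,
      sequences = sequences[order(as.integer(names(sequences)))])
}

#' Toy evolution model (symmetric mutation + half recombination)
#'
#' Speciation follows a Jukes-Cantor-style symmetric substitution kernel
#' over a three-letter alphabet: `PS(s, s') = mu^d (1 - 2 mu)^(L - d)`
#' with d the Hamming distance, valid for `mu < 1/3`. Hybridization is
#' plain recombination of halves: `PH(s1, s2, s')` is 1/2 when s' equals
#' the first half of s1 followed by the second half of s2 or vice versa,
#' and 0 otherwise (the two recombinants coincide when the parents agree
#' on the relevant halves, in which case that single outcome has
#' probability 1 in total). Sequence maximization is exhaustive over the
#' full candidate space `Sigma^L` in lexicographic order, so ties resolve
#' to the lexicographically smallest sequence.
#'
#' @param mu per-site mutation probability, `0 < mu < 1/3`.
#' @param length sequence length (even, default 4).
#' @param alphabet character vector of symbols (default A, B, C).
#' @return a list of class `"EvolutionModel"` with kernels `PS(s, sp)`,
#'   `PH(s1, s2, sp)`, the `candidates` vector and the model parameters.
#' @export
toyModel <- function(mu, length = 4L, alphabet = c("A", "B", "C")) {
  if (!(mu > 0 && mu < 1 / 3))
    stop("mu must lie strictly between 0 and 1/3")
  L <- as.integer(length)
  if (L %% 2L != 0L) stop("sequence length must be even for half-splits")
  half <- L %/% 2L
  hamming <- function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  PS <- function(s, sp) {
    d <- hamming(s, sp)
    mu^d * (1 - 2 * mu)^(L - d)
  }
  PH <- function(s1, s2, sp) {
    r1 <- paste0(substr(s1, 1L, half), substr(s2, half + 1L, L))
    r2 <- paste0(substr(s2, 1L, half), substr(s1, half + 1L, L))
    if (r1 == r2) { if (sp == r1) 1 else 0 }
    else if (sp == r1 || sp == r2) 0.5 else 0
  }
  grids <- rev(rep(list(alphabet), L))
  cands <- do.call(paste0, rev(expand.grid(grids, stringsAsFactors = FALSE)))
  cands <- sort(cands, method = "radix")
  structure(list(PS = PS, PH = PH, candidates = cands, mu = mu,
                 length = L, alphabet = alphabet),
            class = "EvolutionModel")
}

## PS of every candidate against a fixed target, as a vector.
psVec <- function(model, target)
  vapply(model$candidates, function(s) model$PS(s, target), numeric(1),
         USE.NAMES = FALSE)

#' Probability of a sequence at a tree node
#'
#' The probability that sequence `s` arose at tree node `t` from its
#' ancestry: 1 at the root (no ancestry), the speciation kernel from the
#' parent's sequence when the parent is a tree node, and the hybridization
#' kernel from the two grandparents' sequences when the parent is a hybrid
#' node.
#'
#' @param snet a [SequencedNetwork-class].
#' @param t a tree node id.
#' @param s a sequence.
#' @param model an `"EvolutionModel"`.
#' @export
phiProbability <- function(snet, t, s, model) {
  net <- snet@network
  p <- nodeParents(net, t)
  if (!length(p)) return(1)
  kinds <- nodeKinds(net)
  if (kinds[as.character(p)] != "hybrid")
    return(model$PS(snet@sequences[[as.character(p)]], s))
  g <- nodeParents(net, p)
  model$PH(snet@sequences[[as.character(g[1])]],
           snet@sequences[[as.character(g[2])]], s)
}

## phi of node t evaluated at every candidate sequence.
phiVec <- function(snet, t, model)
  vapply(model$candidates, function(s) phiProbability(snet, t, s, model),
         numeric(1), USE.NAMES = FALSE)

## Non-root tree nodes, ascending id: the candidate attachment points. The
## root is excluded: the scores divide the incoming arc of a node, and the
## root has none (its constant phi would also make it trivially dominate).
attachmentCandidates <- function(net) {
  kinds <- nodeKinds(net)
  r <- if (nrow(net@edges)) rootNode(net) else net@nodes
  setdiff(net@nodes[kinds != "hybrid"], r)
}

#' Choose the attachment of a new sequence
#'
#' Scores every candidate speciation attachment: for each non-root tree
#' node t, the best sequence sigma for a new node dividing the arc above t
#' maximizes `phi_t(sigma) * PS(sigma, s(t)) * PS(sigma, s_l)`. Scores
#' every candidate hybrid attachment: for each unordered pair of candidate
#' nodes, the product of the two arc-division factors times
#' `PH(sigma1, sigma2, s_l)`. Picks the better kind, preferring
#' speciation on ties; within a kind, ties go to the smallest node ids and
#' then the lexicographically smallest sequences.
#'
#' @param snet a [SequencedNetwork-class].
#' @param sLeaf the new sequence.
#' @param model an `"EvolutionModel"`.
#' @return a list with `kind` (`"T"`/`"H"`), `S1` (node ids), `sigma`
#'   (inferred sequence(s) for the split nodes), `piT`, `piH`, and
#'   `scores` (per-candidate data frame for the chosen kind T).
#' @export
selectAttachment <- function(snet, sLeaf, model) {
  net <- snet@network
  if (!length(net@nodes)) stop("empty network")
  cand <- attachmentCandidates(net)
  if (!length(cand)) cand <- net@nodes[nodeKinds(net) != "hybrid"][1]
  psL <- psVec(model, sLeaf)

  nodeFactor <- function(t)
    phiVec(snet, t, model) * psVec(model, snet@sequences[[as.character(t)]])

  factors <- lapply(cand, nodeFactor)
  names(factors) <- as.character(cand)

  piT <- -Inf; tauT <- NA_integer_; sigT <- NA_character_
  perNode <- data.frame(node = cand, pi = NA_real_, sigma = NA_character_)
  for (i in seq_along(cand)) {
    v <- factors[[i]] * psL
    j <- which.max(v)
    perNode$pi[i] <- v[j]
    perNode$sigma[i] <- model$candidates[j]
    if (v[j] > piT) { piT <- v[j]; tauT <- cand[i]; sigT <- model$candidates[j] }
  }

  piH <- -Inf; tauH <- c(NA_integer_, NA_integer_)
  sigH <- c(NA_character_, NA_character_)
  nc <- length(model$candidates)
  for (a in seq_along(cand)) for (b in a:length(cand)) {
    fa <- factors[[a]]; fb <- factors[[b]]
    best <- 0; bi <- bj <- NA_integer_
    for (i in seq_len(nc)) {
      if (fa[i] == 0) next
      for (j in seq_len(nc)) {
        ph <- model$PH(model$candidates[i], model$candidates[j], sLeaf)
        if (ph == 0) next
        val <- fa[i] * fb[j] * ph
        if (val > best) { best <- val; bi <- i; bj <- j }
      }
    }
    if (best > piH) {
      piH <- best
      tauH <- c(cand[a], cand[b])
      sigH <- model$candidates[c(bi, bj)]
    }
  }

  if (piT >= piH)
    list(kind = "T", S1 = tauT, sigma = sigT, piT = piT, piH = piH,
         scores = perNode)
  else
    list(kind = "H", S1 = tauH, sigma = sigH, piT = piT, piH = piH,
         scores = perNode)
}

#' Greedily add hybridizations to an attachment
#'
#' Starting from a chosen attachment, iterates k = 1, 2, ...: the
#' candidate set C holds the tree nodes y (non-root, with a tree-node
#' parent) for which appending y to the S2 tuple keeps the pair feasible.
#' For each candidate the best sequence sigma(y) for the new path node
#' feeding a hybrid above y maximizes the three-factor score printed in
#' the trace; the gain `kappa(y)` subtracts the probability of the same
#' data without the hybridization. Candidates with strictly negative gain
#' are dropped (a zero gain is kept); if none remain the loop stops,
#' otherwise the gain-maximizing candidate becomes y_k. Candidates whose
#' parent is a hybrid node (possible only when the S1 node of a T-pair
#' re-enters S2) are skipped with a warning: the scores assume a
#' sequenced parent.
#'
#' @param snet a [SequencedNetwork-class].
#' @param state the attachment as returned by [selectAttachment()].
#' @param sLeaf the new sequence.
#' @param model an `"EvolutionModel"`.
#' @return the state extended with `ys` (accepted node ids in order),
#'   `sigmaY` (their inferred path-node sequences) and `iterations` (one
#'   per-candidate data frame per iteration, including the rejected
#'   candidates and their scores).
#' @export
extendWithHybridizations <- function(snet, state, sLeaf, model) {
  net <- snet@network
  kinds <- nodeKinds(net)
  S1 <- state$S1
  ys <- integer(0)
  sigmaY <- character(0)
  iterations <- list()
  warned <- FALSE
  psL <- psVec(model, sLeaf)

  repeat {
    k <- length(ys) + 1L
    pool <- setdiff(attachmentCandidates(net), ys)
    rows <- list()
    for (y in pool) {
      feas <- checkFeasible(net, S1, c(ys, y))
      if (is.na(feas$kind) || feas$kind != state$kind) next
      p <- nodeParents(net, y)
      if (kinds[as.character(p)] == "hybrid") {
        if (!warned) {
          warning("skipping candidate ", y,
                  " whose parent is a hybrid node (no sequenced parent)")
          warned <- TRUE
        }
        next
      }
      sp <- snet@sequences[[as.character(p)]]
      sy <- snet@sequences[[as.character(y)]]
      phHere <- vapply(model$candidates, function(s) model$PH(s, sp, sy),
                       numeric(1), USE.NAMES = FALSE)
      if (k == 1L && state$kind == "H") {
        fromHybrid <- vapply(model$candidates, function(s)
          model$PH(state$sigma[1], state$sigma[2], s), numeric(1),
          USE.NAMES = FALSE)
        v <- fromHybrid * phHere * psL
        alt <- model$PS(sp, sy) * model$PH(state$sigma[1], state$sigma[2],
                                           sLeaf)
      } else {
        prev <- if (k == 1L) state$sigma[1] else sigmaY[k - 1L]
        v <- psVec(model, prev) * phHere * psL
        alt <- model$PS(sp, sy) * model$PS(prev, sLeaf)
      }
      j <- which.max(v)
      rows[[length(rows) + 1L]] <-
        data.frame(node = y, sigma = model$candidates[j], pi = v[j],
                   kappa = v[j] - alt)
    }
    if (!length(rows)) break
    it <- do.call(rbind, rows)
    it$accepted <- FALSE
    keep <- it$kappa >= 0
    if (!any(keep)) { iterations[[k]] <- it; break }
    best <- which(keep)[which.max(it$kappa[keep])]
    it$accepted[best] <- TRUE
    iterations[[k]] <- it
    ys <- c(ys, it$node[best])
    sigmaY <- c(sigmaY, it$sigma[best])
  }
  c(state, list(ys = ys, sigmaY = sigmaY, iterations = iterations))
}

#' Place a new sequence into a sequenced network
#'
#' Runs [selectAttachment()] and [extendWithHybridizations()], then
#' materializes the resulting augmentation: the network is augmented with
#' the new leaf through the pair (S1, (y_1, ..., y_k)), the split nodes
#' above the S1 member(s) receive the inferred attachment sequence(s), the
#' path nodes feeding the accepted hybrids receive their inferred
#' sequences, the new leaf receives the placed sequence, and every
#' pre-existing tree node keeps its sequence.
#'
#' @param snet a [SequencedNetwork-class].
#' @param label taxon label for the new leaf.
#' @param sLeaf the new sequence.
#' @param model an `"EvolutionModel"`.
#' @return list with `network` (a [SequencedNetwork-class] with one more
#'   leaf) and `trace` (the placement trace: attachment scores, accepted
#'   hybridization nodes, per-candidate gains).
#' @examples
#' snet <- exampleSequencedNetwork()
#' fit <- placeSequence(snet, 4, "AACC", toyModel(0.1))
#' fit$trace$kind                       # "T"
#' @export
placeSequence <- function(snet, label, sLeaf, model) {
  state <- selectAttachment(snet, sLeaf, model)
  state <- extendWithHybridizations(snet, state, sLeaf, model)
  aug <- augmentInternal(snet@network, label, state$S1, state$ys)
  seqs <- snet@sequences
  info <- aug$info
  for (j in seq_along(info$w))
    seqs[[as.character(info$w[j])]] <- state$sigma[j]
  r <- length(info$path)
  if (r > 1L)
    for (i in seq_len(r - 1L))
      seqs[[as.character(info$path[i])]] <- state$sigmaY[i]
  seqs[[as.character(info$leaf)]] <- sLeaf
  out <- sequencedNetwork(aug$network, seqs)
  list(network = out, trace = state)
}
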