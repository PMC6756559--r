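## Exhaustive unique generation of all binary tree-child networks over
## {1..n}, seeded random generation, and the sampling estimator for the
## size of the next level.

#' Generate all binary tree-child networks over 1..n
#'
#' Depth-first expansion from the trivial network: at step i the leaf
#' labeled i + 1 is added through every feasible pair. Every network over
#' `{1..n}` is produced exactly once -- distinct pairs on one network and
#' pairs on non-isomorphic networks always yield non-isomorphic results,
#' so no isomorphism filtering is performed. In count-only mode the last
#' level is never materialized: the count of a network's offspring equals
#' its number of feasible pairs, so the walk stops one level short and
#' sums pair counts, keeping memory at one branch of the recursion tree.
#'
#' @param n number of leaves (n >= 1).
#' @param countOnly if `TRUE` return only the total count (numeric).
#' @return a list of [PhyloNetwork-class] (in the deterministic generation
#'   order), or a count.
#' @examples
#' length(generateAll(3))        # 66
#' generateAll(4, countOnly = TRUE)
#' @export
generateAll <- function(n, countOnly = FALSE) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be at least 1")
  seed <- trivialNetwork(1L)
  if (countOnly) {
    if (n == 1L) return(1)
    rec <- function(net, depth) {
      if (depth == n - 2L) return(countFeasiblePairs(net))
      total <- 0
      for (p in enumerateFeasiblePairs(net))
        total <- total +
          rec(augmentNetwork(net, depth + 2L, p$S1, p$S2), depth + 1L)
      total
    }
    return(rec(seed, 0L))
  }
  acc <- list()
  rec <- function(net, depth) {
    if (depth == n - 1L) {
      acc[[length(acc) + 1L]] <<- net
      return(invisible(NULL))
    }
    for (p in enumerateFeasiblePairs(net))
      rec(augmentNetwork(net, depth + 2L, p$S1, p$S2), depth + 1L)
  }
  rec(seed, 0L)
  acc
}

#' Count networks by number of hybrid nodes
#'
#' Exact per-h counts of the networks over `{1..n}`, obtained by the same
#' one-level-short walk as `generateAll(n, countOnly = TRUE)`: each
#' feasible pair of a level n-1 network determines the hybrid count of the
#' network it would produce. The support is contained in 0..n-1 and the
#' values sum to the total count.
#'
#' @param n number of leaves.
#' @return named numeric vector, names `"0"`, `"1"`, ...; entry h is the
#'   number of networks with h hybrid nodes (trailing zero entries
#'   removed).
#' @export
countByHybrids <- function(n) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be at least 1")
  if (n == 1L) return(c(`0` = 1))
  tally <- numeric(n)                    # h in 0..n-1
  rec <- function(net, depth) {
    if (depth == n - 2L) {
      t <- countFeasiblePairs(net, byOffspringHybrids = TRUE)
      keep <- seq_len(min(length(t), n))
      tally[keep] <<- tally[keep] + t[keep]
      return(invisible(NULL))
    }
    for (p in enumerateFeasiblePairs(net))
      rec(augmentNetwork(net, depth + 2L, p$S1, p$S2), depth + 1L)
  }
  rec(trivialNetwork(1L), 0L)
  names(tally) <- 0:(n - 1L)
  while (length(tally) > 1L && tally[length(tally)] == 0)
    tally <- tally[-length(tally)]
  tally
}

#' Random binary tree-child network
#'
#' Starting from the trivial network, repeatedly enumerates the feasible
#' pairs of the current network and picks one uniformly at random to add
#' the next leaf. Every network over `{1..n}` can be produced, but the
#' distribution is *not* uniform: networks reachable through parents with
#' few feasible pairs are favored. Draws are reproducible: the RNG
#' (Mersenne-Twister via [set.seed()]) is seeded per call and the previous
#' RNG state of the session is restored on exit.
#'
#' @param n number of leaves.
#' @param seed integer seed for the draw.
#' @return a [PhyloNetwork-class] over `{1..n}`.
#' @export
randomNetwork <- function(n, seed) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be at least 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
    globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  net <- trivialNetwork(1L)
  for (i in seq_len(n - 1L)) {
    pairs <- enumerateFeasiblePairs(net)
    p <- pairs[[sample.int(length(pairs), 1L)]]
    net <- augmentNetwork(net, i + 1L, p$S1, p$S2)
  }
  net
}

#' Sampling estimate of the next level's count
#'
#' Materializes all networks over `{1..n}`, draws a uniform sample of
#' distinct networks (simple random sampling without replacement), and
#' estimates the number of networks over `{1..n+1}` as the mean offspring
#' count of the sample times the number of level-n networks. The reported
#' standard error is the conservative `sd/sqrt(m)` (no finite-population
#' correction); the offspring-count distribution is strongly
#' right-skewed, so the conservative form is the safer calibration. When
#' `sampleSize` meets or exceeds the population the estimate is computed
#' exhaustively and is exact (standard error 0).
#'
#' @param n number of leaves of the sampled level.
#' @param sampleSize number of draws.
#' @param seed integer seed.
#' @param networks optionally, the pre-materialized result of
#'   `generateAll(n)`, to amortize generation across repeated calls.
#' @return list with `estimate`, `se` (standard error of the estimate),
#'   `exact` (logical), and `sampleSize` actually used.
#' @export
estimateNextCount <- function(n, sampleSize, seed = 1L, networks = NULL) {
  if (is.null(networks)) networks <- generateAll(n)
  N <- length(networks)
  if (sampleSize >= N) {
    counts <- vapply(networks, countFeasiblePairs, numeric(1))
    return(list(estimate = sum(counts), se = 0, exact = TRUE,
                sampleSize = N))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
    globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  idx <- sample.int(N, sampleSize)
  counts <- vapply(networks[idx], countFeasiblePairs, numeric(1))
  list(estimate = N * mean(counts),
       se = N * stats::sd(counts) / sqrt(sampleSize),
       exact = FALSE, sampleSize = as.integer(sampleSize))
}
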