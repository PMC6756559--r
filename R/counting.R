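## Closed-form pair counts and the recursive upper bound on the number of
## binary tree-child networks.
##
## A network over {1..n} with h hybrid nodes has t = 2n + h - 1 tree nodes;
## exactly 2n - 2h - 1 of them (the root plus sibling pairs) have neither a
## hybrid parent nor a hybrid sibling. Dropping only the descendant
## condition from feasibility makes the pair counts depend on (n, h, k)
## alone, which yields the recursion bounding the network counts.
##
## Degenerate-argument conventions: a tuple count is 1 at k = 0 and 0 at
## k < 0, and every product is a falling-factorial product in steps of two
## that clamps to 0 as soon as a factor is nonpositive; likewise any
## nonpositive linear factor zeroes its term. These conventions are pinned
## down by brute-force pair enumeration on concrete networks (tests) and by
## the bound table below.

fallingEven <- function(from, k) {
  ## product (from)(from-2)...(from-2(k-1)), clamped to 0 at a nonpositive
  ## factor; empty product (k = 0) is 1; k < 0 gives 0.
  if (k < 0) return(0)
  if (k == 0) return(1)
  f <- from - 2 * (seq_len(k) - 1)
  if (any(f <= 0)) return(0)
  prod(f)
}

#' Tuple counts over hybrid-free tree nodes
#'
#' The number of ordered k-tuples of tree nodes of a network with
#' parameters (n, h) such that no two members are equal or siblings and no
#' member has a hybrid parent or a hybrid sibling. Split into the tuples
#' avoiding the root (`p0`) and those containing it (`p1`).
#'
#' @param n leaves, `h` hybrid nodes, `k` tuple length.
#' @param h,k see above.
#' @return list with `p0`, `p1` and their sum `p`.
#' @export
pTuples <- function(n, h, k) {
  p0 <- fallingEven(2 * n - 2 * h - 2, k)
  p1 <- if (k >= 1) k * fallingEven(2 * n - 2 * h - 2, k - 1) else 0
  list(p0 = p0, p1 = p1, p = p0 + p1)
}

pT <- function(n, h, k) if (k < 0) 0 else pTuples(n, h, k)$p

posOrZero <- function(x) if (x > 0) x else 0

#' Upper bound on the H-pairs with |S2| = k
#'
#' Counts the pairs satisfying the feasibility conditions except the
#' descendant condition: a k-tuple from the hybrid-free tuple set plus one
#' tree node (with repetition) or an unordered pair of distinct tree nodes
#' among the t - k = 2n + h - r remaining ones, with r = k + 1.
#'
#' @inheritParams pTuples
#' @export
fH <- function(n, h, k) {
  r <- k + 1
  m <- 2 * n + h - r
  p <- pT(n, h, k)
  p * posOrZero(m) + p * posOrZero(m * (m - 1) / 2)
}

#' Upper bound on the T-pairs with |S2| = k
#'
#' Four mutually exclusive cases for the single S1 node: outside S2;
#' inside S2 as a child or sibling of a hybrid node (3h candidates);
#' inside S2 as the sibling of another S2 member (sibling tree-node pairs,
#' root-aware); inside S2 with none of the above. With r = k + 1.
#'
#' @inheritParams pTuples
#' @export
fT <- function(n, h, k) {
  r <- k + 1
  m <- 2 * n + h - r
  p <- pT(n, h, k)
  f1 <- p * posOrZero(m)
  f2 <- if (k >= 1) pT(n, h, k - 1) * k * 3 * h else 0
  f3 <- if (k >= 2) {
    pk2 <- pTuples(n, h, k - 2)
    k * (k - 1) * (pk2$p1 * posOrZero(2 * n - 2 * h - 2 * r + 6) +
                   pk2$p0 * posOrZero(2 * n - 2 * h - 2 * r + 4))
  } else 0
  f4 <- p * k
  f1 + f2 + f3 + f4
}

#' Recursive upper bound on the number of networks
#'
#' Every network over `{1..n}` with h hybrid nodes arises by a unique
#' augmentation from a network over `{1..n-1}` with h' hybrid nodes, where
#' the S2 tuple has length h - h' (type T) or h - h' - 1 (type H). Using
#' the pair-count bounds [fT()] and [fH()] in place of exact feasible-pair
#' counts gives the recursion
#' `B(n, h) <= sum_h' B(n-1, h') fT(n-1, h', h-h') +
#'  sum_h' B(n-1, h') fH(n-1, h', h-h'-1)`
#' with `B(1, 0) = 1`, and `|BTC_n| <= sum_h B(n, h)` with h at most
#' n - 1. All arithmetic is exact (arbitrary-precision integers).
#'
#' @param nMax compute the table for n = 1..nMax.
#' @return an object of class `"BoundTable"`: a list with `nMax`,
#'   `B` (list over n of character vectors, entry h+1 = B(n, h) as an
#'   exact digit string), `totals` (character vector of digit strings),
#'   and `totalsNumeric` (doubles, exact while below 2^53).
#' @examples
#' boundTable(4)$totals   # "1" "3" "85" "7442"
#' @export
boundTable <- function(nMax) {
  nMax <- as.integer(nMax)
  if (nMax < 1L) stop("nMax must be at least 1")
  B <- vector("list", nMax)              # B[[n]][[h+1]] as bignum
  B[[1]] <- list(bigFromNumeric(1))
  if (nMax > 1L) for (n in 2:nMax) {
    B[[n]] <- vector("list", n)
    for (h in 0:(n - 1L)) {
      acc <- 0L
      for (hp in 0:min(h, n - 2L)) {
        cT <- fT(n - 1L, hp, h - hp)
        if (cT > 0)
          acc <- bigAdd(acc, bigMul(B[[n - 1L]][[hp + 1L]], bigFromNumeric(cT)))
        if (hp <= h - 1L) {
          cH <- fH(n - 1L, hp, h - hp - 1L)
          if (cH > 0)
            acc <- bigAdd(acc, bigMul(B[[n - 1L]][[hp + 1L]], bigFromNumeric(cH)))
        }
      }
      B[[n]][[h + 1L]] <- acc
    }
  }
  totalsBig <- lapply(seq_len(nMax), function(n)
    Reduce(bigAdd, B[[n]], 0L))
  out <- list(
    nMax = nMax,
    B = lapply(B, function(row) vapply(row, bigToString, "")),
    totals = vapply(totalsBig, bigToString, ""),
    totalsNumeric = vapply(totalsBig, bigToNumeric, numeric(1)))
  class(out) <- "BoundTable"
  out
}

#' @export
print.BoundTable <- function(x, ...) {
  cat("Upper bounds on the number of binary tree-child networks\n")
  for (n in seq_len(x$nMax))
    cat(sprintf("  n = %2d: %s\n", n, x$totals[n]))
  invisible(x)
}
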