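---
title: "Reduction, generation and counting of binary tree-child networks"
author: "btcnets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduction, generation and counting of binary tree-child networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(btcnets)
```

# The model

Binary tree-child (BTC) networks are the workhorse class of explicit
phylogenetic networks: rooted, binary, leaf-labeled DAGs whose nodes are
tree nodes (indegree at most one) or hybrid nodes (indegree two, outdegree
one), with the *tree-child* condition that every non-leaf node has at
least one tree-node child. Biologically, every non-extant taxon is
required to have at least one descendant line that evolved by mutation
alone; this is what keeps the class computationally tractable while still
expressing hybridization, recombination and lateral transfer. With `n`
leaves a BTC network has `t = 2n + h - 1` tree nodes and `h <= n - 1`
hybrid nodes; the trivial network is a single node that is root and leaf
at once, with degree pair (0, 0) — the one sanctioned exception to the
degree table, needed so that every reduction chain has a terminal object.

`PhyloNetwork` stores the arc list and the leaf-to-taxon map with opaque
integer node identifiers assigned in creation order. Every iteration
order in the package derives from those identifiers, which is what makes
generation order, enumeration order and serialized output reproducible
across runs and platforms. `validateNetwork()` diagnoses each axiom
separately instead of throwing, so malformed inputs can be reported
usefully by the readers.

# Reduction and augmentation

For a leaf `l`, the *TH-path* is the unique maximal tree-node path ending
at `l` whose off-path children are pairwise distinct hybrid nodes
(`computeTHPath()`). Its head is never the root of a non-trivial network,
and its maximality case decides the leaf's type: type H when the head's
parent is a hybrid node, type T otherwise. `reduceLeaf()` deletes the
(extended) path, eliminates the elementary nodes this creates — provably
exactly the off-path hybrids and the head's parents — and returns the
reduced network together with the *recovering data* `(S1, S2)`: the
multiset of heirs of the deleted parents (one node for T, two for H) and
the tuple of heirs of the deleted hybrids in path order. The two
coincidence cases are informative rather than pathological: when the
single S1 node of a T-reduction also appears in S2, and when the two
S1 members of an H-reduction coincide, which is precisely the signal that
the two deleted parents were linked by an arc.

`augmentNetwork()` inverts this with node splitting: split the S1
node(s), thread a new path, feed a new hybrid above each S2 node in
order, and label the path's end with the new taxon. The split order
(S1 first, then S2 left to right) is semantically load-bearing in the
coincidence cases, reproducing the arc between the two new elementary
nodes. A pair is *feasible* (`checkFeasible()`) when S2 members are
pairwise distinct and non-sibling unless rescued by S1 membership, every
hybrid-adjacent S2 member lies in S1, no S1 node is a proper descendant
of an S2 node, and the kind condition holds. Two readings the package
fixes deliberately:

* **The H kind condition is `|S1| = 2`** (with `S1` and `S2` disjoint).
  A multiset of two — possibly equal — split targets is the only reading
  under which H-reductions produce data that their own augmentation
  accepts, so that is what is implemented and tested.
* **"Proper descendant" is strict**: a node is not a proper descendant of
  itself, which is exactly what permits the single S1 node of a T-pair to
  re-enter S2 (the arc-coincidence case above).

# Unique generation and the random generator

Because distinct feasible pairs on one network, and any pairs on
non-isomorphic networks, give non-isomorphic offspring, depth-first
expansion of the trivial network through every feasible pair — adding
leaves 2, 3, …, n — produces each BTC network over `{1..n}` exactly once.
`generateAll()` never checks isomorphism. In count-only mode the walk
stops one level short and sums feasible-pair counts (each pair *is* one
offspring), so the final level is never materialized and memory stays at
one branch of the recursion; the same walk tallies offspring by hybrid
count for `countByHybrids()`.

Isomorphism, where the tests and the replay machinery do need it, is
decided by the μ-vector canonical key: each node's vector of path counts
to the leaves, taken as a sorted multiset together with the sorted
multiset of arc pairs of such vectors. Within the tree-child class a
μ-vector is shared by at most a hybrid node and its single child, so the
`(kind, μ-vector)` pair is a stable node reference across serialization;
`RecoveringData` carries μ-vectors alongside raw identifiers for exactly
that reason, and `replayAugmentations()` resolves them in the network
reconstructed so far. The arc-pair component of the key is a deliberate
belt-and-braces addition; the whole key is validated against a
brute-force leaf-colored digraph isomorphism search (VF2) on every
network with up to three leaves in the test suite.

`randomNetwork()` picks one feasible pair uniformly at each step. This
reaches every network but is *not* uniform on the space — networks whose
ancestors offer fewer feasible pairs are favored — and no claim of
uniformity is made anywhere; the estimator below is the only consumer of
uniform sampling and it samples a fully materialized level instead. Each
draw seeds R's Mersenne-Twister locally and restores the session RNG
state on exit.

`estimateNextCount()` estimates the next level's size as (mean offspring
count of a uniform sample) × (level size). Sampling is simple random
sampling *without* replacement — a uniform sample of distinct networks —
and the reported standard error is the conservative `sd/sqrt(m)` without
the finite-population correction. The offspring-count distribution is
strongly right-skewed (at four leaves the counts range from 75 to 1882
around a mean of about 122), so the conservative form is the safer
calibration for the +/- 3 SE sanity interval the tests use. When the
requested sample covers the population the estimate is exact and the
standard error is zero.

# The counting bound

Dropping only the descendant condition makes the number of admissible
pairs a function of `(n, h, |S2|)` alone: `pTuples()` counts the
hybrid-free tuples (split into root-avoiding and root-containing parts),
and `fT()`/`fH()` assemble the four mutually exclusive T cases and the
two H cases. Feeding these into the level recursion with `B(1, 0) = 1`
gives `boundTable()`. Numerical conventions, chosen once and pinned down
by brute-force pair enumeration on concrete networks in the tests: a
tuple count is 1 at `k = 0` and 0 at `k < 0`; every factorial ratio is
evaluated as a step-two falling product that clamps to zero at its first
nonpositive factor; every standalone linear factor likewise zeroes its
term when nonpositive; and the `m(m-1)/2` pair count divides after
multiplying two consecutive integers, so all arithmetic stays integral.

The totals overflow doubles from ten leaves on (about 8.6e19), so the
recursion runs on a small exact big-integer layer (base-1e6 digit
vectors; add, multiply, compare, format) kept internal to the package.
`boundTable()` therefore reports exact digit strings next to the
convenience doubles.

# Sequence placement

A `SequencedNetwork` maps every tree node to an equal-length string over
a finite alphabet; hybrid nodes carry none (their single child does).
The bundled `toyModel()` uses a symmetric single-parameter substitution
kernel `PS(s, s') = mu^d (1-2mu)^(L-d)` over a three-letter alphabet
(`0 < mu < 1/3`) and models hybridization as plain recombination of
sequence halves, each of the two recombinants having probability 1/2
(collapsing to probability 1 when they coincide). Sequence optimization
is exhaustive over the full candidate space in lexicographic order —
81 candidates at the default length 4 — so ties resolve to the
lexicographically smallest sequence; the model object is a plain list of
kernels, so a user-supplied model can swap in any search strategy.

`placeSequence()` runs the greedy heuristic: score every speciation
attachment (`pi(t) = phi_t(sigma) PS(sigma, s(t)) PS(sigma, s_l)`,
maximized over sigma) and every hybridization attachment (the analogous
two-node product through `PH`), prefer speciation on ties, then
iteratively add hybridizations feeding existing nodes while the gain
`kappa` — the score minus the no-hybridization explanation of the same
data — is non-negative, accepting the gain-maximizing candidate each
round. Design choices the package had to fix:

* **The root is not an attachment candidate.** The scores divide the
  incoming arc of a candidate node and compare descent factors; the root
  has no incoming arc, and its constant ancestry factor would otherwise
  dominate every comparison by construction rather than by evidence.
  Candidate sets for both the attachment and the hybridization rounds are
  therefore the non-root tree nodes.
* **Candidates below a hybrid parent are skipped with a warning.** The
  gain formulas need a sequenced parent; a candidate whose parent is a
  hybrid node (possible only in the T coincidence case) has none, and no
  principled adaptation is available, so such candidates are excluded
  loudly rather than scored arbitrarily.
* **A zero gain keeps the candidate**: the rejection test is strictly
  negative gain. Ties in scores break by smallest node identifier, then
  lexicographically smallest sequence, keeping placement deterministic.
* Sequence inference is stepwise-greedy: each round maximizes its own
  sigma given the previous round's choice; no joint optimization across
  rounds is attempted, and no claim of global optimality is made.

The worked three-taxon example in the README and test suite exercises
every branch: attachment above taxon 1 with inferred sequence AAAC, one
accepted hybridization into taxon 2's lineage with inferred sequence
AACC, and a second round that rejects all remaining candidates. The gain
of that hybridization changes sign at `mu = 1/(2 + sqrt 2)`, which the
acceptance script recovers numerically from the heuristic's own trace.

# Input and output

The extended Newick dialect writes every hybrid node twice under a shared
`#Hk` tag (numbered by ascending node identifier), expanding its subtree
at the first occurrence only; children appear in ascending identifier
order, so output is byte-stable. The reader merges tag occurrences,
rejects tags appearing once or carrying several subtrees, accepts
arbitrary string taxa (mapped to `1..n` with the dictionary attached as
an attribute), and validates the result — erroring by default,
downgrading to a warning with `strict = FALSE`. Because eNewick
anonymizes nodes, the tab-separated edge-list format is provided as the
lossless interchange, preserving identifiers exactly. FASTA files keyed
by node identifiers supply placement sequences. A thin command-line
wrapper (`btcCLI()`, `inst/scripts/btcnets.R`) exposes generation,
counting, bounds, reduction, augmentation, random draws, estimation and
placement as subcommands.

# Problem sizes and limitations

The test suite exercises exhaustive generation fully to five leaves
(496,710 networks, counted without materialization in roughly half a
minute on one core), key uniqueness on all 4,059 four-leaf networks,
round trips over every four-leaf network and leaf, 200 random
reduction/replay chains up to eight leaves, and bound totals to ten
leaves. Six-leaf exhaustive generation (101,833,875 networks) follows
the same code path but is hours-scale in R and is not part of any
routine run. The random-network support-coverage check draws 2,000
three-leaf networks; with the least likely of the 66 networks drawn with
probability at least about 1/75, the chance of missing any is below
1e-9.

What passing these checks does and does not show: the generator and the
counting recursion are exact combinatorial statements and are tested as
such; the placement heuristic, by contrast, is a greedy procedure whose
correctness claims are only that it reproduces its defining scores and
terminates — a sequence of locally optimal choices need not be a global
optimum, and the toy model's recombination kernel is a caricature of real
reticulate evolution (no branch lengths, no rate heterogeneity, fixed
alphabet, hard half-splits). Uniform sampling of BTC networks is out of
scope by construction, as is anything non-binary, unrooted, or with
out-degree above two; the μ-machinery is used for equality testing only,
not as a distance.
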