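test_that("the validator accepts legal networks, including the trivial one", {
  expect_true(validateNetwork(trivialNetwork())$ok)
  expect_true(validateNetwork(exampleHybridNetwork())$ok)
  expect_true(validateNetwork(cherryNetwork())$ok)
})

test_that("the validator pinpoints a hybrid node whose only child is hybrid", {
  ## r -> a, b; a and b feed hybrid h1; a and h1 feed hybrid h2
  net <- phyloNetwork(
    rbind(c(3, 4), c(3, 5), c(4, 6), c(5, 6), c(4, 7), c(6, 7),
          c(7, 1), c(5, 2)),
    c(`1` = 1, `2` = 2))
  v <- validateNetwork(net)
  expect_false(v$ok)
  rules <- vapply(v$violations, `[[`, "", "rule")
  expect_true("tree-child" %in% rules)
  offenders <- unlist(lapply(v$violations[rules == "tree-child"], `[[`,
                             "nodes"))
  expect_true(6 %in% offenders)   # the hybrid with a hybrid-only child
})

test_that("the validator separates degree, root and label violations", {
  ## two roots
  twoRoots <- phyloNetwork(rbind(c(3, 1), c(4, 2)), c(`1` = 1, `2` = 2))
  rules <- vapply(validateNetwork(twoRoots)$violations, `[[`, "", "rule")
  expect_true("single-root" %in% rules)
  ## out-degree 3 at the root
  deg3 <- phyloNetwork(rbind(c(4, 1), c(4, 2), c(4, 3)),
                       c(`1` = 1, `2` = 2, `3` = 3))
  rules <- vapply(validateNetwork(deg3)$violations, `[[`, "", "rule")
  expect_true("degree-table" %in% rules)
  ## duplicated taxon
  dup <- phyloNetwork(rbind(c(3, 1), c(3, 2)), c(`1` = 1, `2` = 1))
  rules <- vapply(validateNetwork(dup)$violations, `[[`, "", "rule")
  expect_true("label-bijection" %in% rules)
})

test_that("splitting creates an elementary node and elimination undoes it", {
  triv <- trivialNetwork()
  sp <- splitNode(triv, 1)
  expect_identical(networkEdges(sp$network),
                   matrix(c(sp$node, 1L), 1, 2))  # d(new) = (0, 1)
  back <- eliminateElementary(sp$network)
  expect_true(isIsomorphic(back, triv))

  ## split an internal node twice: an elementary path of length two
  net <- exampleHybridNetwork()
  s1 <- splitNode(net, 6)
  s2 <- splitNode(s1$network, s1$node)
  restored <- eliminateElementary(s2$network)
  expect_true(isIsomorphic(restored, net))
  expect_identical(sort(networkNodes(restored)), sort(networkNodes(net)))
})

test_that("splitting an unknown node errors; foreign degrees are rejected", {
  expect_error(splitNode(trivialNetwork(), 99), "not in the network")
  bad <- phyloNetwork(rbind(c(4, 1), c(4, 2), c(4, 3)),
                      c(`1` = 1, `2` = 2, `3` = 3))
  expect_error(eliminateElementary(bad), "degree outside")
})

test_that("a chain of elementary nodes above a leaf collapses to the trivial network", {
  ## root(0,1) -> e -> leaf
  chain <- phyloNetwork(rbind(c(3, 2), c(2, 1)), c(`1` = 1))
  out <- eliminateElementary(chain)
  expect_true(isIsomorphic(out, trivialNetwork()))
})

test_that("mu-vectors have the forced values on tiny networks", {
  expect_equal(unname(muVectors(trivialNetwork())), matrix(1L, 1, 1))
  mu <- muVectors(cherryNetwork())
  rows <- sort(unname(apply(mu, 1, paste, collapse = ",")))
  expect_equal(rows, sort(c("1,0", "0,1", "1,1")))
})

test_that("canonical keys agree with brute-force digraph isomorphism on all small networks", {
  skip_if_not_installed("igraph")
  nets <- c(generateAll(2), generateAll(3))
  keys <- vapply(nets, muRepresentation, "")
  expect_false(anyDuplicated(keys) > 0)
  ## distinct keys correspond to non-isomorphic graphs (spot-check VF2 on
  ## every pair within BTC_2 and a systematic sample of BTC_3 pairs)
  for (i in 1:2) for (j in (i + 1):3)
    expect_false(bruteIso(nets[[i]], nets[[j]]))
  n3 <- nets[-(1:3)]
  idx <- seq(1, length(n3), by = 7)
  for (i in idx) for (j in idx) if (i < j)
    expect_false(bruteIso(n3[[i]], n3[[j]]))
  ## renaming nodes preserves both the key and VF2 isomorphism
  for (net in n3[idx[1:3]]) {
    shifted <- phyloNetwork(networkEdges(net) + 100L,
                            stats::setNames(leafTaxa(net),
                                            as.integer(names(leafTaxa(net))) + 100L),
                            nodes = networkNodes(net) + 100L)
    expect_identical(muRepresentation(shifted), muRepresentation(net))
    expect_true(bruteIso(shifted, net))
  }
})

test_that("isomorphism requires equal taxon sets", {
  expect_true(isIsomorphic(cherryNetwork(), cherryNetwork()))
  expect_false(isIsomorphic(cherryNetwork(1, 2), cherryNetwork(1, 3)))
  expect_false(isIsomorphic(cherryNetwork(),
                            augmentNetwork(trivialNetwork(), 2, c(1, 1))))
})

test_that("node-count identities hold on generated and random networks", {
  for (net in generateAll(3)) {
    n <- nLeaves(net); t <- nTreeNodes(net); h <- nHybridNodes(net)
    expect_identical(t - h, 2L * n - 1L)
    expect_lte(h, n - 1L)
    expect_lte(t, 3L * n - 2L)
  }
  for (s in 1:5) {
    net <- randomNetwork(7, s)
    expect_true(validateNetwork(net)$ok)
    expect_identical(nTreeNodes(net) - nHybridNodes(net), 13L)
  }
})
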