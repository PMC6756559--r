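test_that("feasibility on the trivial network matches the defining conditions", {
  triv <- trivialNetwork()
  expect_identical(checkFeasible(triv, 1)$kind, "T")
  expect_identical(checkFeasible(triv, 1, 1)$kind, "T")   # S1 may re-enter S2
  expect_identical(checkFeasible(triv, c(1, 1))$kind, "H")
  bad <- checkFeasible(triv, c(1, 1), 1)
  expect_true(is.na(bad$kind))
  expect_true("4H" %in% bad$violated)
  expect_error(checkFeasible(triv, 99), "not in the network")
})

test_that("feasibility rejects duplicated, sibling and hybrid-adjacent S2 nodes", {
  net <- exampleHybridNetwork()   # leaves 3 and 4 are tree-node siblings
  expect_true("1" %in% checkFeasible(net, 1, c(3, 3))$violated)
  expect_true("1" %in% checkFeasible(net, 1, c(3, 4))$violated)
  expect_identical(checkFeasible(net, 3, c(3, 4))$kind, "T")  # rescued by S1
  ## leaf 2 is the child of the hybrid: needs to be in S1
  expect_true("2" %in% checkFeasible(net, 1, 2)$violated)
  expect_identical(checkFeasible(net, 2, 2)$kind, "T")
  ## descendant condition: the root's child 6 is above leaf 1
  expect_true("3" %in% checkFeasible(net, 1, 6)$violated)
})

test_that("augmenting the trivial network gives the three two-taxon networks", {
  triv <- trivialNetwork()
  pairs <- enumerateFeasiblePairs(triv)
  expect_identical(length(pairs), 3L)
  expect_identical(vapply(pairs, `[[`, "", "kind"), c("T", "T", "H"))
  expect_identical(lapply(pairs, `[[`, "S2"),
                   list(integer(0), 1L, integer(0)))
  nets <- lapply(pairs, function(p) augmentNetwork(triv, 2, p$S1, p$S2))
  keys <- vapply(nets, muRepresentation, "")
  expect_identical(anyDuplicated(keys), 0L)
  ## plain cherry among them; hybrid counts follow the pair shape
  expect_true(any(vapply(nets, function(nn) isIsomorphic(nn, cherryNetwork()),
                         logical(1))))
  expect_identical(vapply(nets, nHybridNodes, integer(1)), c(0L, 1L, 1L))
})

test_that("hybrid-count deltas match the pair shape on every augmentation", {
  for (net in generateAll(2)) {
    h <- nHybridNodes(net)
    for (p in enumerateFeasiblePairs(net)) {
      child <- augmentNetwork(net, 3, p$S1, p$S2)
      expected <- if (p$kind == "T") h + length(p$S2) else h + length(p$S2) + 1L
      expect_identical(nHybridNodes(child), expected)
      expect_true(validateNetwork(child)$ok)
    }
  }
})

test_that("offspring of one network are pairwise non-isomorphic", {
  for (net in generateAll(2)) {
    keys <- vapply(enumerateFeasiblePairs(net), function(p)
      muRepresentation(augmentNetwork(net, 3, p$S1, p$S2)), "")
    expect_identical(anyDuplicated(keys), 0L)
  }
})

test_that("pair counts over a level sum to the next level's count", {
  total <- sum(vapply(generateAll(2), countFeasiblePairs, numeric(1)))
  expect_identical(total, 66)
})

test_that("enumeration is deterministic and bounded by the closed-form counts", {
  net <- randomNetwork(4, 11)
  p1 <- enumerateFeasiblePairs(net)
  p2 <- enumerateFeasiblePairs(net)
  expect_identical(p1, p2)
  ## the closed forms drop only the descendant condition, so they dominate
  n <- nLeaves(net); h <- nHybridNodes(net)
  byLen <- table(factor(vapply(p1, function(p) length(p$S2), integer(1)),
                        levels = 0:8),
                 vapply(p1, `[[`, "", "kind"))
  for (k in 0:8) {
    expect_lte(byLen[as.character(k), "T"], fT(n, h, k))
    expect_lte(byLen[as.character(k), "H"], fH(n, h, k))
  }
})

test_that("infeasible pairs and duplicate labels are refused", {
  expect_error(augmentNetwork(trivialNetwork(), 2, c(1, 1), 1),
               "not feasible")
  expect_error(augmentNetwork(trivialNetwork(), 1, 1), "already a taxon")
})
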