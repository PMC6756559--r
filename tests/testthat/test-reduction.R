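test_that("TH-paths classify the textbook cases", {
  ## cherry, leaf of taxon 2: r = 1, type T (sibling is a tree node)
  th <- computeTHPath(cherryNetwork(), 2)
  expect_identical(th$path, 2L)
  expect_identical(th$type, "T")
  expect_identical(th$r, 1L)

  ## leaf below the hybrid of the one-hybrid two-taxon network: type H
  netH <- augmentNetwork(trivialNetwork(), 2, c(1, 1))
  leaf2 <- as.integer(names(leafTaxa(netH))[leafTaxa(netH) == 2])
  thH <- computeTHPath(netH, leaf2)
  expect_identical(thH$type, "H")
  expect_identical(thH$r, 1L)
  expect_identical(length(thH$w), 2L)

  ## coincidence augmentation: extension stops because the head's parent
  ## feeds an off-path hybrid already on the path (type T, r = 2)
  netT <- augmentNetwork(trivialNetwork(), 2, 1, 1)
  leaf2 <- as.integer(names(leafTaxa(netT))[leafTaxa(netT) == 2])
  thT <- computeTHPath(netT, leaf2)
  expect_identical(thT$type, "T")
  expect_identical(thT$r, 2L)
  expect_identical(length(thT$v), 1L)

  expect_error(computeTHPath(trivialNetwork(), 1), "trivial")
  expect_error(computeTHPath(cherryNetwork(), 3), "not a leaf")
})

test_that("TH-path heads are never the root on non-trivial networks", {
  for (s in 1:8) {
    net <- randomNetwork(6, 40 + s)
    r <- rootNode(net)
    for (lf in leafNodes(net))
      expect_false(computeTHPath(net, lf)$path[1] == r)
  }
})

test_that("reducing a cherry yields the trivial network with T recovering data", {
  res <- reduceLeaf(cherryNetwork(), 2)
  expect_true(isIsomorphic(res$network, trivialNetwork()))
  expect_identical(res$data@kind, "T")
  expect_identical(res$data@S2, integer(0))
  expect_identical(leafTaxa(res$network)[[as.character(res$data@S1)]], 1L)
})

test_that("the coincidence cases put one heir in both S1 and S2 (T) or twice in S1 (H)", {
  ## T with the S1 node re-entering S2
  netT <- augmentNetwork(trivialNetwork(), 2, 1, 1)
  leaf2 <- as.integer(names(leafTaxa(netT))[leafTaxa(netT) == 2])
  res <- reduceLeaf(netT, leaf2)
  expect_identical(res$data@kind, "T")
  expect_identical(res$data@S1, res$data@S2)

  ## H with the two w-nodes linked by an arc: equal heirs
  netH <- augmentNetwork(trivialNetwork(), 2, c(1, 1))
  leaf2 <- as.integer(names(leafTaxa(netH))[leafTaxa(netH) == 2])
  resH <- reduceLeaf(netH, leaf2)
  expect_identical(resH$data@kind, "H")
  expect_identical(resH$data@S1[1], resH$data@S1[2])
})

test_that("node-count deltas of a reduction follow the extended path length", {
  for (s in 1:6) {
    net <- randomNetwork(5, 90 + s)
    for (lf in leafNodes(net)) {
      th <- computeTHPath(net, lf)
      res <- reduceLeaf(net, lf)
      expect_identical(nTreeNodes(res$network),
                       nTreeNodes(net) - length(th$extended) - 1L)
      expect_identical(nHybridNodes(res$network),
                       nHybridNodes(net) - length(th$extended) + 1L)
      expect_true(validateNetwork(res$network)$ok)
      feas <- checkFeasible(res$network, res$data@S1, res$data@S2)
      expect_identical(feas$kind, res$data@kind)
    }
  }
})

test_that("reduction inverts augmentation exactly (same pair recovered)", {
  for (net in generateAll(2)) {
    for (p in enumerateFeasiblePairs(net)) {
      child <- augmentNetwork(net, nLeaves(net) + 1L, p$S1, p$S2)
      leaf <- as.integer(names(leafTaxa(child))[leafTaxa(child) ==
                                                  nLeaves(net) + 1L])
      back <- reduceLeaf(child, leaf)
      expect_true(isIsomorphic(back$network, net))
      expect_identical(back$data@kind, p$kind)
      expect_identical(sort(back$data@S1), sort(p$S1))
      expect_identical(back$data@S2, p$S2)
    }
  }
})

test_that("reduce-to-trivial then replay reconstructs the network", {
  expect_identical(reduceToTrivial(trivialNetwork()), list())
  steps <- reduceToTrivial(cherryNetwork())
  expect_identical(length(steps), 1L)
  expect_identical(steps[[1]]@kind, "T")
  for (s in c(7, 19, 23)) {
    net <- randomNetwork(6, s)
    back <- replayAugmentations(reduceToTrivial(net))
    expect_true(isIsomorphic(net, back))
  }
})

test_that("reduction refuses the trivial network and foreign labels", {
  expect_error(reduceLeaf(trivialNetwork(), 1), "trivial")
  expect_error(reduceToTrivial(cherryNetwork(1, 3)), "1..n")
})
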