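mu <- 0.1
model <- toyModel(mu)

test_that("the toy kernels follow the symmetric-mutation and half-recombination rules", {
  expect_equal(model$PS("AAAC", "AAAC"), (1 - 2 * mu)^4)
  expect_equal(model$PS("AAAC", "AACC"), mu * (1 - 2 * mu)^3)
  expect_equal(model$PH("AABB", "CCBB", "AABB"), 0.5)
  expect_equal(model$PH("AABB", "CCBB", "CCBB"), 0.5)
  expect_equal(model$PH("AABB", "CCBB", "ACCB"), 0)
  ## the recombinant distribution sums to one, also when both halves agree
  tot <- sum(vapply(model$candidates, function(s)
    model$PH("AABB", "CCBB", s), numeric(1)))
  expect_equal(tot, 1)
  expect_equal(sum(vapply(model$candidates, function(s)
    model$PH("ABAB", "ABCC", s), numeric(1))), 1)
  expect_error(toyModel(0.4), "between 0 and 1/3")
  expect_error(toyModel(0.1, length = 3), "even")
})

test_that("ancestry probabilities are one at the root and kernel-driven elsewhere", {
  snet <- exampleSequencedNetwork()
  expect_equal(phiProbability(snet, 4, "CCCC", model), 1)
  expect_equal(phiProbability(snet, 1, "AAAC", model),
               model$PS("AAAA", "AAAC"))
  ## below a hybrid: the two grandparent sequences recombine
  fit <- placeSequence(snet, 4, "AACC", model)
  net2 <- fit$network
  kinds <- nodeKinds(net2@network)
  hyb <- networkNodes(net2@network)[kinds == "hybrid"]
  below <- networkEdges(net2@network)[networkEdges(net2@network)[, 1] == hyb, 2]
  expect_equal(phiProbability(net2, below, net2@sequences[[as.character(below)]],
                              model), 0.5)
})

test_that("attachment selection reproduces the worked example's scores", {
  snet <- exampleSequencedNetwork()
  sel <- selectAttachment(snet, "AACC", model)
  expect_identical(sel$kind, "T")
  expect_identical(leafTaxa(snet@network)[[as.character(sel$S1)]], 1L)
  expect_identical(sel$sigma, "AAAC")
  expect_equal(sel$piT, mu^2 * (1 - 2 * mu)^10)
  expect_equal(sel$piH, mu^3 * (1 - 2 * mu)^13 / 2)
})

test_that("speciation beats hybridization at every admissible mutation rate here", {
  for (m in c(0.05, 0.15, 0.25, 0.32)) {
    sel <- selectAttachment(exampleSequencedNetwork(), "AACC", toyModel(m))
    expect_identical(sel$kind, "T")
  }
})

test_that("the greedy extension accepts exactly one hybridization in the worked example", {
  snet <- exampleSequencedNetwork()
  fit <- placeSequence(snet, 4, "AACC", model)
  tr <- fit$trace
  expect_identical(leafTaxa(snet@network)[[as.character(tr$ys)]], 2L)
  expect_identical(tr$sigmaY, "AACC")
  it1 <- tr$iterations[[1]]
  accepted <- it1[it1$accepted, ]
  expect_equal(accepted$pi, mu * (1 - 2 * mu)^7 / 2)
  expect_equal(accepted$kappa,
               mu * (1 - 2 * mu)^7 / 2 - mu^3 * (1 - 2 * mu)^5)
  ## the second round rejects every remaining candidate
  expect_identical(length(tr$iterations), 2L)
  expect_false(any(tr$iterations[[2]]$accepted))
  ## final network: one speciation split above taxon 1 plus a hybrid into
  ## taxon 2's lineage
  ref <- augmentNetwork(snet@network, 4, 1, 2)
  expect_true(isIsomorphic(fit$network@network, ref))
  expect_true(validateNetwork(fit$network@network)$ok)
  expect_identical(nLeaves(fit$network@network), 4L)
})

test_that("above the gain threshold no hybridization is accepted", {
  fit <- placeSequence(exampleSequencedNetwork(), 4, "AACC", toyModel(0.3))
  expect_identical(fit$trace$ys, integer(0))
  expect_true(isIsomorphic(fit$network@network,
                           augmentNetwork(exampleSequencedNetwork()@network,
                                          4, 1)))
})

test_that("degenerate placements behave: trivial host and duplicate sequences", {
  ## trivial network: only a speciation attachment is possible
  triv <- sequencedNetwork(trivialNetwork(), c(`1` = "AAAA"))
  fit <- placeSequence(triv, 2, "AAAA", model)
  expect_true(isIsomorphic(fit$network@network, cherryNetwork()))
  expect_identical(fit$trace$kind, "T")
  ## placing a copy of an existing leaf sequence into a two-leaf tree
  two <- sequencedNetwork(cherryNetwork(),
                          c(`1` = "AAAA", `2` = "CCCC", `3` = "CCCC"))
  fit2 <- placeSequence(two, 3, "AAAA", model)
  expect_identical(fit2$trace$kind, "T")
  expect_identical(fit2$trace$ys, integer(0))
  expect_identical(nHybridNodes(fit2$network@network), 0L)
})

test_that("placement is deterministic", {
  a <- placeSequence(exampleSequencedNetwork(), 4, "AACC", model)
  b <- placeSequence(exampleSequencedNetwork(), 4, "AACC", model)
  expect_identical(a$trace, b$trace)
  expect_identical(networkEdges(a$network@network),
                   networkEdges(b$network@network))
})
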