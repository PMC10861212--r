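test_that("transition operator is column-stochastic with the stated normalization", {
  # single edge A-B: M swaps the two nodes
  net <- WeightedNetwork(data.frame(from = "A", to = "B", weight = 1))
  M <- as.matrix(buildTransition(net))
  expect_equal(unname(M), rbind(c(0, 1), c(1, 0)))
  # weighted star: column of the hub splits proportionally to edge weight
  star <- WeightedNetwork(data.frame(from = c("H", "H", "H"),
                                     to = c("X", "Y", "Z"),
                                     weight = c(0.2, 0.3, 0.5)))
  Ms <- as.matrix(buildTransition(star))
  expect_equal(Ms[c("X", "Y", "Z"), "H"], c(X = 0.2, Y = 0.3, Z = 0.5))
  expect_equal(unname(colSums(Ms)), rep(1, 4))
  # random graphs: every column sums to 1, isolated nodes self-absorb
  for (s in 1:3) {
    rn <- random_network(40, p = 0.05, seed = s)
    Mr <- buildTransition(rn)
    expect_equal(unname(Matrix::colSums(Mr)), rep(1, length(networkNodes(rn))),
                 tolerance = 1e-12)
  }
})

test_that("rwr solves the two-node case analytically", {
  net <- WeightedNetwork(data.frame(from = "A", to = "B", weight = 1))
  prop <- rwr(net, "A", restart = 0.7)
  # closed form: p = r (I - (1-r)M)^-1 e => (0.7/0.91, 0.21/0.91)
  expect_equal(unname(affinity(prop)[c("A", "B")]),
               c(0.7 / 0.91, 0.21 / 0.91), tolerance = 1e-9)
  expect_true(isConverged(prop))
})

test_that("rwr agrees with the dense direct solve and conserves mass", {
  for (s in 1:5) {
    net <- random_network(60, p = 0.06, seed = s)
    nodes <- networkNodes(net)
    seedNode <- nodes[[1 + (s %% length(nodes))]]
    prop <- rwr(net, seedNode, restart = 0.7)
    want <- oracle_rwr(buildTransition(net), match(seedNode, nodes), 0.7)
    expect_lt(max(abs(affinity(prop) - want)), 1e-8)
    expect_equal(sum(affinity(prop)), 1, tolerance = 1e-9)
  }
})

test_that("unreachable components score exactly zero", {
  net <- WeightedNetwork(data.frame(from = c("A", "C"), to = c("B", "D"),
                                    weight = c(1, 1)))
  prop <- rwr(net, "A")
  expect_identical(unname(affinity(prop)[c("C", "D")]), c(0, 0))
  # and pseudo-activation therefore excludes them
  act <- pseudoActivated(prop)
  expect_identical(geneIds(act), "B")
})

test_that("rwr is equivariant under node relabeling and concentrates as r -> 1", {
  net <- random_network(30, p = 0.15, seed = 9)
  prop <- rwr(net, networkNodes(net)[[1]], restart = 0.7)
  # relabel nodes by a fixed permutation of names
  e <- networkEdges(net)
  perm <- setNames(sprintf("Z%03d", seq_along(networkNodes(net))),
                   networkNodes(net))
  net2 <- WeightedNetwork(data.frame(from = perm[e$from], to = perm[e$to],
                                     weight = e$weight),
                          nodes = unname(perm))
  prop2 <- rwr(net2, perm[[networkNodes(net)[[1]]]], restart = 0.7)
  expect_equal(unname(affinity(prop2)[perm[names(affinity(prop))]]),
               unname(affinity(prop)), tolerance = 1e-12)
  # restart monotonicity: seed affinity grows toward 1
  seedNode <- networkNodes(net)[[1]]
  a <- vapply(c(0.3, 0.6, 0.9, 0.99), function(r)
    affinity(rwr(net, seedNode, restart = r))[[seedNode]], numeric(1))
  expect_true(all(diff(a) > 0))
  expect_gt(a[[4]], 0.97)
})

test_that("rwr validates seeds and pseudoActivated requires convergence", {
  net <- toy_two_cliques()
  expect_error(rwr(net, "NOPE"), "NOPE")
  prop <- rwr(net, "A", tol = 0, maxIter = 3)
  expect_false(isConverged(prop))
  expect_error(pseudoActivated(prop), "converge")
  # connected graph, empty exclusion: all non-seed nodes pseudo-activated
  ok <- rwr(net, "A")
  expect_setequal(geneIds(pseudoActivated(ok)),
                  setdiff(networkNodes(net), "A"))
  expect_setequal(geneIds(pseudoActivated(ok, exclude = c("B", "C"))),
                  c("D", "E", "F"))
})

test_that("module detection separates cliques and beats singletons", {
  part <- detectModules(toy_two_cliques())
  mem <- moduleMembership(part)
  expect_equal(length(unique(mem[mem > 0])), 2)
  expect_length(unique(mem[c("A", "B", "C")]), 1)
  expect_length(unique(mem[c("D", "E", "F")]), 1)
  expect_gt(part@modularity, 0)  # better than the all-singleton partition
  # planted partition recovery over seeds
  ari <- vapply(1:5, function(s) {
    sim <- simulateNetwork(80, c(40, 40), pIn = 0.3, pOut = 0.02, seed = s)
    mem <- moduleMembership(detectModules(sim$network))
    truth <- sim$truth@plantedModules[names(mem)]
    oracle_ari(mem[names(truth)], truth)
  }, numeric(1))
  expect_gte(mean(ari >= 0.8), 0.8)
})

test_that("module annotation agrees with hypergeometric enumeration on a tiny universe", {
  net <- toy_two_cliques()
  part <- detectModules(net)
  mem <- moduleMembership(part)
  m1 <- sort(names(mem)[mem == mem[["A"]]])
  sets <- list(GeneSet(m1, name = "EXACT"),
               GeneSet(setdiff(networkNodes(net), m1), name = "DISJOINT"))
  ann <- annotateModule(part, mem[["A"]], sets)
  expect_equal(ann$label[[1]], "EXACT")
  expect_equal(ann$p[ann$label == "DISJOINT"], 1)
  # enumeration oracle: P(X >= a) by summing dhyper over the tail
  a <- ann$overlap[ann$label == "EXACT"]
  K <- 3; n <- 6; k <- 3
  want <- sum(dhyper(a:k, K, n - K, k))
  expect_equal(ann$p[ann$label == "EXACT"], want, tolerance = 1e-12)
  expect_error(annotateModule(part, 99L, sets), "no module")
})
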