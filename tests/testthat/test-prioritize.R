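# Direct-neighborhood prioritization and the context-associated hub scan.

test_that("hypergeometric overlap p matches brute-force enumeration on small universes", {
  expect_equal(fisherOverlapP(10, 5, 5, 5), 1 / 252)
  expect_equal(fisherOverlapP(4, 2, 2, 1), 5 / 6)
  expect_equal(fisherOverlapP(8, 3, 4, 0), 1)
  set.seed(17)
  for (i in 1:200) {
    N <- sample(2:25, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(fisherOverlapP(N, K, n, k), bruteHyperUpper(N, K, n, k),
                 tolerance = 1e-12)
  }
  expect_error(fisherOverlapP(10, 11, 5, 1), "inconsistent")
  expect_error(fisherOverlapP(10, 5, 3, 4), "inconsistent")
})

test_that("overlap p is non-increasing in the observed overlap", {
  for (N in c(10, 20)) {
    K <- N %/% 2; n <- N %/% 3
    ps <- vapply(0:min(n, K), function(k) fisherOverlapP(N, K, n, k),
                 numeric(1))
    expect_true(all(diff(ps) <= 0))
  }
})

test_that("neighborhood ranking sums guide-edge weights and excludes guides", {
  net <- FunctionalNetwork(c("g1", "g1", "g1", "g2", "g2"),
                           c("c1", "c2", "g2", "c1", "c3"),
                           c(1.5, 0.7, 9, 2.5, 0.2))
  rc <- neighborhoodRank(net, c("g1", "g2", "ghost"), topN = 100)
  tb <- candidates(rc)
  expect_identical(tb$gene, c("C1", "C2", "C3"))
  expect_equal(tb$score, c(4.0, 0.7, 0.2))  # c1 linked to both guides
  expect_identical(tb$rank, 1:3)
  expect_false(any(c("G1", "G2") %in% tb$gene))  # guide-guide edge ignored
  expect_identical(rc@guidesUnmapped, "GHOST")
  expect_error(neighborhoodRank(net, "nowhere"), "NOWHERE")
})

test_that("single-guide star ranks leaves by edge weight", {
  net <- starNetwork("G", c("x", "y"), c(1.5, 0.7))
  tb <- candidates(neighborhoodRank(net, "G"))
  expect_identical(tb$gene, c("X", "Y"))
  expect_equal(tb$score, c(1.5, 0.7))
})

test_that("ranking is invariant to guide order and edge orientation; ranks are dense", {
  pm <- plantedModuleNetwork(80, 4, 0.4, 0.05, seed = 6)
  guides <- names(pm$truth$modules)[pm$truth$modules == 1][1:8]
  r1 <- candidates(neighborhoodRank(pm$network, guides), all = TRUE)
  r2 <- candidates(neighborhoodRank(pm$network, rev(guides)), all = TRUE)
  expect_identical(r1, r2)
  e <- edges(pm$network)
  flipped <- FunctionalNetwork(e$geneB, e$geneA, e$score)
  r3 <- candidates(neighborhoodRank(flipped, guides), all = TRUE)
  expect_identical(r1, r3)
  expect_true(all(diff(r1$score) <= 0))
  expect_identical(sort(unique(r1$rank)), seq_along(unique(r1$score)))
})

test_that("equal scores share a dense rank and the top-n cut is flagged on ties", {
  net <- FunctionalNetwork(rep("g", 4), c("a", "b", "c", "d"), c(2, 1, 1, 0.5))
  rc <- suppressMessages(neighborhoodRank(net, "g", topN = 2))
  tb <- candidates(rc, all = TRUE)
  expect_identical(tb$rank, c(1L, 2L, 2L, 3L))
  expect_true(rc@tieAtCut)
  expect_equal(nrow(candidates(rc)), 2)
  expect_equal(nrow(tb), 4)
})

test_that("the hub scan finds a planted DEG-enriched hub and orders by p", {
  pm <- plantedModuleNetwork(200, 1, 0.25, 0.01, seed = 8)
  net <- pm$network
  hubs <- genesWithMinNeighbors(net, 30)
  expect_gt(length(hubs), 1)
  degs <- plantedDegContext(net, hubs[1], 0.9, 0.02, seed = 9)
  res <- contextHubScan(net, degs, minNeighbors = 30)
  expect_identical(res$hub[1], hubs[1])
  expect_true(all(diff(res$p) >= 0))
  expect_true(res$significant[1])
  expect_true(all(res$nOverlap <= pmin(res$nNeighbors, length(degs))))
})

test_that("hub scan degenerate cases: DEGs everywhere, no hubs, disjoint DEGs", {
  pm <- plantedModuleNetwork(60, 2, 0.8, 0.2, seed = 10)
  all <- contextHubScan(pm$network, genes(pm$network), minNeighbors = 10)
  expect_true(all(all$p == 1))  # K = N forces the overlap
  none <- contextHubScan(pm$network, genes(pm$network)[1:5],
                         minNeighbors = 1000)
  expect_equal(nrow(none), 0)
  expect_error(contextHubScan(pm$network, c("zz1", "zz2")), "intersection size 0")
})

test_that("BH q-values are a monotone transform of the p-values", {
  pm <- plantedModuleNetwork(150, 3, 0.3, 0.02, seed = 11)
  degs <- plantedDegContext(pm$network, genes(pm$network)[1], 0.8, 0.1,
                            seed = 12)
  res <- contextHubScan(pm$network, degs, minNeighbors = 10, adjust = TRUE)
  expect_true(all(diff(res$q) >= -1e-12))
  expect_equal(res$q, p.adjust(res$p, "BH"))
  expect_true(all(res$q >= res$p))
})

test_that("paralog annotation joins without disturbing the ranking", {
  net <- starNetwork("G", c("x", "y", "z"), c(3, 2, 1))
  rc <- neighborhoodRank(net, "G")
  plain <- annotateParalogs(rc)
  expect_identical(candidates(plain)$paralogs, c("", "", ""))
  expect_identical(candidates(plain)[, c("rank", "gene", "score")],
                   candidates(rc))
  ann <- annotateParalogs(rc, list(x = c("p2", "p1"), z = "OUTSIDER"))
  tb <- candidates(ann)
  expect_identical(tb$paralogs, c("P1,P2", "", "OUTSIDER"))
})
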