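# Log-likelihood calibration and weighted-sum integration.

makeGold <- function(posKeys, negKeys) {
  new("GoldStandard", positives = sort(posKeys), negatives = sort(negKeys),
      sourceTerms = character())
}

# one labeled evidence row per key, all in one score band
bandEvidence <- function(keys, score) {
  d <- splitPairKeys(keys)
  asEvidenceTable(d$geneA, d$geneB, rep(score, length(keys)))
}

test_that("prior odds from a gold standard and from printed pair counts", {
  gold <- buildGoldStandard(tinyAnnotation())
  expect_equal(priorOdds(gold), 4 / 2)
  expect_equal(priorOdds(10, 40), 0.25)
  expect_equal(priorOdds(5, 5), 1)
  # the genome-scale training standard: 591664 positives, 58416152 negatives
  expect_equal(priorOdds(591664, 58416152), 0.0101284, tolerance = 1e-5)
})

test_that("a single bin of 30 positives and 10 negatives at unit prior scores ln 3", {
  pos <- sprintf("P%02d|Q%02d", 1:30, 1:30)
  neg <- sprintf("M%02d|N%02d", 1:30, 1:30)  # 30 negatives overall: prior 1
  gold <- makeGold(pos, neg)
  ev <- rbind(bandEvidence(pos, 1), bandEvidence(neg[1:10], 1))
  bt <- fitLLSBins(ev, gold, minPosPerBin = 30, pseudocount = 0)
  b <- llsBins(bt)
  expect_equal(nrow(b), 1)
  expect_equal(b$pos, 30)
  expect_equal(b$neg, 10)
  expect_equal(b$lls, log(3))
})

test_that("a bin whose pos/neg ratio equals the prior odds scores zero", {
  pos <- sprintf("P%02d|Q%02d", 1:20, 1:20)
  neg <- sprintf("M%02d|N%02d", 1:40, 1:40)  # prior odds 0.5
  gold <- makeGold(pos, neg)
  ev <- rbind(bandEvidence(pos[1:10], 2), bandEvidence(neg[1:20], 2))
  bt <- fitLLSBins(ev, gold, minPosPerBin = 10, pseudocount = 0)
  expect_equal(llsBins(bt)$lls, 0)
})

test_that("the pseudocount keeps zero-negative bins finite", {
  pos <- sprintf("P%02d|Q%02d", 1:10, 1:10)
  neg <- sprintf("M%02d|N%02d", 1:10, 1:10)
  gold <- makeGold(pos, neg)
  ev <- bandEvidence(pos, 3)
  bt <- fitLLSBins(ev, gold, minPosPerBin = 10, pseudocount = 0.5)
  expect_equal(llsBins(bt)$lls, log(((10 + 0.5) / 0.5) / 1))
  expect_error(fitLLSBins(ev, gold, minPosPerBin = 10, pseudocount = 0),
               "pseudocount")
})

test_that("uncalibratable evidence errors and bin counts conserve gold positives", {
  gold <- makeGold(sprintf("P%02d|Q%02d", 1:10, 1:10),
                   sprintf("M%02d|N%02d", 1:10, 1:10))
  stranger <- bandEvidence(sprintf("X%02d|Y%02d", 1:5, 1:5), 1)
  expect_error(fitLLSBins(stranger, gold, minPosPerBin = 2),
               "cannot be calibrated")
  pm <- plantedModuleNetwork(80, 4, 0.4, 0.05, seed = 2)
  gold2 <- buildGoldStandard(truthAnnotations(pm$truth))
  ev <- evidenceTables(pm$truth, nLayers = 1, signal = 1.5, noiseSd = 1,
                       seed = 3)[[1]]
  bt <- fitLLSBins(ev, gold2, minPosPerBin = 40)
  key <- paste(ev$geneA, ev$geneB, sep = "|")
  expect_equal(sum(llsBins(bt)$pos), sum(key %in% positivePairs(gold2)))
  expect_equal(sum(llsBins(bt)$neg), sum(key %in% negativePairs(gold2)))
  # edges strictly increasing and contiguous
  b <- llsBins(bt)
  expect_true(all(diff(b$lower) > 0))
  expect_equal(b$upper[-nrow(b)], b$lower[-1])
})

test_that("component scoring assigns bin LLS, clamps to terminal bins and applies the cutoff", {
  bins <- data.frame(lower = c(-Inf, 0, 1), upper = c(0, 1, Inf),
                     pos = c(1L, 1L, 1L), neg = c(1L, 1L, 1L),
                     lls = c(-1, 0.5, 2))
  bt <- new("LLSBinTable", bins = bins, priorOdds = 1, pseudocount = 0.5)
  ev <- asEvidenceTable(c("a", "c", "e", "g"), c("b", "d", "f", "h"),
                        c(-5, 0.5, 10, 0.2))
  net <- scoreComponent(ev, bt, minLLS = 0)
  e <- edges(net)
  expect_setequal(paste(e$geneA, e$geneB), c("C D", "E F", "G H"))
  expect_equal(e$score[e$geneA == "E"], 2)  # raw 10 beyond fitted range -> top bin
  expect_equal(e$score[e$geneA == "C"], 0.5)
  expect_equal(numEdges(scoreComponent(ev, bt, minLLS = 5)), 0)
  allOne <- scoreComponent(asEvidenceTable(c("a", "c"), c("b", "d"),
                                           c(2, 3)), bt)
  expect_equal(unique(edges(allOne)$score), 2)
})

test_that("weighted sum follows L0 + sum Li/(D i) and its limits", {
  expect_equal(weightedSum(2, D = 7), 2)
  expect_equal(weightedSum(c(2, 1), D = 1), 3)
  expect_equal(weightedSum(c(2, 1), D = 2), 2.5)
  expect_equal(weightedSum(c(1, 2), D = 2), 2.5)  # order-free
  expect_error(weightedSum(numeric(), 1), "undefined")
  expect_error(weightedSum(c(1, 2), 0.5), ">= 1")
  # monotone in each Li; strictly decreasing in D when n >= 2, L1 > 0
  set.seed(3)
  for (i in 1:20) {
    l <- sort(rexp(sample(2:6, 1)), decreasing = TRUE)
    D <- runif(1, 1, 5)
    expect_gte(weightedSum(l + 0.1, D), weightedSum(l, D))
    expect_lt(weightedSum(l, D + 1), weightedSum(l, D))
    expect_gte(weightedSum(l, D), l[1])
  }
  l <- c(3, 2, 1)
  expect_equal(weightedSum(l, D = 1e6), l[1], tolerance = 1e-6)
})

test_that("network integration collects per-pair LLS values across components", {
  c1 <- FunctionalNetwork(c("a", "c"), c("b", "d"), c(2, 1))
  c2 <- FunctionalNetwork("a", "b", 1)
  one <- integrateNetworks(list(c1), D = 3)
  expect_identical(edges(one), edges(c1))
  net <- integrateNetworks(list(c1, c2), D = 1)
  e <- edges(net)
  expect_equal(e$score[e$geneA == "A"], 3)
  expect_equal(e$score[e$geneA == "C"], 1)
  net2 <- integrateNetworks(list(c2, c1), D = 1)
  expect_identical(edges(net), edges(net2))
  # permutation invariance on a larger random ensemble
  pm <- plantedModuleNetwork(60, 3, 0.4, 0.1, seed = 9)
  comps <- lapply(1:3, function(s) {
    k <- topLinks(pm$network, 100 + 20 * s)
    FunctionalNetwork(edges(k)$geneA, edges(k)$geneB, edges(k)$score + s / 10)
  })
  i1 <- integrateNetworks(comps, D = 2)
  i2 <- integrateNetworks(rev(comps), D = 2)
  expect_equal(edges(i1), edges(i2))
  capped <- integrateNetworks(comps, D = 2, maxLinks = 50)
  expect_equal(numEdges(capped), 50)
})

test_that("D selection returns the grid value maximizing held-out OR-curve area", {
  expect_equal(selectD(list(FunctionalNetwork("a", "b", 1)),
                       buildGoldStandard(tinyAnnotation()), grid = 2.5), 2.5)
  # identical components: all D tie, smallest returned
  pm <- plantedModuleNetwork(60, 3, 0.5, 0.05, seed = 4)
  gold <- buildGoldStandard(truthAnnotations(pm$truth))
  same <- list(pm$network, pm$network)
  expect_equal(selectD(same, gold, grid = c(1, 2, 4)), 1)
  # informative + pure-noise component: chosen D does not lose to D = 1
  ev <- evidenceTables(pm$truth, nLayers = 2, signal = c(2, 0), noiseSd = 1,
                       seed = 5)
  comps <- lapply(ev, function(e) scoreComponent(e, fitLLSBins(e, gold, 30)))
  grid <- c(1, 2, 4, 8)
  areas <- vapply(grid, function(D) {
    cofunet:::orCurveArea(integrateNetworks(comps, D = D), gold)
  }, numeric(1))
  best <- selectD(comps, gold, grid = grid)
  expect_gte(areas[match(best, grid)], areas[grid == 1])
})
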