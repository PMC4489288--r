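# Odds-ratio precision-recall, guilt-by-association AUC, Wilcoxon
# comparisons and candidate-set enrichment.

test_that("odds ratio follows its definition, with infinite flag and correction", {
  expect_equal(oddsRatio(2, 1, 4, 4), 2)
  expect_equal(oddsRatio(4, 4, 4, 4), 1)  # full standard in the network
  expect_identical(oddsRatio(3, 0, 4, 4), Inf)
  expect_true(is.finite(oddsRatio(3, 0, 4, 4, correction = 0.5)))
  expect_error(oddsRatio(1, 1, 0, 4), "positive")
  expect_error(oddsRatio(5, 0, 4, 4), "inconsistent")
})

test_that("the cumulative OR curve has the stated limiting behaviour", {
  gold <- buildGoldStandard(tinyAnnotation())  # pos: ab ac bc cd; neg: ad bd
  # perfectly sorted: positives above negatives
  net <- FunctionalNetwork(c("a", "a", "b", "c", "a", "b"),
                           c("b", "c", "c", "d", "d", "d"),
                           c(6, 5, 4, 3, 2, 1))
  pr <- prCurve(net, gold)
  expect_identical(pr$oddsRatio[1], Inf)  # low recall, no negatives yet
  expect_equal(pr$oddsRatio[nrow(pr)], 1)  # network = whole validation set
  expect_equal(pr$recall[nrow(pr)], 1)
  expect_true(all(diff(pr$recall) >= 0))
  # single top edge on a validation positive: recall 1/posTot, infinite OR
  single <- FunctionalNetwork(c("a", "c", "a"), c("b", "d", "d"),
                              c(5, 0.5, 0.1))
  pr1 <- prCurve(single, gold)
  expect_equal(pr1$posIn[1], 1)
  expect_equal(pr1$recall[1], 1 / 4)
  expect_identical(pr1$oddsRatio[1], Inf)
  expect_error(prCurve(FunctionalNetwork("x", "y", 1), gold), "overlap")
})

test_that("tied scores enter the OR curve as one block", {
  gold <- buildGoldStandard(tinyAnnotation())
  net <- FunctionalNetwork(c("a", "a", "a"), c("b", "c", "d"), c(2, 2, 2))
  pr <- prCurve(net, gold)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$linksConsidered, 3)
})

test_that("a random-score network has OR near 1 across recalls", {
  pm <- plantedModuleNetwork(120, 4, 0.35, 0.05, seed = 20)
  gold <- buildGoldStandard(truthAnnotations(pm$truth))
  ij <- cofunet:::pairIndices(120)
  g <- names(pm$truth$modules)
  set.seed(21)
  rand <- FunctionalNetwork(g[ij$i], g[ij$j], runif(nrow(ij)))
  pr <- prCurve(rand, gold, correction = 0)
  mid <- pr[pr$recall > 0.2, ]
  # every labeled pair is in the network: OR is a consistent estimator of 1
  expect_true(all(abs(mid$oddsRatio - 1) <
                    3 / sqrt(pmin(mid$posIn, mid$negIn))))
  expect_equal(pr$oddsRatio[nrow(pr)], 1)
})

test_that("better-sorted validation pairs never lower the OR-curve area", {
  pm <- plantedModuleNetwork(100, 4, 0.4, 0.05, seed = 22)
  gold <- buildGoldStandard(truthAnnotations(pm$truth))
  mod <- pm$truth$modules
  ij <- cofunet:::pairIndices(100)
  g <- names(mod)
  same <- as.numeric(mod[ij$i] == mod[ij$j])
  set.seed(23)
  noise <- rnorm(nrow(ij))
  sharp <- FunctionalNetwork(g[ij$i], g[ij$j], 3 * same + noise)
  blurred <- FunctionalNetwork(g[ij$i], g[ij$j], 1 * same + noise)
  aSharp <- cofunet:::orCurveArea(sharp, gold)
  aBlur <- cofunet:::orCurveArea(blurred, gold)
  expect_gte(aSharp, aBlur)
})

test_that("guilt-by-association scores sum member edge weights with leave-one-out", {
  mem <- c("m1", "m2", "m3", "m4", "m5")
  cl <- t(combn(mem, 2))
  net <- FunctionalNetwork(c(cl[, 1], "m1", "lonely1"),
                           c(cl[, 2], "outsider", "lonely2"),
                           c(rep(1, nrow(cl)), 1, 1))
  s <- gbaScores(net, mem)
  expect_equal(unname(s[toupper(mem)]), rep(4, 5))  # 4 fellow members each
  expect_equal(unname(s["OUTSIDER"]), 1)
  expect_equal(unname(s["LONELY1"]), 0)
  # a member with no member edges scores 0 despite membership
  net2 <- FunctionalNetwork(c("m1", "m3"), c("m2", "x"), c(1, 1))
  s2 <- gbaScores(net2, c("m1", "m2", "m3"))
  expect_equal(unname(s2["M3"]), 0)
})

test_that("rocAuc equals the brute-force ordered-pair fraction and its complement identity", {
  expect_equal(rocAuc(setNames(c(3, 1, 2, 0), c("a", "b", "c", "d")),
                      c("a", "b")), 0.75)
  expect_equal(rocAuc(setNames(c(5, 4), c("a", "b")), "a"), 1)
  expect_equal(rocAuc(setNames(rep(1, 6), letters[1:6]), c("a", "b")), 0.5)
  set.seed(30)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    sc <- setNames(sample(round(rnorm(n), 2)), sprintf("g%03d", 1:n))
    mem <- sample(names(sc), sample(2:(n - 2), 1))
    auc <- rocAuc(sc, mem)
    expect_equal(auc, bruteAuc(sc, mem), tolerance = 1e-12)
    expect_equal(auc + rocAuc(-sc, mem), 1, tolerance = 1e-12)
  }
  expect_error(rocAuc(setNames(1:3, c("a", "b", "c")), c("a", "b", "c")),
               "undefined")
})

test_that("per-term AUC applies the membership floor and separates planted from scrambled terms", {
  pm <- plantedModuleNetwork(120, 4, 0.4, 0.02, seed = 31)
  ann <- truthAnnotations(pm$truth)
  small <- PathwayAnnotation(c(ann@terms,
                               list(TINY = genes(pm$network)[1:4])))
  res <- aucPerTerm(pm$network, small, minMembers = 5)
  expect_false("TINY" %in% res$term)
  expect_true("TINY" %in% attr(res, "skipped"))
  expect_true(all(res$auc[res$term %in% termNames(ann)] > 0.9))
  set.seed(32)
  scram <- PathwayAnnotation(list(SCRAM = sample(genes(pm$network), 30)))
  resS <- aucPerTerm(pm$network, scram)
  expect_lt(abs(resS$auc - 0.5), 0.2)
  # determinism
  expect_identical(res, aucPerTerm(pm$network, small, minMembers = 5))
})

test_that("signed-rank comparison: degenerate, exact-enumeration and symmetry cases", {
  a <- c(0.5, 0.6, 0.7, 0.8)
  expect_warning(res <- compareNetworks(a, a), "zero")
  expect_equal(res$p.value, 1)
  # uniform +0.1 shift on 8 pairs: exact two-sided p = 2/256
  b <- seq(0.1, 0.8, 0.1)
  res <- compareNetworks(b + 0.1, b)
  expect_equal(res$p.value, 2 / 256)
  expect_identical(res$method, "exact")
  # pair order must not matter
  perm <- sample(8)
  res2 <- compareNetworks((b + 0.1)[perm], b[perm])
  expect_equal(res2[c("statistic", "p.value")], res[c("statistic", "p.value")])
  # tie-free case agrees with the reference implementation
  set.seed(40)
  x <- rnorm(12); y <- x + rnorm(12, 0.3)
  ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
  mine <- compareNetworks(x, y)
  expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
})

test_that("exact signed-rank p agrees with the large-sample approximation for moderate n", {
  # outside the extreme tail, where a normal approximation is meaningful
  set.seed(41)
  checked <- 0
  for (i in 1:40) {
    d <- rnorm(15, mean = runif(1, 0, 0.4))
    exact <- compareNetworks(d, rep(0, 15), exactLimit = 16)
    if (exact$p.value < 0.05) next
    approx <- compareNetworks(d, rep(0, 15), exactLimit = 0)
    expect_lt(abs(approx$p.value - exact$p.value) / exact$p.value, 0.1)
    checked <- checked + 1
  }
  expect_gte(checked, 10)
})

test_that("rank-sum comparison: exact enumeration, shift invariance, reference agreement", {
  res <- rankSumCompare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 0.1)  # 2 x 1/20 by labeling enumeration
  same <- rankSumCompare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p.value, 1)
  shifted <- rankSumCompare(c(1, 2, 3) + 100, c(4, 5, 6) + 100)
  expect_equal(shifted[c("statistic", "p.value")],
               res[c("statistic", "p.value")])
  set.seed(42)
  x <- rnorm(8); y <- rnorm(9, 1)
  ref <- wilcox.test(x, y, exact = TRUE)
  mine <- rankSumCompare(x, y)
  expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
})

test_that("candidate-set enrichment wraps the hypergeometric upper tail", {
  univ <- sprintf("u%02d", 1:20)
  ann <- univ[1:10]
  expect_equal(enrichment(univ[11:15], ann, univ)$p.value, 1)  # disjoint
  full <- enrichment(univ, univ, univ)
  expect_equal(full$p.value, 1)  # forced overlap
  res <- enrichment(univ[1:5], ann, univ)
  expect_equal(res$overlap, 5)
  expect_equal(res$p.value, choose(10, 5) / choose(20, 5))
  expect_error(enrichment("a", "b", character()), "empty")
})
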