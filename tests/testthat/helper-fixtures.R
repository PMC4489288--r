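# Shared fixtures and independent oracles, built in code.

starNetwork <- function(center = "H", leaves = paste0("L", 1:4),
                        weights = rep(1, length(leaves))) {
  FunctionalNetwork(rep(center, length(leaves)), leaves, weights)
}

tinyAnnotation <- function() {
  PathwayAnnotation(list(T1 = c("a", "b", "c"), T2 = c("c", "d")))
}

# Independent hypergeometric upper-tail oracle: direct enumeration of the
# probability mass from binomial coefficients.
bruteHyperUpper <- function(N, K, n, k) {
  js <- k:min(n, K)
  js <- js[js >= max(0, n - (N - K))]
  if (!length(js)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Independent AUC oracle: fraction of (member, non-member) pairs correctly
# ordered, ties counted 0.5.
bruteAuc <- function(scores, members) {
  isMem <- names(scores) %in% members
  s1 <- scores[isMem]
  s0 <- scores[!isMem]
  cmp <- outer(s1, s0, function(x, y) (x > y) + 0.5 * (x == y))
  mean(cmp)
}

# Independent gold-standard oracle: label every pair of the annotated
# universe by brute force shared-term lookup.
bruteGold <- function(termList) {
  termList <- lapply(termList, function(g) unique(toupper(g)))
  genes <- sort(unique(unlist(termList)))
  pos <- character(); neg <- character()
  for (i in seq_along(genes)) {
    for (j in seq_len(i - 1L)) {
      a <- genes[j]; b <- genes[i]
      shared <- any(vapply(termList, function(g) a %in% g && b %in% g,
                           logical(1L)))
      key <- paste(a, b, sep = "|")
      if (shared) pos <- c(pos, key) else neg <- c(neg, key)
    }
  }
  list(positives = sort(pos), negatives = sort(neg))
}

randomAnnotation <- function(nGenes, nTerms, seed) {
  set.seed(seed)
  genes <- sprintf("R%03d", seq_len(nGenes))
  terms <- lapply(seq_len(nTerms), function(i) {
    sample(genes, sample(2:max(2, nGenes %/% 2), 1L))
  })
  names(terms) <- sprintf("T%02d", seq_len(nTerms))
  terms
}
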