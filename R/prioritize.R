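# Gene prioritization: direct-neighborhood ranking from guide genes, and
# the context-associated-hub scan against a DEG set.

#' One-sided Fisher (hypergeometric upper-tail) overlap probability
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim Hypergeom(N, K, n)}: the probability of
#' drawing at least \code{k} special items when \code{n} items are drawn
#' without replacement from a universe of \code{N} containing \code{K}
#' special ones. This is the p-value of a one-sided Fisher exact test for
#' over-representation.
#'
#' @param N universe size.
#' @param K special items in the universe (e.g. DEGs).
#' @param n draw size (e.g. a hub's neighbor count).
#' @param k observed overlap, \code{0 <= k <= min(n, K)}.
#' @return probability in (0, 1].
#' @examples
#' fisherOverlapP(10, 5, 5, 5)  # 1/252
#' @export
fisherOverlapP <- function(N, K, n, k) {
  N <- assertCount(N, "N"); K <- assertCount(K, "K")
  n <- assertCount(n, "n"); k <- assertCount(k, "k")
  if (K > N || n > N)
    stop("inconsistent counts: need K <= N and n <= N", call. = FALSE)
  if (k > min(n, K))
    stop("inconsistent counts: need k <= min(n, K)", call. = FALSE)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Prioritize genes by direct network neighborhood of guide genes
#'
#' Candidate genes are the direct neighbors of the mapped guide genes,
#' excluding the guides themselves (candidates are strictly novel). Each
#' candidate's score is the sum of its edge weights (log-likelihood scores)
#' over all edges to mapped guides. Candidates are sorted by score
#' descending, ties by gene id; dense ranks are assigned (equal scores
#' share a rank) and the list is cut after the \code{topN}-th row of the
#' tie-sorted order. The full ranking is kept in the returned object
#' (\code{candidates(x, all = TRUE)}).
#'
#' Guides absent from the network are reported, not fatal — unless none
#' maps, which is an error.
#'
#' @param net a [FunctionalNetwork-class].
#' @param guides character vector of guide gene ids.
#' @param topN truncation length for the default view (default 100).
#' @return a [RankedCandidates-class].
#' @export
neighborhoodRank <- function(net, guides, topN = 100) {
  stopifnot(is(net, "FunctionalNetwork"))
  topN <- assertCount(topN, "topN", min = 1)
  guides <- unique(normalizeGeneId(guides))
  g <- genes(net)
  mapped <- intersect(guides, g)
  unmapped <- setdiff(guides, g)
  if (!length(mapped))
    stop(sprintf("no guide gene maps into the network (unmapped: %s)",
                 paste(unmapped, collapse = ", ")), call. = FALSE)
  e <- edges(net)
  ia <- e$geneA %in% mapped & !(e$geneB %in% guides)
  ib <- e$geneB %in% mapped & !(e$geneA %in% guides)
  cand <- c(e$geneB[ia], e$geneA[ib])
  sc <- c(e$score[ia], e$score[ib])
  if (length(cand)) {
    agg <- rowsum(sc, cand)
    cand <- rownames(agg)
    sc <- as.numeric(agg[, 1L])
  } else {
    cand <- character(); sc <- numeric()
  }
  ord <- order(-sc, cand)
  cand <- cand[ord]; sc <- sc[ord]
  rnk <- if (length(sc)) match(sc, unique(sc)) else integer()
  tieAtCut <- length(sc) > topN && sc[topN] == sc[topN + 1L]
  if (tieAtCut)
    message(sprintf("a score tie straddles the top-%d cut", topN))
  tb <- data.frame(rank = rnk, gene = cand, score = sc,
                   stringsAsFactors = FALSE)
  rownames(tb) <- NULL
  new("RankedCandidates", table = tb, topN = as.integer(topN),
      guidesUsed = mapped, guidesUnmapped = unmapped, tieAtCut = tieAtCut)
}

#' @describeIn neighborhoodRank the ranked candidate table; the top-n slice
#'   by default, the full ranking with \code{all = TRUE}.
#' @param x a RankedCandidates object.
#' @param all return the full ranking instead of the top-n slice.
#' @export
setMethod("candidates", "RankedCandidates", function(x, all = FALSE, ...) {
  if (all) x@table else utils::head(x@table, x@topN)
})

setMethod("show", "RankedCandidates", function(object) {
  cat(sprintf(
    "RankedCandidates: %d candidates (showing top %d), %d guides used, %d unmapped\n",
    nrow(object@table), min(object@topN, nrow(object@table)),
    length(object@guidesUsed), length(object@guidesUnmapped)))
  print(utils::head(object@table, 5L))
  if (object@tieAtCut) cat("  note: a score tie straddles the top-n cut\n")
})

#' Scan for context-associated hubs
#'
#' Tests every hub gene (degree strictly greater than \code{minNeighbors},
#' default 50) for over-representation of a DEG set among its direct
#' neighbors, using the one-sided hypergeometric test with the full network
#' gene set as universe. DEGs outside the network are dropped (their count
#' is reported via the \code{"nDegsDropped"} attribute); a DEG set disjoint
#' from the network is an error. A hub is never counted in its own
#' neighborhood. Results are sorted by p ascending, ties by larger overlap
#' then gene id; hubs with \code{p <= alpha} are flagged significant.
#' Benjamini-Hochberg q-values are attached when \code{adjust = TRUE}
#' (off by default — the raw threshold is the method's operating
#' convention).
#'
#' @param net a [FunctionalNetwork-class].
#' @param degs character vector of differentially expressed gene ids.
#' @param minNeighbors hub degree threshold (default 50, strict).
#' @param strict require degree strictly greater than \code{minNeighbors}.
#' @param alpha significance threshold on the raw p-value (default 0.01).
#' @param adjust attach BH-adjusted q-values.
#' @return data.frame (hub, nNeighbors, nOverlap, p, significant[, q]),
#'   one row per hub; empty when no gene exceeds the degree threshold.
#' @export
contextHubScan <- function(net, degs, minNeighbors = 50, strict = TRUE,
                           alpha = 0.01, adjust = FALSE) {
  stopifnot(is(net, "FunctionalNetwork"))
  alpha <- assertProb(alpha, "alpha")
  g <- genes(net)
  degs <- unique(normalizeGeneId(degs))
  degsIn <- intersect(degs, g)
  nDropped <- length(degs) - length(degsIn)
  if (!length(degsIn))
    stop(sprintf("none of the %d DEGs occur in the network (intersection size 0)",
                 length(degs)), call. = FALSE)
  hubs <- genesWithMinNeighbors(net, minNeighbors, strict = strict)
  N <- length(g)
  K <- length(degsIn)
  if (!length(hubs)) {
    out <- data.frame(hub = character(), nNeighbors = integer(),
                      nOverlap = integer(), p = numeric(),
                      significant = logical())
    attr(out, "nDegsDropped") <- nDropped
    return(out)
  }
  e <- edges(net)
  nbrOf <- c(split(e$geneB, e$geneA), split(e$geneA, e$geneB))
  res <- lapply(hubs, function(h) {
    nb <- unlist(nbrOf[names(nbrOf) == h], use.names = FALSE)
    n <- length(nb)
    k <- sum(nb %in% degsIn)
    data.frame(hub = h, nNeighbors = n, nOverlap = k,
               p = fisherOverlapP(N, K, n, k), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$p, -out$nOverlap, out$hub), , drop = FALSE]
  rownames(out) <- NULL
  out$significant <- out$p <= alpha
  if (adjust) out$q <- stats::p.adjust(out$p, method = "BH")
  attr(out, "nDegsDropped") <- nDropped
  out
}

#' Annotate ranked candidates with paralogs
#'
#' Left-joins a gene-to-paralog table onto a candidate ranking to flag
#' potential functional back-up during mutant phenotyping. Ranking is
#' unchanged; candidates without table entries get an empty paralog field.
#' Paralog membership in the network is irrelevant — the annotation is
#' independent of network structure.
#'
#' @param cands a [RankedCandidates-class].
#' @param paralogTable named list: gene id -> character vector of paralog
#'   ids. May be empty.
#' @return the [RankedCandidates-class] with a \code{paralogs} column
#'   (comma-separated, lexicographic order).
#' @export
annotateParalogs <- function(cands, paralogTable = list()) {
  stopifnot(is(cands, "RankedCandidates"))
  if (length(paralogTable))
    names(paralogTable) <- normalizeGeneId(names(paralogTable))
  tb <- cands@table
  tb$paralogs <- vapply(tb$gene, function(gn) {
    p <- paralogTable[[gn]]
    if (is.null(p) || !length(p)) "" else
      paste(sort(unique(normalizeGeneId(p))), collapse = ",")
  }, character(1L))
  cands@table <- tb
  cands
}
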