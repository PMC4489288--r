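# Network assessment: odds-ratio precision-recall, guilt-by-association
# ROC/AUC, nonparametric network comparison, candidate-set enrichment.

#' Odds ratio of a network against a validation standard
#'
#' Precision relative to chance for a set of network links:
#' \deqn{OR = \frac{(pos_{in}) / (neg_{in})}{pos_{tot} / neg_{tot}}}
#' the ratio of labeled positives to labeled negatives among network links,
#' divided by the same ratio over the whole validation standard. A network
#' containing every labeled pair has OR = 1. With \code{correction = 0} and
#' \code{negIn = 0} the result is \code{Inf} (the infinite flag); a
#' positive \code{correction} (e.g. 0.5) is added to both network counts to
#' keep the value finite.
#'
#' @param posIn,negIn labeled positive/negative pairs among network links.
#' @param posTot,negTot total labeled positives/negatives (> 0).
#' @param correction additive continuity correction (default 0).
#' @return a single non-negative number, possibly \code{Inf}.
#' @examples
#' oddsRatio(2, 1, 4, 4)  # 2
#' @export
oddsRatio <- function(posIn, negIn, posTot, negTot, correction = 0) {
  if (posTot <= 0 || negTot <= 0)
    stop("total positive and negative counts must be positive", call. = FALSE)
  if (posIn > posTot || negIn > negTot || posIn < 0 || negIn < 0)
    stop("inconsistent counts: need 0 <= posIn <= posTot, 0 <= negIn <= negTot",
         call. = FALSE)
  num <- posIn + correction
  den <- negIn + correction
  if (den == 0) {
    if (num == 0) return(NaN)
    return(Inf)
  }
  (num / den) / (posTot / negTot)
}

#' Cumulative odds-ratio precision-recall curve
#'
#' Walks the network's links from the highest score down and emits the
#' cumulative odds ratio and recall after each block of tied scores (tied
#' links enter as one block, so the curve does not depend on their order).
#' Only links whose pair carries a validation label count; unlabeled links
#' are ignored. Validation pairs are first restricted to genes present in
#' the network, and recall is the fraction of those restricted positives
#' recovered.
#'
#' @param net a [FunctionalNetwork-class].
#' @param validation a [GoldStandard-class].
#' @param nPoints number of evenly spaced recall checkpoints to flag in the
#'   \code{checkpoint} column (default 20).
#' @param correction continuity correction passed to [oddsRatio()]
#'   (default 0: early all-positive blocks give \code{Inf}).
#' @return data.frame with one row per tied-score block:
#'   \code{linksConsidered}, \code{posIn}, \code{negIn}, \code{recall},
#'   \code{oddsRatio}, \code{checkpoint}.
#' @export
prCurve <- function(net, validation, nPoints = 20, correction = 0) {
  stopifnot(is(net, "FunctionalNetwork"), is(validation, "GoldStandard"))
  nPoints <- assertCount(nPoints, "nPoints", min = 1)
  g <- genes(net)
  restrictKeys <- function(keys) {
    d <- splitPairKeys(keys)
    keys[d$geneA %in% g & d$geneB %in% g]
  }
  pos <- restrictKeys(validation@positives)
  neg <- restrictKeys(validation@negatives)
  if (!length(pos) || !length(neg))
    stop("validation standard does not overlap the network gene universe",
         call. = FALSE)
  key <- pairKeys(net)
  lab <- integer(length(key))
  lab[key %in% pos] <- 1L
  lab[key %in% neg] <- -1L
  keep <- lab != 0L
  if (!any(keep))
    stop("no network link carries a validation label", call. = FALSE)
  s <- edges(net)$score[keep]
  l <- lab[keep]
  ord <- order(-s)
  s <- s[ord]; l <- l[ord]
  blockEnds <- c(which(diff(s) < 0), length(s))
  cumPos <- cumsum(l == 1L)[blockEnds]
  cumNeg <- cumsum(l == -1L)[blockEnds]
  recall <- cumPos / length(pos)
  or <- mapply(oddsRatio, cumPos, cumNeg,
               MoreArgs = list(posTot = length(pos), negTot = length(neg),
                               correction = correction))
  targets <- seq_len(nPoints) / nPoints
  checkpointIdx <- unique(vapply(targets, function(t) {
    which(recall >= t - 1e-12)[1L]
  }, integer(1L)))
  checkpointIdx <- checkpointIdx[!is.na(checkpointIdx)]
  data.frame(
    linksConsidered = blockEnds,
    posIn = cumPos, negIn = cumNeg,
    recall = recall, oddsRatio = as.numeric(or),
    checkpoint = seq_along(blockEnds) %in% checkpointIdx
  )
}

#' Guilt-by-association scores for a gene set
#'
#' Scores every network gene by the sum of its edge weights to the member
#' genes. A member is scored against the other members only (leave-one-out;
#' with no self-loops this is simply the sum of its edges to the remaining
#' members), so member genes can be ranked without label leakage.
#'
#' @param net a [FunctionalNetwork-class].
#' @param members character vector of member gene ids; at least two must be
#'   present in the network.
#' @return named numeric vector over all network genes (0 for genes with no
#'   edge to any member).
#' @export
gbaScores <- function(net, members) {
  members <- unique(normalizeGeneId(members))
  g <- genes(net)
  inNet <- intersect(members, g)
  if (length(inNet) < 2L)
    stop(sprintf("need >= 2 member genes in the network (found %d)",
                 length(inNet)), call. = FALSE)
  e <- edges(net)
  scores <- setNames(numeric(length(g)), g)
  ia <- e$geneA %in% inNet
  ib <- e$geneB %in% inNet
  if (any(ia)) {
    add <- rowsum(e$score[ia], e$geneB[ia])
    scores[rownames(add)] <- scores[rownames(add)] + add[, 1L]
  }
  if (any(ib)) {
    add <- rowsum(e$score[ib], e$geneA[ib])
    scores[rownames(add)] <- scores[rownames(add)] + add[, 1L]
  }
  scores
}

#' ROC AUC by the rank-sum formulation
#'
#' The probability that a randomly chosen member outranks a randomly chosen
#' non-member, with ties credited 0.5 — equivalently the Mann-Whitney
#' statistic divided by \eqn{n_1 n_2}, computed from mid-ranks.
#'
#' @param scores named numeric vector (gene -> score) over the evaluation
#'   universe.
#' @param members character vector of positive-class gene ids.
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(scores, members) {
  if (is.null(names(scores))) stop("'scores' must be named by gene", call. = FALSE)
  names(scores) <- normalizeGeneId(names(scores))
  members <- unique(normalizeGeneId(members))
  isMem <- names(scores) %in% members
  n1 <- sum(isMem); n2 <- sum(!isMem)
  if (n1 == 0L || n2 == 0L)
    stop("AUC undefined: need at least one member and one non-member scored",
         call. = FALSE)
  r <- rank(scores)
  (sum(r[isMem]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Per-term guilt-by-association AUC
#'
#' For each annotation term with at least \code{minMembers} genes present
#' in the network, scores all network genes by [gbaScores()] against the
#' term's members and summarizes recovery of the members as a ROC AUC.
#' Terms below the membership floor are skipped and reported in the
#' \code{"skipped"} attribute.
#'
#' @param net a [FunctionalNetwork-class].
#' @param ann a [PathwayAnnotation-class].
#' @param minMembers membership floor counting only genes present in the
#'   network (default 5, i.e. strictly more than four).
#' @return data.frame (term, nMembers, auc), one row per qualifying term;
#'   attribute \code{"skipped"} lists the terms below the floor.
#' @export
aucPerTerm <- function(net, ann, minMembers = 5) {
  stopifnot(is(net, "FunctionalNetwork"), is(ann, "PathwayAnnotation"))
  minMembers <- assertCount(minMembers, "minMembers", min = 2)
  g <- genes(net)
  ids <- termNames(ann)
  rows <- list()
  skipped <- character()
  for (id in ids) {
    mem <- intersect(termGenes(ann, id), g)
    if (length(mem) < minMembers || length(mem) == length(g)) {
      skipped <- c(skipped, id)
      next
    }
    auc <- rocAuc(gbaScores(net, mem), mem)
    rows[[id]] <- data.frame(term = id, nMembers = length(mem), auc = auc,
                             stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(term = character(), nMembers = integer(), auc = numeric())
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

# Exact signed-rank null: distribution of the positive-rank sum over all
# 2^n sign assignments of the absolute-difference ranks.
signFlipPValue <- function(ranks, V) {
  sums <- 0
  for (r in ranks) sums <- c(sums, sums + r)
  eps <- 1e-9
  p <- 2 * min(mean(sums <= V + eps), mean(sums >= V - eps))
  min(1, p)
}

#' Paired comparison of AUC vectors (Wilcoxon signed rank)
#'
#' Two-sided Wilcoxon signed-rank test on paired differences
#' \code{a - b}. Zero differences are dropped (the standard convention).
#' With \code{n} non-zero differences at most \code{exactLimit}, the
#' p-value is computed by exhaustive enumeration of all \eqn{2^n} sign
#' assignments (correct under tied magnitudes, where the large-sample
#' formula is only approximate); otherwise a tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param a,b equal-length paired numeric vectors (e.g. per-term AUCs of
#'   two networks).
#' @param exactLimit maximum n for exact enumeration (default 16).
#' @return list with \code{statistic} (positive-rank sum V), \code{p.value},
#'   \code{n.used} and \code{method}.
#' @export
compareNetworks <- function(a, b, exactLimit = 16) {
  if (length(a) != length(b))
    stop("'a' and 'b' must be paired vectors of equal length", call. = FALSE)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero; no evidence of a difference")
    return(list(statistic = 0, p.value = 1, n.used = 0L, method = "degenerate"))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exactLimit) {
    p <- signFlipPValue(r, V)
    return(list(statistic = V, p.value = p, n.used = n, method = "exact"))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
  list(statistic = V, p.value = min(1, 2 * stats::pnorm(-abs(z))),
       n.used = n, method = "normal")
}

#' Two-sample rank-sum comparison (Mann-Whitney)
#'
#' Two-sided Wilcoxon rank-sum test, e.g. expression of top candidate genes
#' versus random genes. With a combined sample size at most
#' \code{exactLimit}, the p-value is exact by enumeration of all
#' \eqn{\binom{n_a+n_b}{n_a}} group labelings of the observed values
#' (valid under ties); otherwise a tie-corrected normal approximation with
#' continuity correction.
#'
#' @param a,b numeric vectors, both non-empty.
#' @param exactLimit maximum combined size for exact enumeration
#'   (default 20).
#' @return list with \code{statistic} (Mann-Whitney U for group a),
#'   \code{p.value}, and \code{method}.
#' @export
rankSumCompare <- function(a, b, exactLimit = 20) {
  if (!length(a) || !length(b))
    stop("both groups must be non-empty", call. = FALSE)
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  W <- sum(r[seq_len(na)])
  U <- W - na * (na + 1) / 2
  if (n <= exactLimit) {
    ws <- utils::combn(n, na, FUN = function(i) sum(r[i]))
    eps <- 1e-9
    p <- min(1, 2 * min(mean(ws <= W + eps), mean(ws >= W - eps)))
    return(list(statistic = U, p.value = p, method = "exact"))
  }
  mu <- na * nb / 2
  ties <- table(r)
  sigma2 <- na * nb / 12 * (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  list(statistic = U, p.value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal")
}

#' Hypergeometric enrichment of a candidate set
#'
#' Overlap of a candidate gene set with an annotated set inside a universe,
#' tested with the one-sided (upper tail) hypergeometric probability — a
#' Fisher exact enrichment test. Candidates and the annotated set are first
#' intersected with the universe.
#'
#' @param candidates character vector of candidate gene ids.
#' @param annotated character vector of annotated gene ids.
#' @param universe non-empty character vector defining the evaluation
#'   universe.
#' @return list with \code{overlap} (count) and \code{p.value}.
#' @export
enrichment <- function(candidates, annotated, universe) {
  universe <- unique(normalizeGeneId(universe))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  candidates <- intersect(unique(normalizeGeneId(candidates)), universe)
  annotated <- intersect(unique(normalizeGeneId(annotated)), universe)
  k <- length(intersect(candidates, annotated))
  p <- fisherOverlapP(length(universe), length(annotated),
                      length(candidates), k)
  list(overlap = k, p.value = p)
}
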