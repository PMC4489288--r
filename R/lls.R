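# Bayesian log-likelihood calibration of raw evidence scores.

#' Fit log-likelihood score bins for an evidence layer
#'
#' Calibrates raw pair scores against a gold standard under a naive Bayes
#' framework. Evidence pairs that carry a gold-standard label are sorted by
#' raw score descending and cut into contiguous bins, each holding at least
#' \code{minPosPerBin} gold positives (equal-positive-count binning
#' stabilizes the per-bin LLS variance). A bin never splits a run of tied
#' raw scores, so the binning is deterministic. Each bin receives
#' \deqn{LLS = \ln\frac{(pos + c)/(neg + c)}{P/N}}
#' with pseudocount \eqn{c} (default 0.5, which keeps zero-count bins
#' finite) and prior odds \eqn{P/N} from the gold standard. The trailing
#' segment with fewer than \code{minPosPerBin} positives is merged into the
#' previous bin. Terminal bin edges extend to \eqn{\pm\infty}; interior
#' edges sit at the midpoint between adjacent observed scores.
#'
#' @param evidence data.frame (geneA, geneB, score) of raw pair scores, as
#'   from [readEvidenceTable()].
#' @param gold a [GoldStandard-class].
#' @param minPosPerBin minimum gold positives per bin (default 100).
#' @param pseudocount additive count \eqn{c} (default 0.5).
#' @return an [LLSBinTable-class] with bins in ascending raw-score order.
#' @seealso [scoreComponent()], [priorOdds()]
#' @export
fitLLSBins <- function(evidence, gold, minPosPerBin = 100, pseudocount = 0.5) {
  stopifnot(is(gold, "GoldStandard"))
  minPosPerBin <- assertCount(minPosPerBin, "minPosPerBin", min = 1)
  if (pseudocount < 0) stop("'pseudocount' must be >= 0", call. = FALSE)
  key <- paste(evidence$geneA, evidence$geneB, sep = "|")
  lab <- integer(length(key))
  lab[key %in% gold@positives] <- 1L
  lab[key %in% gold@negatives] <- -1L
  nPos <- sum(lab == 1L)
  if (nPos == 0L)
    stop(paste("evidence shares no pairs with the gold standard;",
               "this layer cannot be calibrated"), call. = FALSE)
  if (nPos < minPosPerBin)
    stop(sprintf(
      "only %d gold-positive pairs in evidence; need >= minPosPerBin (%d)",
      nPos, minPosPerBin), call. = FALSE)
  keep <- lab != 0L
  s <- evidence$score[keep]
  l <- lab[keep]
  ord <- order(-s)
  s <- s[ord]; l <- l[ord]
  n <- length(s)
  cumPos <- cumsum(l == 1L)
  # candidate cut positions: last index of each tied-score run
  runEnds <- c(which(diff(s) < 0), n)
  cuts <- integer()
  start <- 0L
  for (i in runEnds) {
    if (cumPos[i] - start >= minPosPerBin) {
      cuts <- c(cuts, i)
      start <- cumPos[i]
    }
  }
  if (!length(cuts)) cuts <- n
  if (cuts[length(cuts)] != n) {
    # merge the short tail into the last full bin
    cuts[length(cuts)] <- n
  }
  starts <- c(1L, utils::head(cuts, -1L) + 1L)
  pos <- neg <- integer(length(cuts))
  for (b in seq_along(cuts)) {
    idx <- starts[b]:cuts[b]
    pos[b] <- sum(l[idx] == 1L)
    neg[b] <- sum(l[idx] == -1L)
  }
  # descending-score bins -> edges at midpoints between adjacent runs
  inner <- if (length(cuts) > 1L)
    (s[utils::head(cuts, -1L)] + s[utils::head(cuts, -1L) + 1L]) / 2
  else numeric()
  upper <- c(Inf, inner)
  lower <- c(inner, -Inf)
  po <- priorOdds(gold)
  lls <- log(((pos + pseudocount) / (neg + pseudocount)) / po)
  if (any(!is.finite(lls)))
    stop("non-finite LLS in a zero-count bin; use a positive pseudocount",
         call. = FALSE)
  bins <- data.frame(lower = rev(lower), upper = rev(upper),
                     pos = rev(pos), neg = rev(neg), lls = rev(lls))
  rownames(bins) <- NULL
  new("LLSBinTable", bins = bins, priorOdds = po,
      pseudocount = as.numeric(pseudocount))
}

#' @describeIn fitLLSBins the bin table (lower, upper, pos, neg, lls).
#' @param x an LLSBinTable.
#' @export
setMethod("llsBins", "LLSBinTable", function(x) x@bins)

# Bin index for each raw score (bins ascending; terminal bins are open).
binIndex <- function(table, score) {
  lowers <- table@bins$lower  # lowers[1] == -Inf
  findInterval(score, lowers, rightmost.closed = FALSE)
}

#' Score an evidence layer into a component network
#'
#' Assigns every evidence pair the LLS of the bin containing its raw score
#' (terminal bins are open, so scores beyond the fitted range take the
#' nearest terminal bin's LLS rather than being dropped), then drops pairs
#' with LLS at or below \code{minLLS}.
#'
#' @param evidence data.frame (geneA, geneB, score) of raw pair scores.
#' @param table an [LLSBinTable-class] fitted on the same score dimension.
#' @param minLLS component inclusion cutoff; pairs with
#'   \code{LLS <= minLLS} are removed (default 0 — keep only pairs more
#'   likely co-functional than the prior).
#' @return a [FunctionalNetwork-class] with LLS edge weights.
#' @export
scoreComponent <- function(evidence, table, minLLS = 0) {
  stopifnot(is(table, "LLSBinTable"))
  if (!nrow(evidence))
    return(FunctionalNetwork())
  lls <- table@bins$lls[binIndex(table, evidence$score)]
  keep <- lls > minLLS
  FunctionalNetwork(evidence$geneA[keep], evidence$geneB[keep], lls[keep])
}

setMethod("show", "LLSBinTable", function(object) {
  b <- object@bins
  cat(sprintf("LLSBinTable: %d bins, prior odds %.6g, pseudocount %g\n",
              nrow(b), object@priorOdds, object@pseudocount))
  print(b)
})
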