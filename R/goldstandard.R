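# Gold-standard construction from pathway annotations.

#' Build a co-functional gold standard from annotations
#'
#' Positive pairs are all unordered pairs of distinct genes co-annotated to
#' at least one term; negative pairs are all remaining pairs of annotated
#' genes (genes sharing no term). Together the two sets partition all
#' C(G, 2) pairs of the annotated universe, which fixes the prior odds P/N
#' used in log-likelihood scoring. Apply [filterBroadTerms()] first to keep
#' broad pathway concepts from flooding the positives.
#'
#' Pair sets are materialized as sorted canonical \code{"A|B"} keys, so the
#' construction is deterministic and invariant to term order and to gene
#' order within terms.
#'
#' @param ann a [PathwayAnnotation-class] with at least two annotated genes.
#' @return a [GoldStandard-class].
#' @examples
#' ann <- PathwayAnnotation(list(T1 = c("a", "b", "c"), T2 = c("c", "d")))
#' gold <- buildGoldStandard(ann)
#' length(positivePairs(gold))  # ab, ac, bc, cd
#' @export
buildGoldStandard <- function(ann) {
  stopifnot(is(ann, "PathwayAnnotation"))
  univ <- annotatedGenes(ann)
  if (length(univ) < 2L)
    stop("gold standard undefined: fewer than two annotated genes", call. = FALSE)
  pos <- unlist(lapply(ann@terms, function(g) {
    if (length(g) < 2L) return(character())
    m <- utils::combn(g, 2L)  # g already sorted, so pairs are canonical
    paste(m[1L, ], m[2L, ], sep = "|")
  }), use.names = FALSE)
  pos <- sort(unique(pos))
  allPairs <- allPairKeys(univ)
  neg <- allPairs[!(allPairs %in% pos)]
  new("GoldStandard", positives = pos, negatives = neg,
      sourceTerms = termNames(ann))
}

# All C(n,2) canonical pair keys of a sorted gene vector, in canonical-pair
# lexicographic order.
allPairKeys <- function(genes) {
  genes <- sort(unique(genes))
  n <- length(genes)
  if (n < 2L) return(character())
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  sort(paste(genes[i], genes[j], sep = "|"))
}

#' @describeIn buildGoldStandard sorted positive pair keys.
#' @param x a GoldStandard.
#' @export
setMethod("positivePairs", "GoldStandard", function(x) x@positives)

#' @describeIn buildGoldStandard sorted negative pair keys.
#' @export
setMethod("negativePairs", "GoldStandard", function(x) x@negatives)

#' Prior odds of co-functionality
#'
#' The ratio of positive to negative gold-standard pairs, \eqn{P/N}: the
#' odds that a random pair of annotated genes is co-functional before any
#' evidence is seen. The denominator of every log-likelihood score.
#'
#' @param x a [GoldStandard-class], or the positive pair count as a number.
#' @param nNegative negative pair count, when \code{x} is given as a count.
#' @return a single positive number.
#' @examples
#' priorOdds(591664, 58416152)
#' @export
setMethod("priorOdds", "GoldStandard", function(x, ...) {
  if (length(x@negatives) == 0L)
    stop("prior odds undefined: no negative pairs", call. = FALSE)
  if (length(x@positives) == 0L)
    stop("prior odds undefined: no positive pairs", call. = FALSE)
  length(x@positives) / length(x@negatives)
})

#' @rdname priorOdds
#' @export
setMethod("priorOdds", "numeric", function(x, nNegative, ...) {
  if (length(x) != 1L || length(nNegative) != 1L || x <= 0 || nNegative <= 0)
    stop("both pair counts must be single positive numbers", call. = FALSE)
  x / nNegative
})

#' Fraction of pair set A found in pair set B
#'
#' \eqn{|A \cap B| / |A|}; used to report training/validation overlap of
#' positive pair sets.
#'
#' @param a non-empty character vector of canonical pair keys.
#' @param b character vector of canonical pair keys.
#' @return a fraction in [0, 1].
#' @export
pairOverlapFraction <- function(a, b) {
  if (!length(a)) stop("overlap fraction undefined for an empty set", call. = FALSE)
  a <- unique(a)
  length(intersect(a, b)) / length(a)
}

setMethod("show", "GoldStandard", function(object) {
  cat(sprintf("GoldStandard: %d positive, %d negative pairs (%d source terms)\n",
              length(object@positives), length(object@negatives),
              length(object@sourceTerms)))
  if (length(object@positives) && length(object@negatives))
    cat(sprintf("  prior odds P/N = %.6g\n", priorOdds(object)))
})
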