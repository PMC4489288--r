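# S4 classes for the toolkit's central objects.

#' FunctionalNetwork: an undirected weighted gene network
#'
#' Stores co-functional links as a canonical edge table: one row per
#' unordered gene pair, endpoints in lexicographic order
#' (\code{geneA < geneB}), no self-loops, no duplicate pairs, all scores
#' finite. Scores are dimensionless edge weights — per-evidence
#' log-likelihood scores (LLS) or integrated weighted-sum (WS) scores; the
#' class treats the unit as opaque.
#'
#' @slot edges data.frame with columns \code{geneA}, \code{geneB}
#'   (character, canonical order) and \code{score} (numeric, finite), sorted
#'   by \code{(geneA, geneB)}.
#'
#' @seealso [FunctionalNetwork()], [readEdgeList()], [neighbors()],
#'   [topLinks()]
#' @export
setClass("FunctionalNetwork", slots = c(edges = "data.frame"))

setValidity("FunctionalNetwork", function(object) {
  e <- object@edges
  req <- c("geneA", "geneB", "score")
  if (!all(req %in% names(e)))
    return("edges must have columns geneA, geneB, score")
  if (nrow(e) == 0L) return(TRUE)
  if (!is.character(e$geneA) || !is.character(e$geneB))
    return("gene columns must be character")
  if (!is.numeric(e$score) || any(!is.finite(e$score)))
    return("all edge scores must be finite numbers")
  if (any(e$geneA == e$geneB))
    return("self-loops are not allowed")
  if (any(e$geneA > e$geneB))
    return("pairs must be in canonical (lexicographic) endpoint order")
  if (anyDuplicated(paste(e$geneA, e$geneB, sep = "|")))
    return("duplicate gene pairs are not allowed")
  TRUE
})

#' PathwayAnnotation: flat term-to-gene annotations
#'
#' A set of pathway/process terms, each annotating one or more genes, as
#' read from a GMT file. Terms are flat gene sets; no ontology-graph
#' propagation is performed.
#'
#' @slot terms named list; each element a character vector of normalized,
#'   deduplicated gene ids (sorted), names are term ids.
#' @slot descriptions named character vector parallel to \code{terms}.
#'
#' @seealso [PathwayAnnotation()], [readGmt()], [buildGoldStandard()]
#' @export
setClass("PathwayAnnotation",
         slots = c(terms = "list", descriptions = "character"))

setValidity("PathwayAnnotation", function(object) {
  tl <- object@terms
  if (length(tl) == 0L) return(TRUE)
  nm <- names(tl)
  if (is.null(nm) || any(!nzchar(nm))) return("every term needs a non-empty id")
  if (anyDuplicated(nm)) return("term ids must be unique")
  if (!all(vapply(tl, function(g) is.character(g) && length(g) >= 1L, logical(1L))))
    return("every term must annotate at least one gene")
  if (!identical(sort(nm), sort(names(object@descriptions))))
    return("descriptions must be named parallel to terms")
  TRUE
})

#' GoldStandard: positive and negative co-functional gene pairs
#'
#' Positive pairs share at least one annotation term; negative pairs are
#' pairs of annotated genes sharing no term. The two sets are disjoint and
#' together define the prior odds used for log-likelihood scoring.
#' Pairs are stored as canonical \code{"A|B"} keys in sorted order.
#'
#' @slot positives sorted character vector of pair keys.
#' @slot negatives sorted character vector of pair keys.
#' @slot sourceTerms character vector of the term ids the standard was built
#'   from.
#'
#' @seealso [buildGoldStandard()], [priorOdds()], [fitLLSBins()]
#' @export
setClass("GoldStandard",
         slots = c(positives = "character", negatives = "character",
                   sourceTerms = "character"))

setValidity("GoldStandard", function(object) {
  if (length(intersect(object@positives, object@negatives)))
    return("positive and negative pair sets must be disjoint")
  if (anyDuplicated(object@positives) || anyDuplicated(object@negatives))
    return("pair sets must not contain duplicates")
  TRUE
})

#' LLSBinTable: binned log-likelihood calibration of an evidence layer
#'
#' Contiguous raw-score bins, each carrying gold-standard positive/negative
#' counts and the resulting log-likelihood score
#' \eqn{LLS = \ln\frac{(pos + c)/(neg + c)}{P/N}} where \eqn{P/N} is the
#' prior odds and \eqn{c} a pseudocount. Bins are stored in ascending raw
#' score order; the terminal bins extend to \eqn{\pm\infty} so every raw
#' score maps to a bin.
#'
#' @slot bins data.frame with columns \code{lower}, \code{upper},
#'   \code{pos}, \code{neg}, \code{lls}; \code{lower} strictly increasing,
#'   intervals contiguous (\code{upper[i] == lower[i+1]}).
#' @slot priorOdds single positive number, \eqn{P/N} of the gold standard.
#' @slot pseudocount single non-negative number.
#'
#' @seealso [fitLLSBins()], [scoreComponent()]
#' @export
setClass("LLSBinTable",
         slots = c(bins = "data.frame", priorOdds = "numeric",
                   pseudocount = "numeric"))

setValidity("LLSBinTable", function(object) {
  b <- object@bins
  req <- c("lower", "upper", "pos", "neg", "lls")
  if (!all(req %in% names(b))) return("bins need columns lower, upper, pos, neg, lls")
  if (nrow(b) == 0L) return("at least one bin required")
  if (any(b$upper <= b$lower)) return("each bin must have lower < upper")
  if (nrow(b) > 1L) {
    if (any(diff(b$lower) <= 0)) return("bin lower edges must be strictly increasing")
    if (any(abs(utils::head(b$upper, -1L) - b$lower[-1L]) > 0))
      return("bins must be contiguous")
  }
  if (any(b$pos < 0) || any(b$neg < 0)) return("counts must be non-negative")
  if (any(!is.finite(b$lls))) return("LLS values must be finite (use a pseudocount)")
  if (length(object@priorOdds) != 1L || !is.finite(object@priorOdds) ||
      object@priorOdds <= 0)
    return("priorOdds must be a single positive number")
  TRUE
})

#' RankedCandidates: output of direct-neighborhood gene prioritization
#'
#' An ordered candidate table with dense ranks (equal scores share a rank).
#' Guide genes never appear as candidates. The full ranking is retained;
#' [candidates()] returns the top-n slice by default.
#'
#' @slot table data.frame with columns \code{rank}, \code{gene},
#'   \code{score} (plus \code{paralogs} after [annotateParalogs()]); scores
#'   non-increasing.
#' @slot topN integer, the requested truncation length.
#' @slot guidesUsed character, guide genes found in the network.
#' @slot guidesUnmapped character, guide genes absent from the network.
#' @slot tieAtCut logical, TRUE when a score tie straddles the top-n cut.
#'
#' @seealso [neighborhoodRank()], [candidates()], [annotateParalogs()]
#' @export
setClass("RankedCandidates",
         slots = c(table = "data.frame", topN = "integer",
                   guidesUsed = "character", guidesUnmapped = "character",
                   tieAtCut = "logical"))

setValidity("RankedCandidates", function(object) {
  tb <- object@table
  if (!all(c("rank", "gene", "score") %in% names(tb)))
    return("table needs columns rank, gene, score")
  if (nrow(tb) > 1L && any(diff(tb$score) > 0))
    return("scores must be non-increasing down the ranking")
  if (length(intersect(tb$gene, object@guidesUsed)))
    return("guide genes must not appear as candidates")
  TRUE
})
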