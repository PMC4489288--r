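# Reciprocal-best-hit orthology mapping and guide-gene translation.

#' Best hit per query
#'
#' Per query: the hit with the smallest E-value; E-value ties resolve to
#' the larger bit score, remaining ties to the lexicographically smallest
#' target — a deterministic chain.
#'
#' @param hits data.frame with columns query, target, evalue, bitscore
#'   (as from [readBlastHits()]).
#' @return data.frame with one row per query.
#' @export
bestHitPerQuery <- function(hits) {
  if (!nrow(hits)) return(hits)
  hits$query <- normalizeGeneId(hits$query)
  hits$target <- normalizeGeneId(hits$target)
  ord <- order(hits$query, hits$evalue, -hits$bitscore, hits$target)
  h <- hits[ord, , drop = FALSE]
  h <- h[!duplicated(h$query), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Reciprocal best hits between two gene namespaces
#'
#' A pair (a, b) is kept iff b is a's best hit in the A-to-B table, a is
#' b's best hit in the B-to-A table, and both directional hits satisfy
#' \code{evalue <= eCutoff}. The strict default cutoff of 1e-4 in both
#' directions suits closely related genomes where spurious orthology must
#' be avoided. The output is a bijection on its support (asserted on every
#' run) and anti-monotone in the cutoff: lowering \code{eCutoff} never adds
#' pairs.
#'
#' @param ab hits from namespace A to B (data.frame: query, target, evalue,
#'   bitscore).
#' @param ba hits from B to A.
#' @param eCutoff E-value threshold applied to both directions
#'   (default 1e-4).
#' @return data.frame (source, target, evalueForward, evalueReverse),
#'   sorted by source; zero rows when the inputs are empty.
#' @export
reciprocalBestHits <- function(ab, ba, eCutoff = 1e-4) {
  if (!is.numeric(eCutoff) || length(eCutoff) != 1L || eCutoff <= 0)
    stop("'eCutoff' must be a single positive number", call. = FALSE)
  empty <- data.frame(source = character(), target = character(),
                      evalueForward = numeric(), evalueReverse = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(ab) || !nrow(ba)) return(empty)
  bestAB <- bestHitPerQuery(ab)
  bestBA <- bestHitPerQuery(ba)
  back <- match(bestAB$target, bestBA$query)
  ok <- !is.na(back) &
    bestBA$target[back] == bestAB$query &
    bestAB$evalue <= eCutoff &
    bestBA$evalue[back] <= eCutoff
  out <- data.frame(source = bestAB$query[ok],
                    target = bestAB$target[ok],
                    evalueForward = bestAB$evalue[ok],
                    evalueReverse = bestBA$evalue[back[ok]],
                    stringsAsFactors = FALSE)
  out <- out[order(out$source), , drop = FALSE]
  rownames(out) <- NULL
  if (anyDuplicated(out$source) || anyDuplicated(out$target))
    stop("internal error: reciprocal best hits are not a bijection")
  out
}

#' Translate guide genes across namespaces
#'
#' Maps a guide gene set through an orthology table into the network's
#' namespace. In \code{"one2one"} mode the table must be a bijection (as
#' produced by [reciprocalBestHits()]); \code{"many"} mode accepts
#' externally supplied one-to-many tables (e.g. inparalog-inclusive
#' mappings for a more distant reference species). Mapped targets are
#' deduplicated; the provenance records which source guide produced each
#' target.
#'
#' @param guides character vector of guide gene ids in the source
#'   namespace.
#' @param table data.frame with columns source, target (e.g. from
#'   [reciprocalBestHits()]).
#' @param mode \code{"one2one"} (default) or \code{"many"}.
#' @return list with \code{mapped} (sorted unique target ids),
#'   \code{unmapped} (guides without a table entry) and \code{provenance}
#'   (data.frame source, target).
#' @export
translateGuides <- function(guides, table, mode = c("one2one", "many")) {
  mode <- match.arg(mode)
  guides <- unique(normalizeGeneId(guides))
  src <- normalizeGeneId(table$source)
  tgt <- normalizeGeneId(table$target)
  if (mode == "one2one" && anyDuplicated(src))
    stop("orthology table is not one-to-one; use mode = 'many'", call. = FALSE)
  hit <- src %in% guides
  prov <- data.frame(source = src[hit], target = tgt[hit],
                     stringsAsFactors = FALSE)
  prov <- prov[order(prov$source, prov$target), , drop = FALSE]
  rownames(prov) <- NULL
  unmapped <- setdiff(guides, src)
  if (!nrow(prov))
    stop(sprintf("no guide gene maps through the orthology table (unmapped: %s)",
                 paste(unmapped, collapse = ", ")), call. = FALSE)
  list(mapped = sort(unique(prov$target)), unmapped = unmapped,
       provenance = prov)
}
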