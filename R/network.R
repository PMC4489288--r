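# Construction and accessors for FunctionalNetwork.

#' Construct a functional network from endpoint/score vectors
#'
#' Pairs are normalized and canonicalized; a pair repeated in either
#' orientation is an error under \code{dedup = "error"} (the default —
#' silent merging hides upstream bugs) or merged keeping the larger score
#' under \code{dedup = "max"}.
#'
#' @param geneA,geneB character vectors of endpoints.
#' @param score numeric vector of finite edge scores.
#' @param dedup duplicate-pair policy, \code{"error"} or \code{"max"}.
#' @return a [FunctionalNetwork-class] object.
#' @examples
#' net <- FunctionalNetwork(c("g1", "g2"), c("g2", "g3"), c(1.5, 0.7))
#' numEdges(net)
#' @export
FunctionalNetwork <- function(geneA = character(), geneB = character(),
                              score = numeric(), dedup = c("error", "max")) {
  dedup <- match.arg(dedup)
  if (length(geneA) != length(geneB) || length(geneA) != length(score))
    stop("geneA, geneB and score must have equal length", call. = FALSE)
  if (length(score) && any(!is.finite(score)))
    stop("all edge scores must be finite", call. = FALSE)
  if (length(geneA) == 0L) {
    return(new("FunctionalNetwork",
               edges = data.frame(geneA = character(), geneB = character(),
                                  score = numeric(), stringsAsFactors = FALSE)))
  }
  a <- normalizeGeneId(geneA)
  b <- normalizeGeneId(geneB)
  if (any(a == b)) {
    bad <- a[a == b][1L]
    stop(sprintf("self-loop on gene '%s' is not a valid link", bad), call. = FALSE)
  }
  ga <- pmin(a, b)
  gb <- pmax(a, b)
  key <- paste(ga, gb, sep = "|")
  if (anyDuplicated(key)) {
    if (dedup == "error") {
      bad <- key[duplicated(key)][1L]
      stop(sprintf("duplicate gene pair '%s' (dedup policy 'error')",
                   sub("\\|", " - ", bad)), call. = FALSE)
    }
    score <- vapply(split(score, key), max, numeric(1L))
    ga <- vapply(split(ga, key), `[`, character(1L), 1L)
    gb <- vapply(split(gb, key), `[`, character(1L), 1L)
  }
  e <- data.frame(geneA = ga, geneB = gb, score = as.numeric(score),
                  stringsAsFactors = FALSE)
  e <- e[order(e$geneA, e$geneB), , drop = FALSE]
  rownames(e) <- NULL
  new("FunctionalNetwork", edges = e)
}

#' @describeIn FunctionalNetwork edge table (geneA, geneB, score).
#' @param x a FunctionalNetwork.
#' @export
setMethod("edges", "FunctionalNetwork", function(x, ...) x@edges)

#' @describeIn FunctionalNetwork sorted node set (union of endpoints).
#' @export
setMethod("genes", "FunctionalNetwork", function(x, ...) {
  sort(unique(c(x@edges$geneA, x@edges$geneB)))
})

#' @describeIn FunctionalNetwork number of links.
#' @export
setMethod("numEdges", "FunctionalNetwork", function(x) nrow(x@edges))

#' @describeIn FunctionalNetwork canonical "A|B" keys of all edges.
#' @export
setMethod("pairKeys", "FunctionalNetwork", function(x, ...) {
  paste(x@edges$geneA, x@edges$geneB, sep = "|")
})

#' @describeIn FunctionalNetwork named integer vector of node degrees.
#' @export
setMethod("degree", "FunctionalNetwork", function(x, ...) {
  ends <- c(x@edges$geneA, x@edges$geneB)
  if (!length(ends)) return(setNames(integer(), character()))
  tab <- table(ends)
  d <- setNames(as.integer(tab), names(tab))
  d[order(names(d))]
})

#' Direct neighborhood of a gene
#'
#' All genes sharing an edge with \code{gene}, with edge scores. A gene
#' absent from the network has an empty neighborhood; a gene is never its
#' own neighbor.
#'
#' @param x a [FunctionalNetwork-class].
#' @param gene a single gene id.
#' @return named numeric vector: neighbor id -> edge score.
#' @export
setMethod("neighbors", "FunctionalNetwork", function(x, gene, ...) {
  gene <- normalizeGeneId(gene)
  if (length(gene) != 1L) stop("'gene' must be a single id", call. = FALSE)
  e <- x@edges
  ia <- e$geneA == gene
  ib <- e$geneB == gene
  out <- c(setNames(e$score[ia], e$geneB[ia]),
           setNames(e$score[ib], e$geneA[ib]))
  if (!length(out)) return(setNames(numeric(), character()))
  out[order(names(out))]
})

#' Highest-scoring subnetwork
#'
#' The k top-scoring links; ties at the cut are broken by canonical pair
#' lexicographic order so the result is deterministic. Used to match network
#' sizes when comparing networks of different total link counts.
#'
#' @param x a [FunctionalNetwork-class].
#' @param k number of links to keep; \code{k >= numEdges(x)} returns the
#'   whole network.
#' @return a [FunctionalNetwork-class] with \code{min(k, numEdges(x))} links.
#' @export
setMethod("topLinks", "FunctionalNetwork", function(x, k) {
  k <- assertCount(k, "k")
  e <- x@edges
  ord <- order(-e$score, e$geneA, e$geneB)
  keep <- utils::head(ord, k)
  e <- e[keep, , drop = FALSE]
  FunctionalNetwork(e$geneA, e$geneB, e$score)
})

#' Genes exceeding a degree threshold
#'
#' Hub selection: genes with more than \code{d} connected neighbors
#' (\code{strict = TRUE}, the default, reads the threshold as a strict
#' inequality) or at least \code{d} (\code{strict = FALSE}).
#'
#' @param x a [FunctionalNetwork-class].
#' @param d degree threshold (default 50).
#' @param strict require degree strictly greater than \code{d} (default).
#' @return sorted character vector of gene ids.
#' @export
setMethod("genesWithMinNeighbors", "FunctionalNetwork",
          function(x, d = 50, strict = TRUE) {
  d <- assertCount(d, "d")
  deg <- degree(x)
  if (strict) names(deg)[deg > d] else names(deg)[deg >= d]
})

setMethod("show", "FunctionalNetwork", function(object) {
  e <- object@edges
  ng <- length(unique(c(e$geneA, e$geneB)))
  cat(sprintf("FunctionalNetwork: %d genes, %d links\n", ng, nrow(e)))
  if (nrow(e)) {
    cat(sprintf("  score range: [%g, %g]\n", min(e$score), max(e$score)))
    print(utils::head(e, 3L))
    if (nrow(e) > 3L) cat(sprintf("  ... %d more links\n", nrow(e) - 3L))
  }
})
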