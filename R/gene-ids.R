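#' Normalize gene identifiers
#'
#' Gene identifiers are compared case-insensitively throughout the package:
#' every identifier is trimmed of surrounding whitespace and upper-cased on
#' entry, so \code{"loc_os01g01010"} and \code{"LOC_Os01g01010"} denote the
#' same gene. Empty tokens and tokens containing internal whitespace are
#' rejected.
#'
#' @param x character vector of raw identifiers.
#' @return character vector of normalized identifiers, same length as \code{x}.
#' @examples
#' normalizeGeneId(c(" loc_os01g01010 ", "LOC_Os01g01010"))
#' @export
normalizeGeneId <- function(x) {
  x <- toupper(trimws(as.character(x)))
  if (length(x) && any(!nzchar(x)))
    stop("empty gene identifier after normalization", call. = FALSE)
  if (length(x) && any(grepl("[[:space:]]", x)))
    stop("gene identifiers must not contain whitespace", call. = FALSE)
  x
}

#' Canonical unordered gene pair
#'
#' An undirected co-functional link is stored once, with its endpoints in
#' lexicographic order, so \code{(a, b)} and \code{(b, a)} map to the same
#' pair. Self-pairs are invalid links and raise an error.
#'
#' @param a,b single gene identifiers (normalized internally).
#' @return character vector of length 2: the two endpoints in canonical
#'   (lexicographic) order.
#' @examples
#' canonicalPair("g2", "g1")
#' @seealso [canonicalPairKeys()] for the vectorized key form.
#' @export
canonicalPair <- function(a, b) {
  a <- normalizeGeneId(a)
  b <- normalizeGeneId(b)
  if (length(a) != 1L || length(b) != 1L)
    stop("'a' and 'b' must be single identifiers", call. = FALSE)
  if (a == b)
    stop(sprintf("invalid link: self-pair ('%s','%s')", a, b), call. = FALSE)
  if (a < b) c(a, b) else c(b, a)
}

#' Canonical pair keys
#'
#' Vectorized encoding of unordered gene pairs as single strings
#' \code{"A|B"} with \code{A < B}. Used as the set element for gold-standard
#' positive/negative pair sets and for joining evidence tables to networks.
#'
#' @param a,b character vectors of gene identifiers (recycled pairwise).
#' @return character vector of pair keys.
#' @export
canonicalPairKeys <- function(a, b) {
  a <- normalizeGeneId(a)
  b <- normalizeGeneId(b)
  if (any(a == b)) {
    bad <- a[a == b][1L]
    stop(sprintf("invalid link: self-pair ('%s','%s')", bad, bad), call. = FALSE)
  }
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Split pair keys back into endpoints
#'
#' @param keys character vector of \code{"A|B"} pair keys.
#' @return data.frame with columns \code{geneA}, \code{geneB}.
#' @export
splitPairKeys <- function(keys) {
  parts <- strsplit(keys, "|", fixed = TRUE)
  data.frame(
    geneA = vapply(parts, `[`, character(1L), 1L),
    geneB = vapply(parts, `[`, character(1L), 2L),
    stringsAsFactors = FALSE
  )
}

#' Genome coverage percentage
#'
#' Fraction of an annotated coding genome covered by a network's node set,
#' as a percentage rounded to \code{digits} decimals (e.g. 25765 network
#' genes out of a 36736-gene coding genome is 70.1).
#'
#' @param nNetworkGenes number of genes in the network.
#' @param nGenomeGenes number of protein-coding genes in the genome.
#' @param digits decimals to round to (default 1).
#' @return a single number, percentage of the genome present in the network.
#' @examples
#' genomeCoverage(25765, 36736)
#' @export
genomeCoverage <- function(nNetworkGenes, nGenomeGenes, digits = 1) {
  nNetworkGenes <- assertCount(nNetworkGenes, "nNetworkGenes")
  nGenomeGenes <- assertCount(nGenomeGenes, "nGenomeGenes", min = 1)
  round(100 * nNetworkGenes / nGenomeGenes, digits)
}
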