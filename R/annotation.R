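# PathwayAnnotation construction and term filtering.

#' Construct a pathway annotation from a list of gene sets
#'
#' @param terms named list of character vectors (term id -> gene ids).
#' @param descriptions optional named character vector of term descriptions;
#'   defaults to empty strings.
#' @return a [PathwayAnnotation-class] object; genes are normalized,
#'   deduplicated and sorted within each term.
#' @examples
#' ann <- PathwayAnnotation(list(T1 = c("a", "b", "c"), T2 = c("c", "d")))
#' termSizes(ann)
#' @export
PathwayAnnotation <- function(terms = list(), descriptions = NULL) {
  if (length(terms)) {
    terms <- lapply(terms, function(g) sort(unique(normalizeGeneId(g))))
  }
  nm <- names(terms)
  if (is.null(descriptions)) descriptions <- setNames(rep("", length(terms)), nm)
  descriptions <- descriptions[nm]
  names(descriptions) <- nm
  descriptions[is.na(descriptions)] <- ""
  new("PathwayAnnotation", terms = terms, descriptions = descriptions)
}

#' @describeIn PathwayAnnotation term ids.
#' @param x a PathwayAnnotation.
#' @export
setMethod("termNames", "PathwayAnnotation", function(x) names(x@terms))

#' @describeIn PathwayAnnotation genes annotated to one term.
#' @param term a single term id.
#' @export
setMethod("termGenes", "PathwayAnnotation", function(x, term) {
  if (!term %in% names(x@terms))
    stop(sprintf("unknown term '%s'", term), call. = FALSE)
  x@terms[[term]]
})

#' @describeIn PathwayAnnotation named integer vector of term sizes.
#' @export
setMethod("termSizes", "PathwayAnnotation", function(x) {
  vapply(x@terms, length, integer(1L))
})

#' @describeIn PathwayAnnotation named character vector of descriptions.
#' @export
setMethod("termDescriptions", "PathwayAnnotation", function(x) x@descriptions)

#' @describeIn PathwayAnnotation sorted union of all annotated genes.
#' @export
setMethod("annotatedGenes", "PathwayAnnotation", function(x) {
  sort(unique(unlist(x@terms, use.names = FALSE)))
})

#' Remove the n largest terms
#'
#' Removes the \code{n} terms annotating the most genes, a validation-time
#' guard against assessment being dominated by a few huge generic terms.
#' Size ties are broken by lexicographic term id (the earlier id is removed
#' first). Genes annotated only by removed terms leave the annotated
#' universe. \code{n} larger than the number of terms yields an empty map.
#'
#' @param x a [PathwayAnnotation-class].
#' @param n number of terms to drop.
#' @return a [PathwayAnnotation-class].
#' @export
setMethod("dropLargestTerms", "PathwayAnnotation", function(x, n) {
  n <- assertCount(n, "n")
  if (n == 0L || length(x@terms) == 0L) return(x)
  sz <- termSizes(x)
  ord <- order(-sz, names(sz))
  drop <- utils::head(names(sz)[ord], n)
  keep <- setdiff(names(x@terms), drop)
  PathwayAnnotation(x@terms[keep], x@descriptions[keep])
})

#' Remove broad terms by size cap
#'
#' Terms annotating more than \code{maxSize} genes are removed before
#' gold-standard construction: broad pathway concepts generate excessive
#' numbers of co-annotated pairs and bias training. The cap is a
#' configuration knob, not a fixed rule.
#'
#' @param x a [PathwayAnnotation-class].
#' @param maxSize maximum allowed term size (>= 2).
#' @return a [PathwayAnnotation-class].
#' @export
setMethod("filterBroadTerms", "PathwayAnnotation", function(x, maxSize) {
  maxSize <- assertCount(maxSize, "maxSize", min = 2)
  keep <- names(x@terms)[termSizes(x) <= maxSize]
  PathwayAnnotation(x@terms[keep], x@descriptions[keep])
})

setMethod("show", "PathwayAnnotation", function(object) {
  sz <- termSizes(object)
  cat(sprintf("PathwayAnnotation: %d terms, %d annotated genes\n",
              length(sz), length(annotatedGenes(object))))
  if (length(sz))
    cat(sprintf("  term sizes: min %d, median %g, max %d\n",
                min(sz), stats::median(sz), max(sz)))
})
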