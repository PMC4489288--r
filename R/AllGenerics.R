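# Generics for the S4 surface. Methods live next to their classes.

#' @export
setGeneric("edges", function(x, ...) standardGeneric("edges"))

#' @export
setGeneric("genes", function(x, ...) standardGeneric("genes"))

#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @export
setGeneric("degree", function(x, ...) standardGeneric("degree"))

#' @export
setGeneric("neighbors", function(x, gene, ...) standardGeneric("neighbors"))

#' @export
setGeneric("topLinks", function(x, k) standardGeneric("topLinks"))

#' @export
setGeneric("genesWithMinNeighbors",
           function(x, d = 50, strict = TRUE) standardGeneric("genesWithMinNeighbors"))

#' @export
setGeneric("pairKeys", function(x, ...) standardGeneric("pairKeys"))

#' @export
setGeneric("termNames", function(x) standardGeneric("termNames"))

#' @export
setGeneric("termGenes", function(x, term) standardGeneric("termGenes"))

#' @export
setGeneric("termSizes", function(x) standardGeneric("termSizes"))

#' @export
setGeneric("termDescriptions", function(x) standardGeneric("termDescriptions"))

#' @export
setGeneric("annotatedGenes", function(x) standardGeneric("annotatedGenes"))

#' @export
setGeneric("dropLargestTerms", function(x, n) standardGeneric("dropLargestTerms"))

#' @export
setGeneric("filterBroadTerms", function(x, maxSize) standardGeneric("filterBroadTerms"))

#' @export
setGeneric("positivePairs", function(x) standardGeneric("positivePairs"))

#' @export
setGeneric("negativePairs", function(x) standardGeneric("negativePairs"))

#' @export
setGeneric("priorOdds", function(x, ...) standardGeneric("priorOdds"))

#' @export
setGeneric("llsBins", function(x) standardGeneric("llsBins"))

#' @export
setGeneric("candidates", function(x, ...) standardGeneric("candidates"))
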