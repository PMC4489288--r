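# Weighted-sum integration of LLS component networks.

#' Weighted sum of evidence log-likelihood scores
#'
#' Integration score of one gene pair across evidence layers:
#' \deqn{WS = L_0 + \sum_{i=1}^{n-1} \frac{L_i}{D \cdot i}}
#' where \eqn{L_0 \ge L_1 \ge \dots} are the pair's per-evidence LLS values
#' in descending order and \eqn{D \ge 1} is a degradation constant
#' down-weighting lower-ranked evidence (D = 1 sums freely; large D
#' approaches the single best evidence). Values are sorted internally with
#' a stable sort, so ties keep their input (component) order.
#'
#' @param lls numeric vector of per-evidence LLS values (at least one).
#' @param D degradation constant, \code{>= 1}.
#' @return a single number, \code{>= max(lls)} whenever the remaining
#'   values are positive.
#' @examples
#' weightedSum(c(2, 1), D = 1)  # 3
#' weightedSum(c(2, 1), D = 2)  # 2.5
#' @export
weightedSum <- function(lls, D = 1) {
  if (!length(lls)) stop("weighted sum of no evidence is undefined", call. = FALSE)
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D < 1)
    stop("'D' must be a single number >= 1", call. = FALSE)
  if (any(!is.finite(lls))) stop("LLS values must be finite", call. = FALSE)
  l <- lls[order(-lls)]  # radix order is stable: ties keep input order
  n <- length(l)
  if (n == 1L) return(l[1L])
  l[1L] + sum(l[-1L] / (D * seq_len(n - 1L)))
}

#' Integrate component networks by the weighted-sum method
#'
#' For every pair present in at least one component, collects its
#' per-component LLS values, sorts them descending (ties by component input
#' order) and applies [weightedSum()]. The result is invariant under
#' permutation of the component list. Optionally truncated to the
#' \code{maxLinks} highest-scoring links via [topLinks()].
#'
#' @param components list of [FunctionalNetwork-class] objects (LLS-scored
#'   evidence layers).
#' @param D degradation constant (default 1; see [selectD()]).
#' @param maxLinks optional final size cap.
#' @return a [FunctionalNetwork-class] with WS edge scores.
#' @export
integrateNetworks <- function(components, D = 1, maxLinks = NULL) {
  if (!length(components)) stop("need at least one component", call. = FALSE)
  stopifnot(all(vapply(components, is, logical(1L), "FunctionalNetwork")))
  key <- unlist(lapply(components, pairKeys), use.names = FALSE)
  score <- unlist(lapply(components, function(x) edges(x)$score),
                  use.names = FALSE)
  comp <- rep.int(seq_along(components),
                  vapply(components, numEdges, integer(1L)))
  if (!length(key)) return(FunctionalNetwork())
  ord <- order(key, -score, comp)
  key <- key[ord]; score <- score[ord]
  runs <- rle(key)
  n <- runs$lengths
  # rank of each value within its pair (0-based): 0 for L0, i for Li
  i <- sequence(n) - 1L
  contrib <- ifelse(i == 0L, score, score / (D * i))
  ws <- rowsum(contrib, group = key, reorder = TRUE)
  keys <- rownames(ws)
  d <- splitPairKeys(keys)
  net <- FunctionalNetwork(d$geneA, d$geneB, as.numeric(ws))
  if (!is.null(maxLinks)) net <- topLinks(net, maxLinks)
  net
}

# Area under the odds-ratio-vs-recall curve, computed with a finite
# continuity correction so early infinite ORs do not dominate.
orCurveArea <- function(net, gold, correction = 0.5) {
  pr <- prCurve(net, gold, correction = correction)
  trapezoidArea(pr$recall, pr$oddsRatio)
}

#' Select the weighted-sum degradation constant on held-out pairs
#'
#' Grid search: integrates the components at each candidate \code{D} and
#' keeps the value maximizing the area under the odds-ratio-vs-recall curve
#' against a held-out gold standard. Ties (within a small numeric
#' tolerance) resolve toward the smaller \code{D}.
#'
#' @param components list of [FunctionalNetwork-class] components.
#' @param goldValidation a held-out [GoldStandard-class].
#' @param grid numeric vector of candidate D values (all \code{>= 1}).
#' @return the selected D (a single number from \code{grid}).
#' @export
selectD <- function(components, goldValidation, grid = c(1, 1.5, 2, 3, 4)) {
  if (!length(grid)) stop("'grid' must be non-empty", call. = FALSE)
  grid <- sort(as.numeric(grid))
  if (length(grid) == 1L) return(grid)
  areas <- vapply(grid, function(D) {
    orCurveArea(integrateNetworks(components, D = D), goldValidation)
  }, numeric(1L))
  best <- max(areas)
  grid[which(areas >= best - 1e-12)[1L]]
}
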