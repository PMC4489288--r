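# Seeded synthetic-data generators with planted ground truth. Every
# generator is a pure function of its parameters and an explicit seed
# (same seed => identical output); seeds are never defaulted.

#' Planted-module (stochastic block) network
#'
#' Genes are split into \code{m} modules (remainder genes go to the last
#' module). Within-module pairs are linked with probability \code{pIn} and
#' weights drawn from \code{wIn}; between-module pairs with \code{pOut} and
#' \code{wOut}. Requires \code{pIn > pOut} so the planted structure is
#' recoverable. Stand-in for a functional network with known pathway
#' modules.
#'
#' @param n number of genes.
#' @param m number of modules.
#' @param pIn,pOut within-/between-module link probabilities,
#'   \code{pIn > pOut}.
#' @param wIn,wOut weight samplers, functions of a count returning that
#'   many positive weights. Defaults: within-module weights uniform on
#'   [1, 2], between-module uniform on [0.25, 1].
#' @param seed required integer seed.
#' @return list with \code{network} (a [FunctionalNetwork-class]) and
#'   \code{truth} (module assignment, parameters, seed).
#' @export
plantedModuleNetwork <- function(n, m, pIn, pOut,
                                 wIn = function(k) stats::runif(k, 1, 2),
                                 wOut = function(k) stats::runif(k, 0.25, 1),
                                 seed) {
  n <- assertCount(n, "n", min = 2)
  m <- assertCount(m, "m", min = 1)
  pIn <- assertProb(pIn, "pIn")
  pOut <- assertProb(pOut, "pOut")
  if (pIn <= pOut)
    stop("'pIn' must exceed 'pOut' (the planted structure must be informative)",
         call. = FALSE)
  geneIds <- sprintf("G%0*d", max(4L, nchar(n)), seq_len(n))
  base <- n %/% m
  mod <- rep(seq_len(m), times = c(rep(base, m - 1L), n - base * (m - 1L)))
  ij <- pairIndices(n)
  same <- mod[ij$i] == mod[ij$j]
  net <- withSeed(seed, {
    keep <- stats::runif(nrow(ij)) < ifelse(same, pIn, pOut)
    w <- numeric(sum(keep))
    ks <- same[keep]
    w[ks] <- wIn(sum(ks))
    w[!ks] <- wOut(sum(!ks))
    FunctionalNetwork(geneIds[ij$i[keep]], geneIds[ij$j[keep]], w)
  })
  truth <- list(modules = setNames(mod, geneIds),
                params = list(n = n, m = m, pIn = pIn, pOut = pOut),
                seed = seed)
  list(network = net, truth = truth)
}

# All i < j index pairs of 1..n.
pairIndices <- function(n) {
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  data.frame(i = i, j = j)
}

#' Annotation terms from planted modules
#'
#' One term per planted module, so gold-standard construction and per-term
#' AUC benchmarking can run against known ground truth.
#'
#' @param truth the \code{truth} element of [plantedModuleNetwork()].
#' @return a [PathwayAnnotation-class] with one term per module.
#' @export
truthAnnotations <- function(truth) {
  mod <- truth$modules
  ids <- sort(unique(mod))
  terms <- lapply(ids, function(k) names(mod)[mod == k])
  names(terms) <- sprintf("MOD%02d", ids)
  desc <- setNames(sprintf("planted module %d", ids), names(terms))
  PathwayAnnotation(terms, desc)
}

#' Synthetic raw-evidence layers over a planted truth
#'
#' For every gene pair, each layer's raw score is
#' \code{signal * [same module] + Gaussian(0, noiseSd)} — a stand-in for
#' heterogeneous evidence sources whose per-layer \code{signal} controls
#' the log-likelihood recoverable after calibration (signal 0 is a pure
#' noise layer).
#'
#' @param truth the \code{truth} element of [plantedModuleNetwork()].
#' @param nLayers number of layers.
#' @param signal per-layer signal shift; recycled to \code{nLayers}.
#' @param noiseSd Gaussian noise standard deviation.
#' @param seed required integer seed.
#' @return list of \code{nLayers} evidence data.frames (geneA, geneB,
#'   score) over all gene pairs.
#' @export
evidenceTables <- function(truth, nLayers = 3, signal = 2, noiseSd = 1, seed) {
  nLayers <- assertCount(nLayers, "nLayers", min = 1)
  if (noiseSd <= 0) stop("'noiseSd' must be positive", call. = FALSE)
  signal <- rep_len(as.numeric(signal), nLayers)
  mod <- truth$modules
  geneIds <- names(mod)
  ij <- pairIndices(length(geneIds))
  same <- as.numeric(mod[ij$i] == mod[ij$j])
  a <- geneIds[ij$i]
  b <- geneIds[ij$j]
  withSeed(seed, {
    lapply(seq_len(nLayers), function(l) {
      asEvidenceTable(a, b, signal[l] * same +
                        stats::rnorm(length(same), 0, noiseSd))
    })
  })
}

#' Planted DEG context around a hub
#'
#' Emulates a condition-specific differential-expression experiment whose
#' signal concentrates in one hub's neighborhood: each neighbor of
#' \code{hub} becomes a DEG with probability \code{pNeighbor}, every other
#' network gene with probability \code{pBackground}
#' (\code{pNeighbor > pBackground} required).
#'
#' @param net a [FunctionalNetwork-class].
#' @param hub a gene present in the network.
#' @param pNeighbor,pBackground DEG probabilities for neighbors and
#'   non-neighbors.
#' @param seed required integer seed.
#' @return character vector of DEG gene ids.
#' @export
plantedDegContext <- function(net, hub, pNeighbor, pBackground, seed) {
  hub <- normalizeGeneId(hub)
  g <- genes(net)
  if (!hub %in% g)
    stop(sprintf("hub '%s' is not in the network", hub), call. = FALSE)
  pNeighbor <- assertProb(pNeighbor, "pNeighbor")
  pBackground <- assertProb(pBackground, "pBackground")
  if (pNeighbor <= pBackground)
    stop("'pNeighbor' must exceed 'pBackground'", call. = FALSE)
  nb <- names(neighbors(net, hub))
  other <- setdiff(g, nb)
  withSeed(seed, {
    degN <- nb[stats::runif(length(nb)) < pNeighbor]
    degO <- other[stats::runif(length(other)) < pBackground]
    sort(c(degN, degO))
  })
}

#' Similarity-hit tables with known ortholog pairs
#'
#' Builds a pair of directional hit tables whose reciprocal-best-hit
#' analysis at the default cutoff recovers exactly \code{truePairs}: true
#' pairs get mutual best hits with strong E-values (log-uniform between
#' 1e-30 and 1e-10); decoys are either one-directional hits from novel
#' queries or mutual pairs above the cutoff (E = 1e-3), and true queries
#' additionally get weaker off-target hits that never displace the best
#' hit.
#'
#' @param truePairs data.frame with columns source, target (the planted
#'   ortholog pairs; sources and targets must each be unique).
#' @param nDecoys number of decoy constructs (default 50).
#' @param seed required integer seed.
#' @return list with \code{ab} and \code{ba} hit data.frames (query,
#'   target, evalue, bitscore).
#' @export
hitTableFixture <- function(truePairs, nDecoys = 50, seed) {
  nDecoys <- assertCount(nDecoys, "nDecoys")
  src <- normalizeGeneId(truePairs$source)
  tgt <- normalizeGeneId(truePairs$target)
  if (anyDuplicated(src) || anyDuplicated(tgt))
    stop("true pairs must be one-to-one", call. = FALSE)
  nT <- length(src)
  withSeed(seed, {
    eFwd <- 10^stats::runif(nT, -30, -10)
    eRev <- 10^stats::runif(nT, -30, -10)
    ab <- data.frame(query = src, target = tgt, evalue = eFwd,
                     bitscore = stats::runif(nT, 300, 600),
                     stringsAsFactors = FALSE)
    ba <- data.frame(query = tgt, target = src, evalue = eRev,
                     bitscore = stats::runif(nT, 300, 600),
                     stringsAsFactors = FALSE)
    if (nDecoys > 0L) {
      for (d in seq_len(nDecoys)) {
        kind <- d %% 3L
        if (kind == 0L && nT > 0L) {
          # weak off-target hit of a true query: never the best hit
          q <- src[1L + (d %% nT)]
          t <- sprintf("OFFT%04d", d)
          ab <- rbind(ab, data.frame(query = q, target = t,
                                     evalue = 10^stats::runif(1L, -8, -5),
                                     bitscore = stats::runif(1L, 50, 100)))
        } else if (kind == 1L) {
          # one-directional decoy: strong hit with no reciprocal partner
          ab <- rbind(ab, data.frame(query = sprintf("DECQ%04d", d),
                                     target = sprintf("DECT%04d", d),
                                     evalue = 10^stats::runif(1L, -20, -10),
                                     bitscore = stats::runif(1L, 200, 400)))
        } else {
          # mutual best pair above the cutoff
          q <- sprintf("WEAKA%04d", d)
          t <- sprintf("WEAKB%04d", d)
          ab <- rbind(ab, data.frame(query = q, target = t, evalue = 1e-3,
                                     bitscore = 80))
          ba <- rbind(ba, data.frame(query = t, target = q, evalue = 1e-3,
                                     bitscore = 80))
        }
      }
    }
    rownames(ab) <- rownames(ba) <- NULL
    list(ab = ab, ba = ba)
  })
}
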