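# Readers/writers for the on-disk formats: edge-list TSV, gene-set files,
# GMT annotations, evidence tables, LLS bin tables, gold-standard pair files,
# similarity-search (outfmt-6 style) hit tables.

# Parse a headerless (geneA, geneB, score) file; '#' comments and blank
# lines allowed. Returns the raw columns plus original line numbers for
# error reporting.
parsePairScoreFile <- function(path) {
  lines <- readLines(path)
  lineNo <- seq_along(lines)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  lines <- lines[keep]
  lineNo <- lineNo[keep]
  if (!length(lines))
    return(data.frame(geneA = character(), geneB = character(),
                      score = numeric(), line = integer(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(trimws(lines), "[\t ]+")
  nf <- vapply(fields, length, integer(1L))
  if (any(nf < 3L))
    stop(sprintf("line %d: expected 3 tab-separated columns (geneA, geneB, score)",
                 lineNo[which(nf < 3L)[1L]]), call. = FALSE)
  rawScore <- vapply(fields, `[`, character(1L), 3L)
  score <- suppressWarnings(as.numeric(rawScore))
  if (anyNA(score))
    stop(sprintf("line %d: unparseable score '%s'",
                 lineNo[which(is.na(score))[1L]], rawScore[is.na(score)][1L]),
         call. = FALSE)
  a <- normalizeGeneId(vapply(fields, `[`, character(1L), 1L))
  b <- normalizeGeneId(vapply(fields, `[`, character(1L), 2L))
  if (any(a == b))
    stop(sprintf("line %d: self-loop on gene '%s'",
                 lineNo[which(a == b)[1L]], a[a == b][1L]), call. = FALSE)
  data.frame(geneA = a, geneB = b, score = score, line = lineNo,
             stringsAsFactors = FALSE)
}

#' Read a weighted edge list
#'
#' Headerless TSV with columns geneA, geneB, score; \code{'#'}-prefixed
#' comment lines and blank lines are skipped. Pairs are canonicalized; a
#' pair appearing twice (in either orientation) aborts under
#' \code{dedup = "error"} or keeps the larger score under
#' \code{dedup = "max"}. Unparseable scores and self-loops raise errors
#' naming the offending line.
#'
#' @param path file path.
#' @param dedup duplicate-pair policy, \code{"error"} (default) or
#'   \code{"max"}.
#' @return a [FunctionalNetwork-class].
#' @seealso [writeEdgeList()]
#' @export
readEdgeList <- function(path, dedup = c("error", "max")) {
  dedup <- match.arg(dedup)
  d <- parsePairScoreFile(path)
  FunctionalNetwork(d$geneA, d$geneB, d$score, dedup = dedup)
}

#' Write a weighted edge list
#'
#' Writes tab-separated (geneA, geneB, score) with scores rounded to 6
#' significant digits — enough for stable text round-trips without false
#' precision.
#'
#' @param x a [FunctionalNetwork-class] or a data.frame with columns
#'   geneA, geneB, score (e.g. an evidence table).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeEdgeList <- function(x, path) {
  e <- if (is(x, "FunctionalNetwork")) edges(x) else x
  txt <- sprintf("%s\t%s\t%s", e$geneA, e$geneB, sprintf("%.6g", e$score))
  writeLines(txt, path)
  invisible(path)
}

#' Read an evidence pair-score table
#'
#' Same file contract as [readEdgeList()] (headerless geneA, geneB,
#' raw_score TSV), but returned as a canonical data.frame rather than a
#' network: raw evidence scores are not yet log-likelihood calibrated and
#' may take any finite value. One row per pair; duplicates are an error.
#'
#' @param path file path.
#' @return data.frame with columns geneA, geneB, score (canonical pairs,
#'   sorted).
#' @seealso [fitLLSBins()], [scoreComponent()]
#' @export
readEvidenceTable <- function(path) {
  d <- parsePairScoreFile(path)
  asEvidenceTable(d$geneA, d$geneB, d$score)
}

#' Assemble an evidence table from vectors
#'
#' @param geneA,geneB endpoint vectors.
#' @param score finite raw scores.
#' @return canonical, sorted data.frame (geneA, geneB, score); duplicate
#'   pairs are an error.
#' @export
asEvidenceTable <- function(geneA, geneB, score) {
  if (length(score) && any(!is.finite(score)))
    stop("raw scores must be finite", call. = FALSE)
  a <- normalizeGeneId(geneA)
  b <- normalizeGeneId(geneB)
  if (any(a == b))
    stop(sprintf("self-pair on gene '%s' in evidence table", a[a == b][1L]),
         call. = FALSE)
  d <- data.frame(geneA = pmin(a, b), geneB = pmax(a, b),
                  score = as.numeric(score), stringsAsFactors = FALSE)
  key <- paste(d$geneA, d$geneB, sep = "|")
  if (anyDuplicated(key))
    stop(sprintf("duplicate evidence pair '%s'",
                 sub("\\|", " - ", key[duplicated(key)][1L])), call. = FALSE)
  d <- d[order(d$geneA, d$geneB), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Read a gene-set file
#'
#' One gene id per line; \code{'#'} comments and blank lines skipped. Ids
#' are normalized and deduplicated.
#'
#' @param path file path.
#' @return character vector of gene ids (input order of first occurrence).
#' @export
readGeneSet <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(normalizeGeneId(lines))
}

#' Write a gene-set file (one id per line)
#'
#' @param genes character vector of gene ids.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGeneSet <- function(genes, path) {
  writeLines(normalizeGeneId(genes), path)
  invisible(path)
}

#' Read a GMT annotation file
#'
#' Standard GMT: one term per line, tab-separated
#' \code{term \t description \t gene1 \t gene2 ...}.
#'
#' @param path file path.
#' @return a [PathwayAnnotation-class].
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1L)) < 3L)
  if (length(bad))
    stop(sprintf("GMT line %d: need term, description and at least one gene",
                 bad[1L]), call. = FALSE)
  ids <- vapply(fields, `[`, character(1L), 1L)
  if (anyDuplicated(ids))
    stop(sprintf("duplicate GMT term id '%s'", ids[duplicated(ids)][1L]),
         call. = FALSE)
  desc <- vapply(fields, `[`, character(1L), 2L)
  genes <- lapply(fields, function(f) f[-(1:2)])
  PathwayAnnotation(setNames(genes, ids), setNames(desc, ids))
}

#' Write a GMT annotation file
#'
#' @param ann a [PathwayAnnotation-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGmt <- function(ann, path) {
  ids <- termNames(ann)
  txt <- vapply(ids, function(id) {
    paste(c(id, termDescriptions(ann)[[id]], termGenes(ann, id)),
          collapse = "\t")
  }, character(1L))
  writeLines(txt, path)
  invisible(path)
}

#' Write a gold standard as pair TSVs plus a summary
#'
#' Creates \code{<prefix>.positives.tsv} and \code{<prefix>.negatives.tsv}
#' (two-column canonical pair files) and \code{<prefix>.summary.txt}.
#'
#' @param gold a [GoldStandard-class].
#' @param prefix output path prefix.
#' @return \code{prefix}, invisibly.
#' @export
writeGoldStandard <- function(gold, prefix) {
  writePairFile <- function(keys, path) {
    d <- splitPairKeys(keys)
    writeLines(sprintf("%s\t%s", d$geneA, d$geneB), path)
  }
  writePairFile(positivePairs(gold), paste0(prefix, ".positives.tsv"))
  writePairFile(negativePairs(gold), paste0(prefix, ".negatives.tsv"))
  writeLines(c(
    sprintf("positives\t%d", length(positivePairs(gold))),
    sprintf("negatives\t%d", length(negativePairs(gold))),
    sprintf("prior_odds\t%.6g", priorOdds(gold)),
    sprintf("source_terms\t%d", length(gold@sourceTerms))
  ), paste0(prefix, ".summary.txt"))
  invisible(prefix)
}

#' Read a gold standard written by [writeGoldStandard()]
#'
#' @param prefix path prefix used when writing.
#' @return a [GoldStandard-class] (source terms are not recoverable from
#'   the pair files and are left empty).
#' @export
readGoldStandard <- function(prefix) {
  readPairFile <- function(path) {
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines)) return(character())
    f <- strsplit(lines, "[\t ]+")
    sort(unique(canonicalPairKeys(vapply(f, `[`, character(1L), 1L),
                                  vapply(f, `[`, character(1L), 2L))))
  }
  new("GoldStandard",
      positives = readPairFile(paste0(prefix, ".positives.tsv")),
      negatives = readPairFile(paste0(prefix, ".negatives.tsv")),
      sourceTerms = character())
}

#' Write an LLS bin table
#'
#' TSV with columns (lower, upper, pos, neg, lls) and a one-line header
#' comment carrying the prior odds and pseudocount.
#'
#' @param x an [LLSBinTable-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeLLSTable <- function(x, path) {
  b <- llsBins(x)
  txt <- c(sprintf("# prior_odds=%.15g pseudocount=%.15g",
                   x@priorOdds, x@pseudocount),
           sprintf("%.15g\t%.15g\t%d\t%d\t%.15g",
                   b$lower, b$upper, b$pos, b$neg, b$lls))
  writeLines(txt, path)
  invisible(path)
}

#' Read an LLS bin table written by [writeLLSTable()]
#'
#' @param path file path.
#' @return an [LLSBinTable-class].
#' @export
readLLSTable <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")][1L]
  if (is.na(hdr) || !grepl("prior_odds=", hdr))
    stop("missing '# prior_odds=... pseudocount=...' header", call. = FALSE)
  prior <- as.numeric(sub(".*prior_odds=([^ ]+).*", "\\1", hdr))
  pc <- as.numeric(sub(".*pseudocount=([^ ]+).*", "\\1", hdr))
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  f <- strsplit(body, "\t", fixed = TRUE)
  b <- data.frame(
    lower = as.numeric(vapply(f, `[`, character(1L), 1L)),
    upper = as.numeric(vapply(f, `[`, character(1L), 2L)),
    pos = as.integer(vapply(f, `[`, character(1L), 3L)),
    neg = as.integer(vapply(f, `[`, character(1L), 4L)),
    lls = as.numeric(vapply(f, `[`, character(1L), 5L)),
    stringsAsFactors = FALSE
  )
  new("LLSBinTable", bins = b, priorOdds = prior, pseudocount = pc)
}

#' Read a tabular similarity-search hit table (outfmt-6 style)
#'
#' Parses the standard 12-column tabular output of protein similarity
#' searches; only columns 1 (query), 2 (target), 11 (E-value) and
#' 12 (bit score) are used.
#'
#' @param path file path.
#' @return data.frame with columns query, target, evalue, bitscore.
#' @seealso [reciprocalBestHits()]
#' @export
readBlastHits <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(query = character(), target = character(),
                      evalue = numeric(), bitscore = numeric(),
                      stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(f, length, integer(1L))
  if (any(nf < 12L))
    stop(sprintf("hit-table line %d: expected 12 tab-separated columns",
                 which(nf < 12L)[1L]), call. = FALSE)
  data.frame(
    query = normalizeGeneId(vapply(f, `[`, character(1L), 1L)),
    target = normalizeGeneId(vapply(f, `[`, character(1L), 2L)),
    evalue = as.numeric(vapply(f, `[`, character(1L), 11L)),
    bitscore = as.numeric(vapply(f, `[`, character(1L), 12L)),
    stringsAsFactors = FALSE
  )
}

#' Write a 12-column tabular hit table
#'
#' Companion writer for [readBlastHits()]; the unused alignment columns are
#' filled with zeros.
#'
#' @param hits data.frame with columns query, target, evalue, bitscore.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBlastHits <- function(hits, path) {
  txt <- sprintf("%s\t%s\t0\t0\t0\t0\t0\t0\t0\t0\t%.3g\t%.1f",
                 hits$query, hits$target, hits$evalue, hits$bitscore)
  writeLines(txt, path)
  invisible(path)
}
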