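# Plain tab-separated formats. All readers skip blank lines and lines
# starting with '#'; labels are case-sensitive byte strings.

.readTsvLines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  list(lines = lines[keep], lineno = which(keep))
}

#' Read an undirected network from a tab-separated edge list
#'
#' Each non-comment line holds at least two tab-separated node labels (extra
#' columns are ignored). Duplicate edges are collapsed and self-loops
#' dropped, with counts reported via [message()]. Node order is first
#' appearance in the file, which fixes the indexing used by every matrix in
#' the package.
#'
#' @param path path to the edge-list file
#' @return a [PPINetwork-class]
#' @export
readEdgeList <- function(path) {
  tsv <- .readTsvLines(path)
  if (!length(tsv$lines)) stop("no edges found in ", path)
  parts <- strsplit(tsv$lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) {
    stop("malformed edge line ", tsv$lineno[bad[1L]], " in ", path,
         " (expected at least 2 tab-separated fields)")
  }
  ppiNetwork(cbind(vapply(parts, `[[`, "", 1L), vapply(parts, `[[`, "", 2L)))
}

#' Read cross-network similarity scores
#'
#' Parses a three-column file (source label, target label, non-negative
#' score) into a dense [NodeSimilarity-class] matrix aligned to the node
#' indexings of the two networks. Pairs absent from the file score 0; lines
#' whose labels are not in the networks are skipped (count reported);
#' duplicate pairs keep the maximum score.
#'
#' @param path path to the score file
#' @param net1,net2 the source and target [PPINetwork-class]
#' @return a [NodeSimilarity-class] of dimension n1 x n2
#' @export
readSimilarity <- function(path, net1, net2) {
  tsv <- .readTsvLines(path)
  n1 <- numNodes(net1); n2 <- numNodes(net2)
  S <- matrix(0, n1, n2, dimnames = list(net1@labels, net2@labels))
  if (length(tsv$lines)) {
    parts <- strsplit(tsv$lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 3L)
    if (length(bad)) {
      stop("malformed similarity line ", tsv$lineno[bad[1L]], " in ", path)
    }
    a <- vapply(parts, `[[`, "", 1L)
    b <- vapply(parts, `[[`, "", 2L)
    sc <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
    if (anyNA(sc)) {
      stop("non-numeric score on line ", tsv$lineno[which(is.na(sc))[1L]],
           " in ", path)
    }
    if (any(sc < 0)) {
      stop("negative score on line ", tsv$lineno[which(sc < 0)[1L]],
           " in ", path)
    }
    i <- match(a, net1@labels)
    j <- match(b, net2@labels)
    skip <- is.na(i) | is.na(j)
    if (any(skip)) message(sum(skip), " similarity line(s) with unknown labels skipped")
    # duplicates keep the max score
    for (k in which(!skip)) S[i[k], j[k]] <- max(S[i[k], j[k]], sc[k])
  }
  nodeSimilarity(S)
}

#' Read GO annotations
#'
#' Two tab-separated columns: node label, GO term identifier. Duplicate
#' (label, term) lines are deduplicated.
#'
#' @param path path to the annotation file
#' @return a [GOAnnotation-class]
#' @export
readAnnotations <- function(path) {
  tsv <- .readTsvLines(path)
  if (!length(tsv$lines)) return(goAnnotation())
  parts <- strsplit(tsv$lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) {
    stop("malformed annotation line ", tsv$lineno[bad[1L]], " in ", path)
  }
  lab <- vapply(parts, `[[`, "", 1L)
  term <- vapply(parts, `[[`, "", 2L)
  goAnnotation(split(term, factor(lab, levels = unique(lab))))
}

#' Write an alignment to a tab-separated file
#'
#' One \code{sourceLabel<TAB>targetLabel} line per source node, in source
#' index order. [readAlignmentFile()] inverts this exactly.
#'
#' @param alignment a [NetworkAlignment-class] (or integer target vector)
#' @param net1,net2 the aligned networks
#' @param path output path
#' @export
writeAlignment <- function(alignment, net1, net2, path) {
  p <- alignedPairs(alignment, net1, net2)
  writeLines(paste(p[, 1L], p[, 2L], sep = "\t"), con = path)
  invisible(path)
}

#' Read an alignment written by [writeAlignment()]
#'
#' @param path path to a two-column (source label, target label) file
#' @param net1,net2 the aligned networks; every source node must appear
#'   exactly once and targets must be distinct.
#' @return a [NetworkAlignment-class]
#' @export
readAlignmentFile <- function(path, net1, net2) {
  tsv <- .readTsvLines(path)
  if (!length(tsv$lines)) stop("no alignment pairs in ", path)
  parts <- strsplit(tsv$lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) {
    stop("malformed alignment line ", tsv$lineno[bad[1L]], " in ", path)
  }
  src <- vapply(parts, `[[`, "", 1L)
  tgt <- vapply(parts, `[[`, "", 2L)
  i <- match(src, net1@labels)
  j <- match(tgt, net2@labels)
  if (anyNA(i)) stop("unknown source label: ", src[which(is.na(i))[1L]])
  if (anyNA(j)) stop("unknown target label: ", tgt[which(is.na(j))[1L]])
  if (anyDuplicated(i)) stop("duplicate source label in ", path)
  t <- rep(NA_integer_, numNodes(net1))
  t[i] <- j
  if (anyNA(t)) {
    stop("alignment does not cover source node '",
         net1@labels[which(is.na(t))[1L]], "'")
  }
  networkAlignment(t, numNodes(net2))
}
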