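# Synthetic benchmark instances with known ground truth: a source network
# from a standard random-graph model, a relabelled noisy copy, and a
# similarity matrix concentrated on the true node pairs.

#' Generate a random network
#'
#' Three growth models are offered. \code{erdos_renyi} draws each edge
#' independently with probability \code{param} (via
#' \code{igraph::sample_gnp}); \code{preferential_attachment} grows a
#' scale-free graph adding \code{round(param)} edges per new node (via
#' \code{igraph::sample_pa}); \code{duplication_divergence} grows from a
#' single edge by duplicating a random node and retaining each parental
#' edge independently with probability \code{param} — the mechanism behind
#' protein-family expansion in PPI networks.
#'
#' @param model one of \code{"erdos_renyi"}, \code{"preferential_attachment"},
#'   \code{"duplication_divergence"}
#' @param n number of nodes (>= 2)
#' @param param model parameter (edge probability, edges per node, or edge
#'   retention probability)
#' @param seed optional integer seed
#' @return a [PPINetwork-class] with labels \code{v1 ... vn}
#' @export
generateNetwork <- function(model = c("erdos_renyi", "preferential_attachment",
                                      "duplication_divergence"),
                            n, param, seed = NULL) {
  model <- match.arg(model)
  if (n < 2L) stop("'n' must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  labels <- paste0("v", seq_len(n))
  edges <- switch(model,
    erdos_renyi = {
      g <- igraph::sample_gnp(n, param, directed = FALSE)
      igraph::as_edgelist(g, names = FALSE)
    },
    preferential_attachment = {
      g <- igraph::sample_pa(n, m = max(1L, round(param)), directed = FALSE)
      igraph::as_edgelist(g, names = FALSE)
    },
    duplication_divergence = .growDuplicationDivergence(n, param)
  )
  .networkFromIndexEdges(labels, edges)
}

# duplicate a random node, keep each parental edge with probability p
.growDuplicationDivergence <- function(n, p) {
  adj <- vector("list", n)
  adj[[1L]] <- 2L
  adj[[2L]] <- 1L
  for (v in seq.int(3L, n)) {
    u <- sample.int(v - 1L, 1L)
    keep <- adj[[u]][stats::runif(length(adj[[u]])) < p]
    adj[[v]] <- keep
    for (w in keep) adj[[w]] <- c(adj[[w]], v)
  }
  pairs <- do.call(rbind, lapply(seq_len(n), function(v) {
    nb <- adj[[v]]
    nb <- nb[nb > v]
    if (length(nb)) cbind(v, nb) else NULL
  }))
  if (is.null(pairs)) matrix(integer(), 0L, 2L) else pairs
}

# build a PPINetwork from integer index pairs (dedup + canonicalize)
.networkFromIndexEdges <- function(labels, pairs) {
  if (length(pairs)) {
    lo <- pmin(pairs[, 1L], pairs[, 2L])
    hi <- pmax(pairs[, 1L], pairs[, 2L])
    keep <- lo != hi & !duplicated((lo - 1) * length(labels) + hi)
    e <- cbind(lo[keep], hi[keep])
  } else {
    e <- matrix(integer(), 0L, 2L)
  }
  storage.mode(e) <- "integer"
  new("PPINetwork", labels = labels, edges = e)
}

#' Generate a perturbed copy of a network with known ground truth
#'
#' The target network starts as a relabelled copy of \code{net1} (the true
#' injective mapping is drawn uniformly at random), gains \code{nExtra}
#' additional nodes attached by preferential attachment (two links each,
#' probability proportional to degree + 1), and has
#' \code{floor(rewireP * m1)} copied edges replaced by uniformly random
#' non-edges (never re-creating a removed image, so
#' \code{conservedEdges(trueMap) == m1 - nRewired} holds exactly). The
#' similarity matrix has score 1 at true pairs — except a
#' \code{simDropout} fraction zeroed out — and uniform(0, simNoise)
#' elsewhere.
#'
#' @param net1 source [PPINetwork-class]
#' @param nExtra number of target-only nodes (>= 0)
#' @param rewireP fraction of copied edges to rewire, in [0, 1]
#' @param simNoise magnitude of off-pair similarity noise (>= 0)
#' @param simDropout fraction of true-pair similarities zeroed, in [0, 1]
#' @param seed optional integer seed
#' @return a [SyntheticPair-class]
#' @examples
#' net <- generateNetwork("erdos_renyi", 30, 0.2, seed = 1)
#' pair <- generatePair(net, nExtra = 5, rewireP = 0.1, seed = 2)
#' conservedEdges(pair@trueMap, net, pair@net2) # numEdges(net) - nRewired
#' @export
generatePair <- function(net1, nExtra = 0L, rewireP = 0, simNoise = 0,
                         simDropout = 0, seed = NULL) {
  stopifnot(nExtra >= 0L, rewireP >= 0, rewireP <= 1,
            simNoise >= 0, simDropout >= 0, simDropout <= 1)
  if (!is.null(seed)) set.seed(seed)
  n1 <- numNodes(net1)
  m1 <- numEdges(net1)
  n2 <- n1 + as.integer(nExtra)
  trueMap <- sample.int(n2, n1)

  e1 <- net1@edges
  copied <- cbind(pmin(trueMap[e1[, 1L]], trueMap[e1[, 2L]]),
                  pmax(trueMap[e1[, 1L]], trueMap[e1[, 2L]]))
  if (!nrow(copied)) copied <- matrix(integer(), 0L, 2L)

  # attach the target-only nodes by preferential attachment
  extraEdges <- matrix(integer(), 0L, 2L)
  if (nExtra > 0L) {
    deg <- tabulate(c(copied), nbins = n2)
    attached <- sort(unique(as.integer(trueMap)))
    for (x in setdiff(seq_len(n2), trueMap)) {
      k <- min(2L, length(attached))
      w <- deg[attached] + 1
      nb <- attached[sample.int(length(attached), k, prob = w)]
      extraEdges <- rbind(extraEdges, cbind(pmin(nb, x), pmax(nb, x)))
      deg[nb] <- deg[nb] + 1L
      deg[x] <- k
      attached <- c(attached, x)
    }
  }

  # rewire: remove a fraction of copied edges, add random fresh non-edges
  nRewire <- as.integer(floor(rewireP * m1))
  removedKeys <- numeric(0)
  if (nRewire > 0L) {
    drop <- sample.int(m1, nRewire)
    removedKeys <- (copied[drop, 1L] - 1) * n2 + copied[drop, 2L]
    copied <- copied[-drop, , drop = FALSE]
  }
  edges <- rbind(copied, extraEdges)
  keys <- (edges[, 1L] - 1) * n2 + edges[, 2L]
  added <- 0L
  attempts <- 0L
  while (added < nRewire && attempts < 200L * nRewire + 1000L) {
    attempts <- attempts + 1L
    uv <- sample.int(n2, 2L)
    lo <- min(uv); hi <- max(uv)
    key <- (lo - 1) * n2 + hi
    if (key %in% keys || key %in% removedKeys) next
    edges <- rbind(edges, c(lo, hi))
    keys <- c(keys, key)
    added <- added + 1L
  }

  net2 <- .networkFromIndexEdges(paste0("t", seq_len(n2)), edges)

  B <- matrix(stats::runif(n1 * n2, 0, simNoise), n1, n2,
              dimnames = list(net1@labels, net2@labels))
  trueVal <- rep(1, n1)
  nDrop <- as.integer(floor(simDropout * n1))
  if (nDrop > 0L) trueVal[sample.int(n1, nDrop)] <- 0
  B[cbind(seq_len(n1), trueMap)] <- trueVal

  new("SyntheticPair",
      net1 = net1, net2 = net2,
      trueMap = networkAlignment(trueMap, n2),
      scores = nodeSimilarity(B),
      nRewired = nRewire)
}

#' Generate matched GO annotations for a synthetic pair
#'
#' Gives each true node pair a shared set of \code{termsPerPair} GO-style
#' term identifiers, dropping each term on each side independently with
#' probability \code{dropout}, so functional consistency (GOC) can be
#' exercised end to end. Target-only nodes receive no annotation.
#'
#' @param pair a [SyntheticPair-class]
#' @param termsPerPair shared terms per true pair
#' @param dropout per-term, per-side dropout probability
#' @param seed optional integer seed
#' @return list with [GOAnnotation-class] elements \code{annot1} and
#'   \code{annot2}
#' @export
generateAnnotations <- function(pair, termsPerPair = 3L, dropout = 0.2,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n1 <- numNodes(pair@net1)
  t <- pair@trueMap@targetOf
  a1 <- list(); a2 <- list()
  for (i in seq_len(n1)) {
    terms <- paste0("GO:", sprintf("%07d", (i - 1L) * termsPerPair +
                                     seq_len(termsPerPair)))
    k1 <- terms[stats::runif(termsPerPair) >= dropout]
    k2 <- terms[stats::runif(termsPerPair) >= dropout]
    if (length(k1)) a1[[pair@net1@labels[i]]] <- k1
    if (length(k2)) a2[[pair@net2@labels[t[i]]]] <- k2
  }
  list(annot1 = goAnnotation(a1), annot2 = goAnnotation(a2))
}

#' Write a network as a tab-separated edge list
#'
#' Inverse of [readEdgeList()] up to node order: isolated nodes are listed
#' in a trailing comment block so the file stays a two-column edge list.
#'
#' @param net a [PPINetwork-class]
#' @param path output path
#' @export
writeEdgeList <- function(net, path) {
  e <- net@edges
  lines <- paste(net@labels[e[, 1L]], net@labels[e[, 2L]], sep = "\t")
  iso <- setdiff(seq_len(numNodes(net)), unique(c(e)))
  if (length(iso)) {
    lines <- c(lines, paste0("# isolated: ",
                             paste(net@labels[iso], collapse = " ")))
  }
  writeLines(lines, con = path)
  invisible(path)
}

#' Write a similarity matrix as a three-column score file
#'
#' Only nonzero entries are written, as
#' \code{sourceLabel<TAB>targetLabel<TAB>score} lines readable by
#' [readSimilarity()].
#'
#' @param S a [NodeSimilarity-class] with label dimnames
#' @param path output path
#' @export
writeSimilarity <- function(S, path) {
  m <- S@scores
  nz <- which(m > 0, arr.ind = TRUE)
  writeLines(
    sprintf("%s\t%s\t%.10g",
            rownames(m)[nz[, 1L]], colnames(m)[nz[, 2L]], m[nz]),
    con = path)
  invisible(path)
}

#' Write GO annotations as a two-column file
#'
#' @param annot a [GOAnnotation-class]
#' @param path output path
#' @export
writeAnnotations <- function(annot, path) {
  lab <- rep(names(annot@terms), lengths(annot@terms))
  writeLines(paste(lab, unlist(annot@terms, use.names = FALSE), sep = "\t"),
             con = path)
  invisible(path)
}
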