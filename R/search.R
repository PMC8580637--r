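# The discrete bat optimizer. A bat's "position" is a full injective
# alignment; its "velocity" is a 0/1 vector marking which source nodes may
# be re-assigned ("fly") this iteration. The objective is the number of
# conserved edges. All randomness goes through R's global RNG, so a single
# set.seed() (or the seed argument of batAlign) makes runs reproducible.

#' Construct bat-search parameters
#'
#' Defaults follow common usage for this optimizer: a population of 40, up
#' to 1000 iterations, and a patience of 10 iterations without improvement
#' of the best objective. Frequencies are drawn uniformly on
#' \code{[fMin, fMax]} and binarized at \code{0.5 * (fMax - fMin)}.
#' \code{theta} multiplies a bat's loudness on every accepted move;
#' \code{gamma} controls how fast the pulse rate grows towards
#' \code{rate0}, which gates the local search.
#'
#' @param popSize number of bats
#' @param maxIters iteration cap T
#' @param patience stop after this many consecutive iterations without a
#'   strict improvement of the best objective
#' @param fMin,fMax frequency bounds
#' @param theta loudness decay factor, in (0, 1)
#' @param gamma pulse-rate growth rate, > 0
#' @param loudness0 initial loudness
#' @param rate0 pulse-rate ceiling, in [0, 1]
#' @return a [BatParams-class]
#' @export
batParams <- function(popSize = 40L, maxIters = 1000L, patience = 10L,
                      fMin = 0, fMax = 1, theta = 0.9, gamma = 0.9,
                      loudness0 = 1, rate0 = 0.5) {
  new("BatParams",
      popSize = as.integer(popSize), maxIters = as.integer(maxIters),
      patience = as.integer(patience), fMin = fMin, fMax = fMax,
      theta = theta, gamma = gamma, loudness0 = loudness0, rate0 = rate0)
}

#' Number of conserved edges under an alignment
#'
#' An edge (u, v) of the source network is conserved when its image
#' (f(u), f(v)) is an edge of the target network. This count is the
#' objective function of the bat search.
#'
#' @param alignment a [NetworkAlignment-class] or integer target vector
#' @param net1,net2 the aligned [PPINetwork-class] objects
#' @return integer count, at most \code{min(numEdges(net1), numEdges(net2))}
#' @examples
#' tri <- ppiNetwork(cbind(c("a", "b", "c"), c("b", "c", "a")))
#' conservedEdges(1:3, tri, tri) # identity keeps all 3 edges
#' @export
conservedEdges <- function(alignment, net1, net2) {
  t <- .targetOf(alignment, numNodes(net1), numNodes(net2))
  .conservedCount(t, net1@edges, .edgeKeys(net2), numNodes(net2))
}

.conservedCount <- function(targetOf, e1, keys2, n2) {
  if (!nrow(e1)) return(0L)
  sum(.pairKeys(targetOf[e1[, 1L]], targetOf[e1[, 2L]], n2) %in% keys2)
}

# Greedy selection phase: repeatedly take the globally maximal remaining
# (row, col) score and fix that pair, until every remaining free source row
# is all-zero against the remaining free targets. Ties are broken uniformly
# at random. Returns targets with NA for sources left to random completion.
.greedyCore <- function(S) {
  n1 <- nrow(S); n2 <- ncol(S)
  target <- rep(NA_integer_, n1)
  rowFree <- rep(TRUE, n1); colFree <- rep(TRUE, n2)
  repeat {
    if (!any(rowFree)) break
    sub <- S[rowFree, colFree, drop = FALSE]
    mx <- max(sub)
    if (mx <= 0) break
    hits <- which(sub == mx)
    pick <- hits[[sample.int(length(hits), 1L)]]
    ri <- (pick - 1L) %% nrow(sub) + 1L
    ci <- (pick - 1L) %/% nrow(sub) + 1L
    i <- which(rowFree)[ri]; j <- which(colFree)[ci]
    target[i] <- j
    rowFree[i] <- FALSE; colFree[j] <- FALSE
  }
  target
}

# Uniform random injective completion of a partial target vector.
.randomComplete <- function(target, n2) {
  free <- which(is.na(target))
  if (length(free)) {
    pool <- setdiff(seq_len(n2), target[!is.na(target)])
    target[free] <- pool[sample.int(length(pool), length(free))]
  }
  target
}

#' Similarity-guided greedy initial alignment
#'
#' Repeatedly aligns the highest-scoring unused (source, target) pair until
#' every remaining source row is all-zero against the remaining targets;
#' the leftover sources are then assigned uniformly at random among the
#' unused targets. Equal maximal scores are broken uniformly at random, so
#' results are reproducible only under a fixed RNG seed.
#'
#' @param S a [NodeSimilarity-class] or numeric matrix (n1 x n2, n1 <= n2)
#' @return a [NetworkAlignment-class]
#' @export
greedyInitPosition <- function(S) {
  m <- if (is(S, "NodeSimilarity")) S@scores else S
  if (nrow(m) > ncol(m)) {
    stop("source network must not be larger than the target network")
  }
  networkAlignment(.randomComplete(.greedyCore(m), ncol(m)), ncol(m))
}

#' Initialize flight velocity from an alignment
#'
#' A source node incident to at least one conserved edge keeps its
#' assignment (velocity 0); every other source node is free to fly
#' (velocity 1).
#'
#' @inheritParams conservedEdges
#' @return integer 0/1 vector of length n1
#' @export
initVelocity <- function(alignment, net1, net2) {
  t <- .targetOf(alignment, numNodes(net1), numNodes(net2))
  e1 <- net1@edges
  fly <- rep(1L, numNodes(net1))
  if (nrow(e1)) {
    cons <- .pairKeys(t[e1[, 1L]], t[e1[, 2L]], numNodes(net2)) %in%
      .edgeKeys(net2)
    fly[unique(c(e1[cons, 1L], e1[cons, 2L]))] <- 0L
  }
  fly
}

#' Draw a bat's flight frequency
#'
#' One uniform draw on \code{[fMin, fMax]} per bat per iteration.
#'
#' @param params a [BatParams-class]
#' @return a single numeric frequency
#' @export
drawFrequency <- function(params) {
  params@fMin + (params@fMax - params@fMin) * stats::runif(1L)
}

#' Binarize a frequency
#'
#' Returns 1 when the frequency exceeds \code{0.5 * (fMax - fMin)}
#' (strictly), else 0.
#'
#' @param f numeric frequency from [drawFrequency()]
#' @param params a [BatParams-class]
#' @return integer 0 or 1
#' @export
binarizeFrequency <- function(f, params) {
  as.integer(f > 0.5 * (params@fMax - params@fMin))
}

#' Update a bat's velocity against the global best
#'
#' Per dimension: if the bat already agrees with the best alignment there,
#' the previous velocity is kept; otherwise a previously flying dimension
#' takes the binarized frequency and a resting one stays at 0.
#'
#' @param velocity integer 0/1 vector (previous velocity)
#' @param position integer target vector (the bat's alignment)
#' @param best integer target vector of the global best alignment
#' @param fBin binarized frequency from [binarizeFrequency()]
#' @return integer 0/1 vector
#' @export
updateVelocity <- function(velocity, position, best, fBin) {
  agree <- position == best
  out <- integer(length(velocity))
  out[agree] <- velocity[agree]
  out[!agree & velocity == 1L] <- as.integer(fBin)
  out
}

#' Global search move
#'
#' Velocity-0 dimensions keep their targets; the pool U of targets not held
#' by any velocity-0 dimension is distributed uniformly at random (without
#' replacement) over the flying dimensions. The result is always a valid
#' injective alignment.
#'
#' @param position integer target vector
#' @param velocity integer 0/1 vector
#' @param n2 number of target nodes
#' @return integer target vector
#' @export
globalSearch <- function(position, velocity, n2) {
  fly <- which(velocity == 1L)
  if (!length(fly)) return(position)
  U <- setdiff(seq_len(n2), position[velocity == 0L])
  position[fly] <- U[sample.int(length(U), length(fly))]
  position
}

#' Local search move
#'
#' The targets currently held at flying dimensions are permuted uniformly
#' at random among those same dimensions; resting dimensions are untouched,
#' so the overall set of assigned targets is conserved.
#'
#' @inheritParams globalSearch
#' @return integer target vector
#' @export
localSearch <- function(position, velocity) {
  fly <- which(velocity == 1L)
  if (length(fly) > 1L) {
    position[fly] <- position[fly][sample.int(length(fly))]
  }
  position
}

#' Create a bat (one candidate solution)
#'
#' @param position a [NetworkAlignment-class] or integer target vector
#' @param net1,net2 the aligned networks
#' @param params a [BatParams-class]
#' @return a list with elements \code{position} (integer vector),
#'   \code{velocity}, \code{loudness}, \code{rate}, \code{rate0} and the
#'   cached \code{objective}. The pulse rate starts at 0 (its growth law is
#'   zero at t = 0) and rises towards \code{rate0} on accepted moves.
#' @export
newBat <- function(position, net1, net2, params) {
  t <- .targetOf(position, numNodes(net1), numNodes(net2))
  list(
    position = t,
    velocity = initVelocity(t, net1, net2),
    loudness = params@loudness0,
    rate = 0,
    rate0 = params@rate0,
    objective = conservedEdges(t, net1, net2)
  )
}

#' Loudness/objective-gated acceptance of a candidate position
#'
#' The candidate replaces the bat's position only when it strictly improves
#' the conserved-edge objective AND the bat's current loudness exceeds a
#' fresh uniform(0,1) draw. On acceptance the loudness is multiplied by
#' \code{theta}, the pulse rate is set to
#' \code{rate0 * (1 - exp(-gamma * t))}, and the velocity is re-derived
#' from the new position with [initVelocity()]. Otherwise the bat is
#' returned unchanged.
#'
#' @param bat a bat list from [newBat()]
#' @param candidate integer target vector
#' @param candidateObj conserved-edge count of the candidate
#' @param t current iteration index (1-based)
#' @param params a [BatParams-class]
#' @param net1,net2 the aligned networks
#' @return the (possibly updated) bat
#' @export
acceptStep <- function(bat, candidate, candidateObj, t, params, net1, net2) {
  if (candidateObj > bat$objective && bat$loudness > stats::runif(1L)) {
    bat$position <- candidate
    bat$objective <- candidateObj
    bat$loudness <- params@theta * bat$loudness
    bat$rate <- bat$rate0 * (1 - exp(-params@gamma * t))
    bat$velocity <- initVelocity(candidate, net1, net2)
  }
  bat
}

#' One iteration of a single bat
#'
#' Draws and binarizes a frequency, derives this step's flight velocity
#' against the global best, builds a global-search candidate, and — when a
#' uniform draw exceeds the bat's pulse rate — also a local-search
#' candidate, keeping whichever of the two scores more conserved edges; the
#' surviving candidate then passes through [acceptStep()]. The derived
#' velocity is used only to generate the candidates; the bat's stored
#' velocity changes only when a move is accepted.
#'
#' @param bat a bat list from [newBat()]
#' @param best integer target vector of the global best alignment
#' @param t iteration index
#' @param net1,net2 the aligned networks
#' @param params a [BatParams-class]
#' @return the updated bat
#' @export
stepBat <- function(bat, best, t, net1, net2, params) {
  n2 <- numNodes(net2)
  keys2 <- .edgeKeys(net2)
  e1 <- net1@edges
  fBin <- binarizeFrequency(drawFrequency(params), params)
  # the flight velocity lives only for this step's candidates; the bat's
  # stored velocity changes only on acceptance (re-derived from the new
  # position), so a bat that drew a resting frequency is not frozen for good
  vel <- updateVelocity(bat$velocity, bat$position, best, fBin)
  cand <- globalSearch(bat$position, vel, n2)
  cobj <- .conservedCount(cand, e1, keys2, n2)
  if (stats::runif(1L) > bat$rate) {
    lcand <- localSearch(bat$position, vel)
    lobj <- .conservedCount(lcand, e1, keys2, n2)
    if (lobj > cobj) {
      cand <- lcand
      cobj <- lobj
    }
  }
  acceptStep(bat, cand, cobj, t, params, net1, net2)
}

#' Align two networks with the discrete bat search
#'
#' Runs the full optimizer: a similarity-guided greedy core shared by the
#' whole population (each bat completing the similarity-free sources with
#' its own random assignment), then iterative improvement under the
#' conserved-edge objective. The global best is updated each iteration to
#' the highest-scoring bat, keeping the incumbent on ties; the run stops at
#' \code{maxIters} iterations or after \code{patience} consecutive
#' iterations without strict improvement.
#'
#' @param net1 source [PPINetwork-class]; must not have more nodes than
#'   \code{net2}
#' @param net2 target [PPINetwork-class]
#' @param S blended similarity, a [NodeSimilarity-class] or matrix of shape
#'   n1 x n2 (see [blendedSimilarity()]); use an all-zero matrix for purely
#'   random initialization
#' @param params a [BatParams-class]
#' @param seed optional integer; when given, \code{set.seed(seed)} is
#'   called so the whole run is reproducible
#' @return a [BatAlignResult-class]
#' @examples
#' net <- generateNetwork("erdos_renyi", n = 20, param = 0.2, seed = 7)
#' pair <- generatePair(net, seed = 8)
#' res <- batAlign(net, pair@net2, pair@scores,
#'                 batParams(popSize = 10, maxIters = 50), seed = 9)
#' nodeCorrectness(res@alignment, pair@trueMap)
#' @export
batAlign <- function(net1, net2, S, params = batParams(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n1 <- numNodes(net1); n2 <- numNodes(net2)
  if (n1 < 1L) stop("source network is empty")
  if (n1 > n2) stop("source network must not be larger than the target network")
  m <- if (is(S, "NodeSimilarity")) S@scores else as.matrix(S)
  if (nrow(m) != n1 || ncol(m) != n2) {
    stop("similarity matrix shape does not match the networks")
  }

  core <- .greedyCore(m)
  bats <- lapply(seq_len(params@popSize), function(b) {
    newBat(.randomComplete(core, n2), net1, net2, params)
  })

  objs <- vapply(bats, `[[`, numeric(1L), "objective")
  bestIdx <- which.max(objs)
  best <- bats[[bestIdx]]$position
  bestObj <- objs[[bestIdx]]

  trace <- numeric(params@maxIters + 1L)
  trace[1L] <- bestObj
  stall <- 0L
  t <- 0L
  while (t < params@maxIters && stall < params@patience) {
    t <- t + 1L
    for (b in seq_along(bats)) {
      bats[[b]] <- stepBat(bats[[b]], best, t, net1, net2, params)
    }
    objs <- vapply(bats, `[[`, numeric(1L), "objective")
    topIdx <- which.max(objs)
    if (objs[[topIdx]] > bestObj) {
      bestObj <- objs[[topIdx]]
      best <- bats[[topIdx]]$position
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    trace[t + 1L] <- bestObj
  }

  new("BatAlignResult",
      alignment = networkAlignment(best, n2),
      objective = as.numeric(bestObj),
      trace = trace[seq_len(t + 1L)],
      iterations = t,
      converged = stall >= params@patience,
      params = params)
}
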