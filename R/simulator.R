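## Stochastic branching-process simulator of RGP neurogenesis.
##
## Four rules govern a lineage: (1) clone size (total neurons, PyN) is
## drawn from a two-component zero-truncated Poisson mixture; (2) the
## first generation's division pattern is uniform over the feasible
## patterns; (3) subsequent patterns follow a stationary Markov chain over
## (IPP, IP, N); (4) when fewer than four neurons remain, the transition
## matrix is renormalized so the remaining quota is met exactly (no IPPs
## when 2 <= remaining < 4; forced N when exactly 1 remains).

#' Zero-truncated Poisson sampler
#'
#' @param n Number of draws.
#' @param lambda Poisson rate.
#' @return Integer vector of draws, all `>= 1`.
#' @export
rztpois <- function(n, lambda) {
  p0 <- exp(-lambda)
  u <- runif(n, min = p0, max = 1)
  as.integer(qpois(u, lambda))
}

#' Draw clone sizes from the mixture model
#'
#' Picks a mixture component by its weight, then draws a zero-truncated
#' Poisson variate from that component's rate.
#'
#' @param n Number of clones.
#' @param model A [CloneSizeModel-class].
#' @return Integer vector of clone sizes, all `>= 1`.
#' @export
drawCloneSize <- function(n, model = CloneSizeModel()) {
  comp <- sample.int(length(model@weights), n, replace = TRUE,
                     prob = model@weights)
  sizes <- integer(n)
  for (k in seq_along(model@rates)) {
    idx <- comp == k
    if (any(idx)) sizes[idx] <- rztpois(sum(idx), model@rates[k])
  }
  sizes
}

#' Boundary-constrained transition matrix
#'
#' When at least four neurons remain the matrix is unchanged. When two or
#' three remain, the IPP column is zeroed and each row renormalized by its
#' remaining mass. When exactly one remains, every row becomes (0, 0, 1):
#' the RGP can only produce a single neuron.
#'
#' @param p A [TransitionMatrix-class].
#' @param pynRemain Number of neurons the lineage still owes.
#' @return The constrained [TransitionMatrix-class].
#' @export
constrainedMatrix <- function(p, pynRemain) {
  if (pynRemain >= 4) return(p)
  TransitionMatrix(.constrainedProbs(transProbs(p), pynRemain))
}

.constrainedProbs <- function(m, pynRemain) {
  stopifnot(pynRemain >= 1)
  if (pynRemain >= 4) return(m)
  if (pynRemain == 1) {
    m[] <- rep(c(0, 0, 1), each = 3)
    return(m)
  }
  keep <- 1 - m[, 1]
  if (any(keep <= 0))
    stop("constrainedMatrix: degenerate row (all mass on IPP) cannot be renormalized")
  m2 <- m
  m2[, 1] <- 0
  m2[, 2:3] <- m[, 2:3] / keep
  m2
}

.patternConsumption <- c(IPP = 4L, IP = 2L, N = 1L)

## feasible asymmetric patterns given the remaining neuron quota
.feasiblePatterns <- function(pynRemain) {
  if (pynRemain >= 4) c("IPP", "IP", "N")
  else if (pynRemain >= 2) c("IP", "N")
  else "N"
}

#' First-generation division pattern
#'
#' Uniform over the three asymmetric patterns, restricted to those
#' feasible under the remaining-quota rule for the drawn clone size (all
#' three for sizes >= 4; IP and N for sizes 2-3; N alone for size 1).
#'
#' @param pynTarget Drawn clone size.
#' @return One of `"IPP"`, `"IP"`, `"N"`.
#' @export
firstPattern <- function(pynTarget) {
  stopifnot(pynTarget >= 1)
  feas <- .feasiblePatterns(pynTarget)
  if (length(feas) == 1) feas else sample(feas, 1)
}

## cheap two-column data.frame constructor (hot path)
.genTable <- function(generation, pattern) {
  structure(list(generation = as.integer(generation), pattern = pattern),
            class = "data.frame",
            row.names = c(NA_integer_, -length(pattern)))
}

#' Simulate a lineage's division-pattern sequence
#'
#' The Markov core of the simulator without tree construction: draws the
#' clone size, the first pattern (feasibility-renormalized uniform) and
#' subsequent patterns from the boundary-constrained transition matrix
#' until the neuron quota is exhausted, then records the cycle exit.
#'
#' @inheritParams simulateLineage
#' @return data.frame with columns `generation` and `pattern` (ending in
#'   `"EXIT"`).
#' @export
simulatePatternSequence <- function(p = defaultTransitionMatrix(),
                                    model = CloneSizeModel(),
                                    pynTarget = NULL) {
  pyn <- if (is.null(pynTarget)) drawCloneSize(1, model) else
    as.integer(pynTarget)
  stopifnot(pyn >= 1)
  remain <- pyn
  g <- 0L
  patterns <- character(0)
  prev <- NULL
  pm <- transProbs(p)
  while (remain > 0) {
    g <- g + 1L
    pat <- if (is.null(prev)) {
      firstPattern(remain)
    } else {
      probs <- .constrainedProbs(pm, remain)[prev, ]
      sample(.patternOrder, 1, prob = probs)
    }
    patterns[g] <- pat
    remain <- remain - .patternConsumption[[pat]]
    prev <- pat
  }
  .genTable(c(seq_along(patterns), length(patterns) + 1L),
            c(patterns, "EXIT"))
}

#' Simulate one RGP lineage
#'
#' Draws the clone size (unless `pynTarget` is given), chooses the first
#' pattern uniformly over the feasible set, then follows the Markov chain
#' with boundary renormalization until the neuron quota is exhausted, at
#' which point the RGP exits the cycle. Each division appends the progeny
#' subtree (N: one neuron; IP: an IP with two neurons; IPP: an IPP with
#' two IPs of two neurons each) with exact intensity halving (root = 1)
#' and birth-generation annotations.
#'
#' @param p A [TransitionMatrix-class].
#' @param model A [CloneSizeModel-class].
#' @param pynTarget Optional fixed clone size (overrides `model`).
#' @param cloneId Identifier stamped on the tree.
#' @return An annotated [LineageTree-class]; the number of neuron leaves
#'   equals the drawn clone size exactly.
#' @export
simulateLineage <- function(p = defaultTransitionMatrix(),
                            model = CloneSizeModel(),
                            pynTarget = NULL, cloneId = "sim") {
  gens <- simulatePatternSequence(p, model, pynTarget)
  patterns <- gens$pattern[gens$pattern != "EXIT"]
  root <- .buildChain(patterns, 1L, ti = 1, cellPrefix = cloneId)
  root$birthGen <- 0L
  .fastTree(root, cloneId = cloneId, generations = gens)
}

## build the RGP chain for a pattern sequence; returns the chain node at
## generation `g` (its division is generation g)
.buildChain <- function(patterns, g, ti, cellPrefix) {
  counterEnv <- new.env(parent = emptyenv())
  counterEnv$i <- 0L
  build <- function(g, ti) {
    pat <- patterns[g]
    prog <- .buildProgeny(pat, g, ti / 2, cellPrefix, counterEnv)
    chain <- if (g == length(patterns)) {
      .newNode("RGP", ti / 2, exit = TRUE, birthGen = g)
    } else {
      build(g + 1L, ti / 2)
    }
    chain$birthGen <- g
    .newNode("RGP", ti, children = list(prog, chain), birthGen = g - 1L)
  }
  root <- build(g, ti)
  root$birthGen <- 0L
  root
}

.buildProgeny <- function(pattern, g, ti, cellPrefix, counterEnv) {
  newNeuron <- function(ti, birthGen) {
    counterEnv$i <- counterEnv$i + 1L
    .newNode("NEURON", ti, cellId = sprintf("%s_n%d", cellPrefix,
                                            counterEnv$i),
             birthGen = birthGen, gen = g, origin = pattern)
  }
  if (pattern == "N") return(newNeuron(ti, g))
  if (pattern == "IP") {
    return(.newNode("IP", ti, birthGen = g,
                    children = list(newNeuron(ti / 2, g + 1L),
                                    newNeuron(ti / 2, g + 1L))))
  }
  ## IPP: two IPs, each with two neurons
  makeIp <- function(tiIp)
    .newNode("IP", tiIp, birthGen = g + 1L,
             children = list(newNeuron(tiIp / 2, g + 2L),
                             newNeuron(tiIp / 2, g + 2L)))
  .newNode("IPP", ti, birthGen = g,
           children = list(makeIp(ti / 2), makeIp(ti / 2)))
}

#' Simulate a batch ensemble of lineages
#'
#' Simulates `nBatches x batchSize` lineages (default geometry 258
#' lineages per batch repeated 100 times) with per-batch reproducible
#' substreams derived from the master seed.
#'
#' @param config A [RunConfig-class] (its `seed`, `batchSize`, `nBatches`,
#'   `sizeModel` and `transitions` are used).
#' @param nBatches Optional override of the batch count.
#' @param maxSize Optional cap on clone size (draws above it are
#'   rejected and redrawn).
#' @return List of batches; each batch is a list of [LineageTree-class].
#' @export
simulateBatch <- function(config = RunConfig(), nBatches = NULL,
                          maxSize = Inf) {
  nb <- if (is.null(nBatches)) config@nBatches else as.integer(nBatches)
  set.seed(config@seed)
  batchSeeds <- sample.int(.Machine$integer.max - 1L, nb)
  lapply(seq_len(nb), function(b) {
    set.seed(batchSeeds[b])
    lapply(seq_len(config@batchSize), function(i) {
      size <- drawCloneSize(1, config@sizeModel)
      while (size > maxSize) size <- drawCloneSize(1, config@sizeModel)
      simulateLineage(config@transitions, pynTarget = size,
                      cloneId = sprintf("b%d_c%d", b, i))
    })
  })
}
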