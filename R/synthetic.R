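## Synthetic observation generator: turns ground-truth simulated trees
## into dye-tracing-like cell tables with intensity-partition noise,
## inside-out spatial structure, marker-consistent neuron classes,
## apoptotic dropout and detection thresholding.

#' Assign noisy measured intensities to a lineage tree
#'
#' The root receives `rootIntensity` (optionally reduced once by the
#' process-localized dye loss fraction). At every division one daughter
#' inherits a fraction f of the parental dye, drawn from a normal
#' distribution with mean 0.5 and SD `daughterFractionSd` truncated to
#' `fractionBounds`; the other daughter receives 1 - f, so the parental
#' intensity is conserved exactly at every division. With SD 0 the
#' intensities equal the theoretical halving exactly.
#'
#' @param tree A [LineageTree-class].
#' @param noise A [NoiseModel-class].
#' @return The tree with `obsIntensity` set on every node.
#' @export
assignNoisyIntensities <- function(tree, noise = NoiseModel()) {
  rootI <- noise@rootIntensity * (1 - noise@processLossFraction)
  tree@root <- .noisyNode(tree@root, rootI, noise)
  tree
}

.noisyNode <- function(node, intensity, noise) {
  node$obsIntensity <- intensity
  if (.isLeaf(node)) return(node)
  f <- .rtruncnorm1(0.5, noise@daughterFractionSd, noise@fractionBounds)
  node$children[[1]] <- .noisyNode(node$children[[1]], intensity * f, noise)
  node$children[[2]] <- .noisyNode(node$children[[2]], intensity * (1 - f),
                                   noise)
  node
}

.rtruncnorm1 <- function(mean, sd, bounds) {
  if (sd == 0) return(mean)
  repeat {
    x <- rnorm(1, mean, sd)
    if (x > bounds[1] && x < bounds[2]) return(x)
  }
}

#' Map relative radial position to a cortical layer
#'
#' @param rrp Relative radial position(s) in `[0, 1]` (0 = pia,
#'   1 = subplate).
#' @param cuts Named increasing upper bounds, see [defaultLayerCuts()].
#' @return Character vector of layer labels; the cut points partition
#'   `[0, 1]` with no gaps.
#' @export
layerFromRrp <- function(rrp, cuts = defaultLayerCuts()) {
  names(cuts)[pmax(1L, findInterval(rrp, c(-Inf, cuts[-length(cuts)]),
                                    left.open = FALSE))]
}

#' Assign inside-out spatial positions to clonal neurons
#'
#' Earlier effective birth order (generation, plus one extra step for
#' IP-derived and two for IPP-derived neurons) places neurons deeper
#' (higher relative radial position); each step toward later birth moves
#' the neuron `insideOutStrength` toward the pia, with Gaussian jitter.
#' Laterally the clone forms a column of scale `cloneColumnScale`;
#' same-IP sibling pairs share an anchor and scatter only by
#' `siblingClusterScale`. Positions are in micrometres with y the depth
#' axis (relative radial position times 1000).
#'
#' @param tree A generation-annotated [LineageTree-class].
#' @param spatial A [SpatialModel-class].
#' @param center Lateral (x, z) centre of the clone column, micrometres.
#' @return The tree with `x`, `y`, `z`, `rrp` and `layer` fields set on
#'   neuron leaves.
#' @export
assignPositions <- function(tree, spatial = SpatialModel(),
                            center = c(0, 0)) {
  if (!nrow(tree@generations))
    stop("assignPositions: tree must be generation-annotated")
  tree@root <- .positionNode(tree@root, spatial, center, anchor = NULL)
  tree
}

.effectiveBirthOrder <- function(leaf) {
  extra <- switch(leaf$origin, N = 0L, NN_TERMINAL = 0L, IP = 1L,
                  IPP = 2L, 0L)
  leaf$gen + extra
}

.positionNode <- function(node, spatial, center, anchor) {
  ## sibling groups born of one IP (or one terminal N/N division) share
  ## a tight anchor; every other neuron gets its own column-scale anchor
  if (!.isLeaf(node) && is.null(anchor) &&
      (node$type == "IP" || isTRUE(node$terminal)))
    anchor <- center + rnorm(2, 0, spatial@cloneColumnScale)
  if (.isLeaf(node)) {
    if (node$type != "NEURON") return(node)
    b <- .effectiveBirthOrder(node)
    rrp <- 0.9 - spatial@insideOutStrength * (b - 1) +
      rnorm(1, 0, spatial@radialJitterSd)
    rrp <- min(max(rrp, 0.01), 0.99)
    at <- if (is.null(anchor))
      center + rnorm(2, 0, spatial@cloneColumnScale)
    else anchor + rnorm(2, 0, spatial@siblingClusterScale)
    node$x <- at[1]
    node$z <- at[2]
    node$rrp <- rrp
    node$y <- rrp * 1000
    return(node)
  }
  node$children <- lapply(node$children, .positionNode, spatial = spatial,
                          center = center, anchor = anchor)
  node
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.classMarkers <- list(
  CPN  = c(satb2 = "+", ctip2 = "-", fog2 = "-"),
  SCPN = c(satb2 = "-", ctip2 = "+", fog2 = "-"),
  CThPN = c(satb2 = "-", ctip2 = "-", fog2 = "+"),
  HPN  = c(satb2 = "+", ctip2 = "+", fog2 = "-"),
  SPN  = c(satb2 = "-", ctip2 = "-", fog2 = "-"))

#' Assign neuron classes and consistent marker triples
#'
#' Each neuron draws a projection class from the class-probability table
#' row matching its spawning division pattern and layer, then receives
#' the class's defining Satb2/Ctip2/Fog2 marker pattern (CPN:
#' Satb2+/Ctip2-/Fog2-; SCPN: Ctip2+ only; CThPN: Fog2+; HPN:
#' Satb2+/Ctip2+; SPN: all negative, subplate). Layer constraints are
#' enforced by the table itself (SCPN/HPN rows only in L5, CThPN only in
#' L6).
#'
#' @param tree A positioned, annotated [LineageTree-class].
#' @param classTable See [defaultClassTable()].
#' @return The tree with `class` and marker fields on neuron leaves.
#' @export
assignClassesAndMarkers <- function(tree, classTable = defaultClassTable()) {
  .validateClassTable(classTable)
  tree@root <- .classNode(tree@root, classTable)
  tree
}

.classNode <- function(node, classTable) {
  if (.isLeaf(node)) {
    if (node$type != "NEURON" || is.null(node$layer) && is.null(node$rrp))
      return(node)
    layer <- node$layer %||% layerFromRrp(node$rrp)
    node$layer <- layer
    if (layer == "SP") {
      cls <- "SPN"
    } else {
      pat <- if (!is.na(node$origin) && node$origin == "NN_TERMINAL") "N"
             else node$origin
      row <- classTable[(classTable$pattern == pat |
                           classTable$pattern == "any") &
                          classTable$layer == layer, , drop = FALSE]
      if (nrow(row) == 0)
        stop("assignClassesAndMarkers: no class-table row for layer ", layer)
      probs <- as.numeric(row[1, c("CPN", "SCPN", "CThPN", "HPN")])
      cls <- sample(c("CPN", "SCPN", "CThPN", "HPN"), 1, prob = probs)
    }
    node$class <- cls
    mk <- .classMarkers[[cls]]
    node$satb2 <- mk[["satb2"]]
    node$ctip2 <- mk[["ctip2"]]
    node$fog2 <- mk[["fog2"]]
    return(node)
  }
  node$children <- lapply(node$children, .classNode, classTable = classTable)
  node
}

#' Apply apoptotic dropout and the detection threshold
#'
#' Each neuron is independently removed with probability `dropoutRate`
#' (flagged apoptotic in the ground truth); remaining neurons with
#' measured intensity below `detectionFactor * backgroundLevel` are
#' removed as undetected. Raising the detection factor never adds cells.
#'
#' @param cellsDf Cell-table data.frame (all ground-truth neurons).
#' @param noise A [NoiseModel-class].
#' @return List with `observed` (surviving rows) and `truth` (all rows
#'   with `apoptotic` and `detected` flags).
#' @export
applyDropoutAndThreshold <- function(cellsDf, noise = NoiseModel()) {
  n <- nrow(cellsDf)
  apoptotic <- runif(n) < noise@dropoutRate
  detected <- cellsDf$intensity >= noise@detectionFactor * noise@backgroundLevel
  truth <- cellsDf
  truth$apoptotic <- apoptotic
  truth$detected <- detected
  observed <- cellsDf[!apoptotic & detected, , drop = FALSE]
  observed$apoptotic <- rep(FALSE, nrow(observed))
  rownames(observed) <- NULL
  list(observed = observed, truth = truth)
}

## extract the neuron leaves of a fully decorated tree as cell-table rows
.treeToCellRows <- function(tree, region = "unknown") {
  leaves <- .collectLeaves(tree@root)
  leaves <- Filter(function(l) l$type == "NEURON", leaves)
  if (length(leaves) == 0) return(NULL)
  data.frame(
    clone_id = tree@cloneId,
    cell_id = vapply(leaves, function(l) l$cellId, character(1)),
    intensity = vapply(leaves, function(l) l$obsIntensity, numeric(1)),
    x = vapply(leaves, function(l) l$x %||% NA_real_, numeric(1)),
    y = vapply(leaves, function(l) l$y %||% NA_real_, numeric(1)),
    z = vapply(leaves, function(l) l$z %||% NA_real_, numeric(1)),
    rel_radial_pos = vapply(leaves, function(l) l$rrp %||% NA_real_,
                            numeric(1)),
    layer = vapply(leaves, function(l) l$layer %||% "unknown", character(1)),
    satb2 = vapply(leaves, function(l) l$satb2 %||% "?", character(1)),
    ctip2 = vapply(leaves, function(l) l$ctip2 %||% "?", character(1)),
    fog2 = vapply(leaves, function(l) l$fog2 %||% "?", character(1)),
    neuron_class = vapply(leaves, function(l) l$class %||% "unknown",
                          character(1)),
    apoptotic = FALSE,
    region = region,
    stringsAsFactors = FALSE)
}

#' Synthesize an observation table from ground-truth trees
#'
#' Runs the full generator: intensity-partition noise, inside-out
#' positioning, class/marker assignment, then apoptotic dropout and the
#' detection threshold. Clones losing every cell are dropped from the
#' observed set (clone extinction).
#'
#' @param trees List of annotated [LineageTree-class] (simulator output).
#' @param noise A [NoiseModel-class].
#' @param spatial A [SpatialModel-class].
#' @param classTable See [defaultClassTable()].
#' @param dropout,threshold Logical switches for the two loss processes
#'   (both on by default).
#' @param seed Optional seed for the generator's randomness.
#' @return List with `clones` (list of [Clone-class]), `cells` (observed
#'   table), `truth` (all ground-truth rows with loss flags) and `trees`
#'   (the decorated ground-truth trees).
#' @export
synthesizeCellTable <- function(trees, noise = NoiseModel(),
                                spatial = SpatialModel(),
                                classTable = defaultClassTable(),
                                dropout = TRUE, threshold = TRUE,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  centers <- matrix(runif(2 * length(trees), -2000, 2000), ncol = 2)
  decorated <- lapply(seq_along(trees), function(i) {
    t <- assignNoisyIntensities(trees[[i]], noise)
    t <- assignPositions(t, spatial, center = centers[i, ])
    assignClassesAndMarkers(t, classTable)
  })
  rows <- do.call(rbind, Filter(Negate(is.null),
                                lapply(decorated, .treeToCellRows)))
  eff <- noise
  if (!dropout) eff@dropoutRate <- 0
  if (!threshold) eff@backgroundLevel <- .Machine$double.xmin
  loss <- applyDropoutAndThreshold(rows, eff)
  observed <- loss$observed
  clones <- lapply(split(observed,
                         factor(observed$clone_id,
                                unique(observed$clone_id))), Clone)
  list(clones = clones, cells = observed, truth = loss$truth,
       trees = decorated)
}
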