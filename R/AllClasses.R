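#' @import methods
#' @importFrom stats rnorm runif rpois qpois ecdf ks.test chisq.test pchisq
#'   dpois sd dist hclust cutree uniroot lm coef residuals quantile
#'   setNames aggregate
#' @importFrom utils read.delim write.table head
NULL

## ---- controlled vocabularies -------------------------------------------

#' Cell types of lineage tree nodes
#'
#' The four node types appearing in clonal lineage trees: radial glial
#' progenitors (`"RGP"`, the self-renewing stem cell), proliferative
#' intermediate progenitors (`"IPP"`, which amplify through two rounds of
#' division into four neurons), neurogenic intermediate progenitors
#' (`"IP"`, one symmetric division into two neurons) and postmitotic
#' neurons (`"NEURON"`).
#'
#' @return Character vector of the four valid cell-type labels.
#' @export
cellTypes <- function() c("RGP", "IPP", "IP", "NEURON")

#' Division patterns of an RGP generation
#'
#' `"N"`, `"IP"` and `"IPP"` are the three asymmetric neurogenic division
#' patterns (the RGP self-renews and produces a neuron, an IP, or an IPP).
#' `"NN_TERMINAL"` marks a terminal self-consuming division into two
#' neurons, `"SYMMETRIC"` a symmetric RGP/RGP division, and `"EXIT"` the
#' exit of the RGP from the neurogenic cycle.
#'
#' @return Character vector of the six division-pattern labels.
#' @export
divisionPatterns <- function()
  c("N", "IP", "IPP", "NN_TERMINAL", "SYMMETRIC", "EXIT")

.patternOrder <- c("IPP", "IP", "N")

.layerLevels <- c("L2/3", "L4", "L5", "L6", "SP", "unknown")
.neuronClasses <- c("CPN", "SCPN", "CThPN", "HPN", "SPN", "unknown")
.markerLevels <- c("+", "-", "?")
.regions <- c("MC", "SC", "AC", "VC", "unknown")

## ---- LineageTree --------------------------------------------------------

## Nodes are plain nested lists (see node-utils.R) carried inside the S4
## container; per-node S4 objects would be prohibitively heavy for
## enumeration.
#' Clonal lineage tree
#'
#' Binary tree over cell-type nodes. Each internal node is a division;
#' both daughters carry exactly half the parent's theoretical dye
#' intensity (root = 1). Leaves are observed neurons or unobserved
#' cycle-exiting RGP placeholders.
#'
#' @slot root Nested-list node structure (internal representation).
#' @slot cloneId Clone identifier.
#' @slot rootType Cell type of the root (`"RGP"` for clones admitted to
#'   RGP-level analyses; `"IP"`, `"IPP"` or `"NEURON"` classify excluded
#'   progenitor/neuron-labelled clones).
#' @slot generations data.frame with columns `generation` (integer) and
#'   `pattern` (division pattern) along the RGP chain; empty until
#'   annotated.
#' @export
setClass("LineageTree", representation(
  root = "list",
  cloneId = "character",
  rootType = "character",
  generations = "data.frame"
))

setValidity("LineageTree", function(object) {
  msg <- .validateNode(object@root, expectTi = object@root$ti)
  if (!is.null(msg)) return(msg)
  if (!object@rootType %in% cellTypes())
    return("rootType must be one of the four cell types")
  if (nrow(object@generations) &&
      !all(object@generations$pattern %in% divisionPatterns()))
    return("unknown division pattern in generations")
  TRUE
})

#' Construct a LineageTree
#' @param root nested-list node (internal representation).
#' @param cloneId clone identifier.
#' @param generations optional annotated generation table.
#' @return A [LineageTree-class] object.
#' @export
LineageTree <- function(root, cloneId = "clone",
                        generations = emptyGenerations()) {
  new("LineageTree", root = root, cloneId = cloneId,
      rootType = root$type, generations = generations)
}

#' @rdname LineageTree
#' @export
emptyGenerations <- function()
  data.frame(generation = integer(), pattern = character(),
             stringsAsFactors = FALSE)

## ---- TransitionMatrix ---------------------------------------------------

#' Row-stochastic division-pattern transition matrix
#'
#' 3x3 matrix p[i, j] giving the probability that an RGP using pattern i
#' (rows/columns ordered IPP, IP, N) in one generation uses pattern j in
#' the next.
#'
#' @slot probs Numeric 3x3 matrix, each row summing to 1.
#' @export
setClass("TransitionMatrix", representation(probs = "matrix"))

setValidity("TransitionMatrix", function(object) {
  p <- object@probs
  if (!is.numeric(p) || !all(dim(p) == c(3L, 3L)))
    return("probs must be a numeric 3x3 matrix")
  if (any(p < -1e-12) || any(p > 1 + 1e-12))
    return("transition probabilities must lie in [0, 1]")
  if (any(abs(rowSums(p) - 1) > 1e-8))
    return("each row of a transition matrix must sum to 1")
  TRUE
})

#' @param probs numeric 3x3 row-stochastic matrix (rows/cols IPP, IP, N).
#' @rdname TransitionMatrix-class
#' @return A [TransitionMatrix-class].
#' @export
TransitionMatrix <- function(probs) {
  probs <- as.matrix(probs)
  dimnames(probs) <- list(.patternOrder, .patternOrder)
  new("TransitionMatrix", probs = probs)
}

#' Illustrative default transition matrix
#'
#' A qualitatively plausible set of transition probabilities (IPP
#' divisions less persistent, N divisions most persistent) used as the
#' documented default wherever a transition matrix is required but not
#' supplied. It is an illustrative configuration value, not an
#' experimental estimate.
#'
#' @return A [TransitionMatrix-class].
#' @export
defaultTransitionMatrix <- function() {
  TransitionMatrix(rbind(
    c(0.20, 0.40, 0.40),   # from IPP
    c(0.15, 0.45, 0.40),   # from IP
    c(0.10, 0.30, 0.60)))  # from N
}

## ---- CloneSizeModel -----------------------------------------------------

#' Two-component zero-truncated Poisson clone-size model
#'
#' Clone sizes (total neurons per lineage) follow a mixture of
#' zero-truncated Poisson components. The defaults are the fitted
#' population values: weights 0.35/0.65 with rates 4.09 and 7.62.
#'
#' @slot weights Mixture weights, summing to 1.
#' @slot rates Positive Poisson rates, one per component.
#' @export
setClass("CloneSizeModel", representation(
  weights = "numeric", rates = "numeric"))

setValidity("CloneSizeModel", function(object) {
  if (length(object@weights) != length(object@rates))
    return("weights and rates must have equal length")
  if (abs(sum(object@weights) - 1) > 1e-8)
    return("mixture weights must sum to 1")
  if (any(object@weights < 0)) return("weights must be nonnegative")
  if (any(object@rates <= 0)) return("rates must be positive")
  TRUE
})

#' @param weights mixture weights.
#' @param rates zero-truncated Poisson rates.
#' @rdname CloneSizeModel-class
#' @return A [CloneSizeModel-class].
#' @export
CloneSizeModel <- function(weights = c(0.35, 0.65),
                           rates = c(4.09, 7.62)) {
  new("CloneSizeModel", weights = weights, rates = rates)
}

## ---- NoiseModel / SpatialModel -----------------------------------------

#' Intensity-partition noise and detection model
#'
#' At each division one daughter inherits a fraction f of the parental
#' dye, drawn from a normal distribution with mean 0.5 truncated to
#' `fractionBounds`; the other daughter receives 1 - f, so intensity is
#' conserved exactly. Neurons are independently lost with probability
#' `dropoutRate` (programmed cell death, ~7 percent of clonal neurons) and
#' cells below `detectionFactor * backgroundLevel` (detection requires at
#' least twice background autofluorescence) are unobserved.
#'
#' @slot daughterFractionSd SD of the inherited fraction (default 0.03).
#' @slot fractionBounds Open truncation interval containing 0.5.
#' @slot backgroundLevel Background autofluorescence, arbitrary units.
#' @slot detectionFactor Detection threshold as a multiple of background.
#' @slot dropoutRate Per-neuron apoptotic loss probability.
#' @slot rootIntensity Absolute dye intensity assigned to the root RGP.
#' @slot processLossFraction One-time multiplicative dye loss at the root
#'   representing process-localised dye (default 0, i.e. off).
#' @export
setClass("NoiseModel", representation(
  daughterFractionSd = "numeric", fractionBounds = "numeric",
  backgroundLevel = "numeric", detectionFactor = "numeric",
  dropoutRate = "numeric", rootIntensity = "numeric",
  processLossFraction = "numeric"))

setValidity("NoiseModel", function(object) {
  b <- object@fractionBounds
  if (length(b) != 2 || b[1] >= 0.5 || b[2] <= 0.5)
    return("fractionBounds must be an interval containing 0.5")
  if (object@daughterFractionSd < 0) return("daughterFractionSd must be >= 0")
  if (object@daughterFractionSd >= (b[2] - b[1]) / 2)
    return("daughterFractionSd must be below half the bound width")
  if (object@dropoutRate < 0 || object@dropoutRate > 1)
    return("dropoutRate must lie in [0, 1]")
  if (object@detectionFactor < 1) return("detectionFactor must be >= 1")
  if (object@backgroundLevel <= 0) return("backgroundLevel must be positive")
  if (object@processLossFraction < 0 || object@processLossFraction >= 1)
    return("processLossFraction must lie in [0, 1)")
  TRUE
})

#' @param daughterFractionSd,fractionBounds,backgroundLevel,detectionFactor,dropoutRate,rootIntensity,processLossFraction
#'   see slot documentation.
#' @rdname NoiseModel-class
#' @return A [NoiseModel-class].
#' @export
NoiseModel <- function(daughterFractionSd = 0.03,
                       fractionBounds = c(0.1, 0.9),
                       backgroundLevel = 1,
                       detectionFactor = 2,
                       dropoutRate = 0.07,
                       rootIntensity = 1000,
                       processLossFraction = 0) {
  new("NoiseModel", daughterFractionSd = daughterFractionSd,
      fractionBounds = fractionBounds, backgroundLevel = backgroundLevel,
      detectionFactor = detectionFactor, dropoutRate = dropoutRate,
      rootIntensity = rootIntensity,
      processLossFraction = processLossFraction)
}

#' Spatial placement model for clonal neurons
#'
#' Clones form radial units: neurons share a narrow cortical column
#' (lateral dispersion `cloneColumnScale`, micrometres) and siblings
#' derived from the same IP cluster much more tightly
#' (`siblingClusterScale`). Radial depth follows the inside-out rule:
#' relative radial position (0 = pia, 1 = subplate) decreases with
#' effective birth order by `insideOutStrength` per step, with Gaussian
#' jitter `radialJitterSd`.
#'
#' @slot insideOutStrength Radial-position decrement per birth-order step.
#' @slot siblingClusterScale Same-IP sibling dispersion, micrometres.
#' @slot cloneColumnScale Clone column lateral dispersion, micrometres.
#' @slot radialJitterSd SD of jitter on relative radial position.
#' @export
setClass("SpatialModel", representation(
  insideOutStrength = "numeric", siblingClusterScale = "numeric",
  cloneColumnScale = "numeric", radialJitterSd = "numeric"))

setValidity("SpatialModel", function(object) {
  if (object@siblingClusterScale >= object@cloneColumnScale)
    return("siblingClusterScale must be smaller than cloneColumnScale")
  if (object@siblingClusterScale <= 0) return("scales must be positive")
  TRUE
})

#' @param insideOutStrength,siblingClusterScale,cloneColumnScale,radialJitterSd
#'   see slot documentation.
#' @rdname SpatialModel-class
#' @return A [SpatialModel-class].
#' @export
SpatialModel <- function(insideOutStrength = 0.1,
                         siblingClusterScale = 15,
                         cloneColumnScale = 120,
                         radialJitterSd = 0.04) {
  new("SpatialModel", insideOutStrength = insideOutStrength,
      siblingClusterScale = siblingClusterScale,
      cloneColumnScale = cloneColumnScale,
      radialJitterSd = radialJitterSd)
}

## ---- Clone / HierarchyAssignment ---------------------------------------

#' A clone of observed labelled cells
#'
#' @slot cloneId Clone identifier.
#' @slot cells data.frame of per-cell observations (the cell-table schema,
#'   see [readCellTable()]).
#' @slot region Cortical region (`"MC"`, `"SC"`, `"AC"`, `"VC"` or
#'   `"unknown"`).
#' @export
setClass("Clone", representation(
  cloneId = "character", cells = "data.frame", region = "character"))

setValidity("Clone", function(object) {
  if (nrow(object@cells) < 1) return("a clone must contain at least one cell")
  if (!all(object@cells$clone_id == object@cloneId))
    return("all cells must share the clone's clone_id")
  if (!object@region %in% .regions) return("unknown region code")
  TRUE
})

#' @param cells data.frame of cell records.
#' @param cloneId clone identifier (defaults to the cells' common id).
#' @param region cortical region code.
#' @rdname Clone-class
#' @return A [Clone-class].
#' @export
Clone <- function(cells, cloneId = as.character(cells$clone_id[1]),
                  region = "unknown") {
  cells$clone_id <- cloneId
  new("Clone", cloneId = cloneId, cells = cells, region = region)
}

#' Hierarchy assignment of cells to dye-intensity levels
#'
#' Level h has intensity phi1 / 2^(h-1), where phi1 is the brightest
#' observed intensity; each cell is assigned to the level nearest to its
#' intensity in log2 space.
#'
#' @slot phi1 Highest observed intensity.
#' @slot levels Named integer vector mapping cell_id to hierarchy index h.
#' @slot outliers Character vector of cell_ids flagged as off-level.
#' @export
setClass("HierarchyAssignment", representation(
  phi1 = "numeric", levels = "integer", outliers = "character"))

## ---- ReconstructionResult ----------------------------------------------

#' Result of reconstructing one clone
#'
#' @slot status One of `"unique"`, `"resolved_by_proximity"`,
#'   `"ambiguous"`, `"failed"`.
#' @slot trees List of canonical deduplicated candidate [LineageTree-class]s.
#' @slot chosen The selected tree, or `NULL` when ambiguous/failed.
#' @slot rootClassification Cell type of the root (`"RGP"` clones enter
#'   downstream RGP analyses; other types flag neuron/progenitor-labelled
#'   clones).
#' @export
setClass("ReconstructionResult", representation(
  status = "character", trees = "list", chosen = "ANY",
  rootClassification = "character"))

setValidity("ReconstructionResult", function(object) {
  if (!object@status %in%
      c("unique", "resolved_by_proximity", "ambiguous", "failed"))
    return("invalid status")
  if (object@status == "unique" && length(object@trees) != 1)
    return("status 'unique' requires exactly one tree")
  if (object@status == "ambiguous" &&
      (length(object@trees) < 2 || !is.null(object@chosen)))
    return("status 'ambiguous' requires >= 2 trees and no chosen tree")
  if (object@status == "failed" && length(object@trees) != 0)
    return("status 'failed' requires an empty tree list")
  TRUE
})

## ---- RunConfig ----------------------------------------------------------

#' Run configuration
#'
#' Bundles every tunable of the pipeline: master seed, simulator batch
#' geometry (default 258 lineages per batch, 100 batches), the clone-size
#' and transition models, noise/spatial/class generators, layer cut
#' points, and clustering settings.
#'
#' @slot seed Master seed.
#' @slot batchSize Lineages per batch.
#' @slot nBatches Number of batches.
#' @slot sizeModel A [CloneSizeModel-class].
#' @slot transitions A [TransitionMatrix-class].
#' @slot noise A [NoiseModel-class].
#' @slot spatial A [SpatialModel-class].
#' @slot classTable data.frame of class probabilities per
#'   (division pattern, layer) used by [assignClassesAndMarkers()].
#' @slot layerCuts Named numeric upper bounds on relative radial position
#'   for layers L2/3, L4, L5, L6.
#' @slot clusterK Number of clone clusters.
#' @slot maxWorkingSet Enumeration guard on the per-level working set.
#' @slot equalTol Relative tolerance for "highly similar" intensities.
#' @slot ntAsN Map terminal N/N divisions to N for transition estimation.
#' @export
setClass("RunConfig", representation(
  seed = "integer", batchSize = "integer", nBatches = "integer",
  sizeModel = "CloneSizeModel", transitions = "TransitionMatrix",
  noise = "NoiseModel", spatial = "SpatialModel",
  classTable = "data.frame", layerCuts = "numeric",
  clusterK = "integer", maxWorkingSet = "integer",
  equalTol = "numeric", ntAsN = "logical"))

setValidity("RunConfig", function(object) {
  if (object@batchSize < 1 || object@nBatches < 1)
    return("batch geometry must be positive")
  if (object@equalTol < 0 || object@equalTol > 1)
    return("equalTol must lie in [0, 1]")
  if (!identical(names(object@layerCuts), c("L2/3", "L4", "L5", "L6")))
    return("layerCuts must name L2/3, L4, L5, L6")
  if (is.unsorted(object@layerCuts) || object@layerCuts[4] != 1)
    return("layerCuts must be increasing and end at 1")
  TRUE
})

#' Default layer cut points on relative radial depth
#' @return Named numeric vector of layer upper bounds.
#' @export
defaultLayerCuts <- function()
  c("L2/3" = 0.35, "L4" = 0.5, "L5" = 0.75, "L6" = 1.0)

#' @param seed,batchSize,nBatches,sizeModel,transitions,noise,spatial,classTable,layerCuts,clusterK,maxWorkingSet,equalTol,ntAsN
#'   see slot documentation.
#' @rdname RunConfig-class
#' @return A [RunConfig-class].
#' @export
RunConfig <- function(seed = 1L, batchSize = 258L, nBatches = 100L,
                      sizeModel = CloneSizeModel(),
                      transitions = defaultTransitionMatrix(),
                      noise = NoiseModel(), spatial = SpatialModel(),
                      classTable = defaultClassTable(),
                      layerCuts = defaultLayerCuts(),
                      clusterK = 5L, maxWorkingSet = 12L,
                      equalTol = 0.15, ntAsN = TRUE) {
  new("RunConfig", seed = as.integer(seed),
      batchSize = as.integer(batchSize), nBatches = as.integer(nBatches),
      sizeModel = sizeModel, transitions = transitions, noise = noise,
      spatial = spatial, classTable = classTable, layerCuts = layerCuts,
      clusterK = as.integer(clusterK),
      maxWorkingSet = as.integer(maxWorkingSet),
      equalTol = equalTol, ntAsN = ntAsN)
}

## ---- generics and accessors --------------------------------------------

#' @rdname Clone-class
#' @param x object.
#' @export
setGeneric("cloneId", function(x) standardGeneric("cloneId"))
#' @rdname Clone-class
#' @export
setGeneric("cells", function(x) standardGeneric("cells"))
#' @rdname TransitionMatrix-class
#' @param x object.
#' @export
setGeneric("transProbs", function(x) standardGeneric("transProbs"))
#' @rdname LineageTree-class
#' @param x object.
#' @export
setGeneric("generations", function(x) standardGeneric("generations"))
#' @rdname LineageTree-class
#' @export
setGeneric("rootType", function(x) standardGeneric("rootType"))
#' @rdname LineageTree-class
#' @export
setGeneric("nNeurons", function(x) standardGeneric("nNeurons"))
#' @rdname ReconstructionResult-class
#' @param x object.
#' @export
setGeneric("reconStatus", function(x) standardGeneric("reconStatus"))
#' @rdname ReconstructionResult-class
#' @export
setGeneric("chosenTree", function(x) standardGeneric("chosenTree"))
#' @rdname ReconstructionResult-class
#' @export
setGeneric("candidateTrees", function(x) standardGeneric("candidateTrees"))
#' @rdname ReconstructionResult-class
#' @export
setGeneric("rootClassification",
           function(x) standardGeneric("rootClassification"))

#' @rdname Clone-class
#' @export
setMethod("cloneId", "Clone", function(x) x@cloneId)
#' @rdname LineageTree-class
#' @export
setMethod("cloneId", "LineageTree", function(x) x@cloneId)
#' @rdname Clone-class
#' @export
setMethod("cells", "Clone", function(x) x@cells)
#' @rdname TransitionMatrix-class
#' @export
setMethod("transProbs", "TransitionMatrix", function(x) x@probs)
#' @rdname LineageTree-class
#' @export
setMethod("generations", "LineageTree", function(x) x@generations)
#' @rdname LineageTree-class
#' @export
setMethod("rootType", "LineageTree", function(x) x@rootType)
#' @rdname LineageTree-class
#' @export
setMethod("nNeurons", "LineageTree",
          function(x) .countLeavesOfType(x@root, "NEURON"))
#' @rdname ReconstructionResult-class
#' @export
setMethod("reconStatus", "ReconstructionResult", function(x) x@status)
#' @rdname ReconstructionResult-class
#' @export
setMethod("chosenTree", "ReconstructionResult", function(x) x@chosen)
#' @rdname ReconstructionResult-class
#' @export
setMethod("candidateTrees", "ReconstructionResult", function(x) x@trees)
#' @rdname ReconstructionResult-class
#' @export
setMethod("rootClassification", "ReconstructionResult",
          function(x) x@rootClassification)

## ---- show methods -------------------------------------------------------

setMethod("show", "LineageTree", function(object) {
  cat(sprintf("LineageTree '%s' (root %s, %d neurons)\n",
              object@cloneId, object@rootType,
              .countLeavesOfType(object@root, "NEURON")))
  if (nrow(object@generations)) {
    cat("  generations:",
        paste(sprintf("G%d:%s", object@generations$generation,
                      object@generations$pattern), collapse = " "), "\n")
  }
  cat(.asciiTree(object@root), sep = "\n")
})

setMethod("show", "TransitionMatrix", function(object) {
  cat("TransitionMatrix (rows/cols IPP, IP, N; row-stochastic)\n")
  print(round(object@probs, 4))
})

setMethod("show", "Clone", function(object) {
  cat(sprintf("Clone '%s': %d cells (region %s)\n", object@cloneId,
              nrow(object@cells), object@region))
})

setMethod("show", "ReconstructionResult", function(object) {
  cat(sprintf("ReconstructionResult: status=%s, root=%s, %d candidate tree(s)\n",
              object@status, object@rootClassification,
              length(object@trees)))
})

setMethod("show", "CloneSizeModel", function(object) {
  cat("CloneSizeModel: zero-truncated Poisson mixture\n")
  cat(sprintf("  weights: %s\n  rates:   %s\n",
              paste(object@weights, collapse = ", "),
              paste(object@rates, collapse = ", ")))
})

setMethod("show", "RunConfig", function(object) {
  cat(sprintf("RunConfig: seed=%d, batches=%dx%d, k=%d\n", object@seed,
              object@nBatches, object@batchSize, object@clusterK))
})
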