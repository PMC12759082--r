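## Internal nested-list node representation.
##
## A node is a list with fields:
##   type     one of cellTypes()
##   ti       theoretical intensity as a fraction of the root (root = 1)
##   children NULL (leaf) or a list of exactly two nodes
##   cellId   observed cell id (NEURON leaves linked to observations)
##   obsIntensity measured intensity (synthetic/observed), NA otherwise
##   exit     TRUE for the unobserved cycle-exiting RGP placeholder leaf
##   terminal TRUE for a terminal self-consuming N/N division node
##   birthGen generation at which the cell came into existence
##   gen      generation of the RGP division that spawned the sublineage
##            (annotated on NEURON leaves)
##   origin   division pattern that spawned the leaf ("N", "IP", "IPP",
##            "NN_TERMINAL")

## fast internal LineageTree constructor: skips the recursive validity
## walk for trees that are valid by construction (simulator, enumerator)
.fastTree <- local({
  template <- NULL
  function(root, cloneId, generations = emptyGenerations()) {
    if (is.null(template))
      template <<- new("LineageTree",
                       root = .newNode("NEURON", 1), cloneId = "t",
                       rootType = "NEURON",
                       generations = emptyGenerations())
    t <- template
    t@root <- root
    t@cloneId <- cloneId
    t@rootType <- root$type
    t@generations <- generations
    t
  }
})

.newNode <- function(type, ti, children = NULL, cellId = NA_character_,
                     obsIntensity = NA_real_, exit = FALSE,
                     terminal = FALSE, birthGen = NA_integer_,
                     gen = NA_integer_, origin = NA_character_) {
  list(type = type, ti = ti, children = children, cellId = cellId,
       obsIntensity = obsIntensity, exit = exit, terminal = terminal,
       birthGen = birthGen, gen = gen, origin = origin)
}

.isLeaf <- function(node) is.null(node$children)

## recursive structural validation used by the LineageTree validity method
.validateNode <- function(node, expectTi) {
  if (!is.list(node) || is.null(node$type)) return("malformed node")
  if (!node$type %in% cellTypes()) return("invalid node cell type")
  if (!is.null(expectTi) && is.finite(expectTi) &&
      abs(node$ti - expectTi) > 1e-9 * max(1, abs(expectTi)))
    return("each child's theoretical intensity must equal half its parent's")
  if (.isLeaf(node)) {
    ok <- node$type == "NEURON" || (node$type == "RGP" && isTRUE(node$exit))
    if (!ok) return("leaves must be neurons or exit placeholders")
    return(NULL)
  }
  if (length(node$children) != 2) return("internal nodes must have 2 children")
  a <- node$children[[1]]; b <- node$children[[2]]
  comb <- combineTypes(a$type, b$type)
  permitted <- (!is.na(comb) && comb == node$type) ||
    (node$type == "RGP" && a$type == "NEURON" && b$type == "NEURON" &&
       isTRUE(node$terminal))
  if (!permitted)
    return(sprintf("child pair (%s, %s) cannot produce a %s node",
                   a$type, b$type, node$type))
  for (ch in node$children) {
    msg <- .validateNode(ch, expectTi = node$ti / 2)
    if (!is.null(msg)) return(msg)
  }
  NULL
}

.countLeavesOfType <- function(node, type) {
  if (.isLeaf(node)) return(as.integer(node$type == type && !isTRUE(node$exit)))
  sum(vapply(node$children, .countLeavesOfType, integer(1), type = type))
}

## collect leaves (as list of nodes), optionally skipping exit placeholders
.collectLeaves <- function(node, skipExit = TRUE) {
  if (.isLeaf(node)) {
    if (skipExit && isTRUE(node$exit)) return(list())
    return(list(node))
  }
  c(.collectLeaves(node$children[[1]], skipExit),
    .collectLeaves(node$children[[2]], skipExit))
}

.countTerminalNN <- function(node) {
  if (.isLeaf(node)) return(0L)
  as.integer(isTRUE(node$terminal)) +
    sum(vapply(node$children, .countTerminalNN, integer(1)))
}

.typeSymbol <- c(RGP = "g", IPP = "a", IP = "b", NEURON = "k")

## Canonical signature of a subtree. withCells = TRUE distinguishes trees
## that pair different observed neurons; FALSE gives the pure topology
## signature (types + terminal/exit flags).
.nodeSignature <- function(node, withCells = TRUE) {
  tag <- .typeSymbol[[node$type]]
  if (isTRUE(node$exit)) tag <- paste0(tag, "!")
  if (isTRUE(node$terminal)) tag <- paste0(tag, "*")
  if (.isLeaf(node)) {
    if (withCells && !is.na(node$cellId)) tag <- paste0(tag, ":", node$cellId)
    return(tag)
  }
  sigs <- sort(vapply(node$children, .nodeSignature, character(1),
                      withCells = withCells))
  paste0(tag, "(", sigs[1], ",", sigs[2], ")")
}

## Observable canonical signature: what reconstruction can recover from
## the observed neurons alone. Exit placeholders are dropped, unary nodes
## collapsed, and each retained node is tagged with its halving depth
## relative to the (collapsed) subtree root, so that e.g. a terminal N/N
## pair (two equal-level neurons) stays distinct from two N divisions at
## successive levels. Used to compare reconstructions with ground truth.
.observableSignature <- function(node) {
  pruned <- .pruneExits(node)
  if (is.null(pruned)) return("")
  .obsSig(pruned, depth = 0L)
}

.pruneExits <- function(node) {
  if (.isLeaf(node)) {
    if (isTRUE(node$exit)) return(NULL)
    return(node)
  }
  kids <- Filter(Negate(is.null), lapply(node$children, .pruneExits))
  if (length(kids) == 0) return(NULL)
  if (length(kids) == 1) return(kids[[1]])  # collapse unary chain
  node$children <- kids
  node
}

.obsSig <- function(node, depth) {
  tag <- paste0(.typeSymbol[[node$type]], depth)
  if (isTRUE(node$terminal)) tag <- paste0(tag, "*")
  if (.isLeaf(node)) return(tag)
  ## halving depth of each child = log2(parent ti / child ti) below parent
  sigs <- sort(vapply(node$children, function(ch) {
    d <- depth + as.integer(round(log2(node$ti / ch$ti)))
    .obsSig(ch, d)
  }, character(1)))
  paste0(tag, "(", paste(sigs, collapse = ","), ")")
}

.asciiTree <- function(node, prefix = "") {
  lab <- node$type
  if (isTRUE(node$exit)) lab <- paste0(lab, " (exit)")
  if (isTRUE(node$terminal)) lab <- paste0(lab, " (terminal N/N)")
  if (!is.na(node$cellId)) lab <- paste0(lab, " [", node$cellId, "]")
  lab <- sprintf("%s%s ti=%.4g", prefix, lab, node$ti)
  if (.isLeaf(node)) return(lab)
  c(lab,
    .asciiTree(node$children[[1]], paste0(prefix, "  ")),
    .asciiTree(node$children[[2]], paste0(prefix, "  ")))
}

## ---- intensity conservation --------------------------------------------

#' Per-generation theoretical intensity totals
#'
#' For a simulated (or annotated) lineage tree with birth generations on
#' every node, returns the sum of theoretical intensity fractions over all
#' cells extant after each generation: the self-renewed (or exited) RGP,
#' any live intermediate progenitors, and all neurons born so far. Because
#' every division splits the parental dye exactly in half, each total
#' equals the normalized root intensity (1) at every stage.
#'
#' @param tree A [LineageTree-class] whose nodes carry `birthGen`.
#' @return Numeric vector, one total per generation (1..max birth
#'   generation).
#' @export
intensityByGeneration <- function(tree) {
  gmax <- .maxBirthGen(tree@root)
  if (gmax < 1) return(numeric(0))
  vapply(seq_len(gmax), function(g) .extantSum(tree@root, g), numeric(1))
}

.maxBirthGen <- function(node) {
  g <- if (is.na(node$birthGen)) 0L else node$birthGen
  if (.isLeaf(node)) return(g)
  max(g, vapply(node$children, .maxBirthGen, integer(1)))
}

## sum of ti over the extant frontier at stage g: a node counts if it was
## born by g and has no children born by g
.extantSum <- function(node, g) {
  if (!is.na(node$birthGen) && node$birthGen > g) return(0)
  if (.isLeaf(node)) return(node$ti)
  kidsBorn <- vapply(node$children,
                     function(ch) !is.na(ch$birthGen) && ch$birthGen <= g,
                     logical(1))
  if (!any(kidsBorn)) return(node$ti)
  sum(vapply(node$children, .extantSum, numeric(1), g = g))
}

## ---- tree comparison ----------------------------------------------------

#' Compare two lineage trees on their observable topology
#'
#' Two trees match when their canonical observable signatures are equal:
#' exit placeholders are ignored, unary chains collapsed, children
#' unordered, and leaves matched up to exchanges of equal-intensity
#' neurons (leaf identities are not compared). This is the comparison used
#' to score reconstruction against simulated ground truth.
#'
#' @param a,b [LineageTree-class] objects.
#' @return `TRUE` when the observable topologies coincide.
#' @export
sameObservableTopology <- function(a, b) {
  identical(.observableSignature(a@root), .observableSignature(b@root))
}

#' Score a reconstruction against its ground-truth tree
#'
#' A reconstruction matches when it determines a single lineage topology
#' (all candidate trees may still differ in which equal-intensity neurons
#' occupy exchangeable leaves) and that topology equals the ground
#' truth's observable topology. Candidates differing only by
#' equal-intensity leaf exchanges describe the same division history, so
#' they do not count as disagreement.
#'
#' @param result A [ReconstructionResult-class].
#' @param truth The generating [LineageTree-class].
#' @return `TRUE` when the reconstruction recovers the ground-truth
#'   topology.
#' @export
matchesGroundTruth <- function(result, truth) {
  if (result@status == "failed" || length(result@trees) == 0) return(FALSE)
  sigs <- unique(vapply(result@trees,
                        function(t) .observableSignature(t@root),
                        character(1)))
  length(sigs) == 1 && identical(sigs, .observableSignature(truth@root))
}
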