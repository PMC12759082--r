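## Lineage tree reconstruction from dye-dilution intensities.
##
## Pipeline: hierarchy assignment (intensity halving levels) ->
## exhaustive bottom-up enumeration of valid pairings under the
## permitted/prohibited combination algebra -> canonical deduplication ->
## spatial proximity resolution -> generation annotation.

## ---- combination algebra ------------------------------------------------

#' Combine two sibling cell types into their parent type
#'
#' The combination algebra over \{RGP, IPP, IP, NEURON\}: any of the seven
#' RGP-producing pairs (an RGP with any partner, or two RGPs) yields an
#' RGP; two neurons yield an IP; two IPs yield an IPP. The remaining seven
#' ordered pairs (neuron/IP, neuron/IPP, IP/IPP in either order, and
#' IPP/IPP) are prohibited: they cannot be siblings of any division.
#' Exactly 9 of the 16 ordered pairs are permitted.
#'
#' @param a,b Cell types of the two siblings.
#' @return The parent cell type, or `NA_character_` for a prohibited pair.
#' @export
combineTypes <- function(a, b) {
  if (a == "RGP" || b == "RGP") return("RGP")
  if (a == "NEURON" && b == "NEURON") return("IP")
  if (a == "IP" && b == "IP") return("IPP")
  NA_character_
}

## ---- hierarchy assignment ----------------------------------------------

#' Assign observed cells to dye-intensity hierarchy levels
#'
#' The brightest observed intensity defines level 1 (phi1); level h has
#' intensity phi1 / 2^(h-1). Each cell is assigned to the nearest level in
#' log2 space, h = 1 + round(log2(phi1 / intensity)), which is
#' scale-consistent with per-division halving. Cells farther than
#' `outlierLogTol` (log2 units) from their nearest level are flagged as
#' outliers.
#'
#' @param cells data.frame with columns `cell_id` and `intensity`, or a
#'   named numeric vector of intensities.
#' @param outlierLogTol Log2 distance beyond which a cell is flagged.
#' @return A [HierarchyAssignment-class].
#' @export
assignHierarchies <- function(cells, outlierLogTol = 0.5) {
  if (is.numeric(cells)) {
    if (length(cells) == 0) stop("assignHierarchies: empty input")
    ids <- names(cells)
    if (is.null(ids)) ids <- paste0("cell", seq_along(cells))
    cells <- data.frame(cell_id = ids, intensity = as.numeric(cells),
                        stringsAsFactors = FALSE)
  }
  if (nrow(cells) == 0) stop("assignHierarchies: empty input")
  if (any(!is.finite(cells$intensity) | cells$intensity <= 0))
    stop("assignHierarchies: intensities must be positive")
  phi1 <- max(cells$intensity)
  lg <- log2(phi1 / cells$intensity)
  h <- as.integer(1 + round(lg))
  outliers <- cells$cell_id[abs(lg - (h - 1)) > outlierLogTol]
  levels <- h
  names(levels) <- cells$cell_id
  new("HierarchyAssignment", phi1 = phi1, levels = levels,
      outliers = as.character(outliers))
}

## ---- pairing enumeration ------------------------------------------------

## All unordered pairings of indices 1..n with at most one singleton (a
## singleton exists iff n is odd). Returns a list of
## list(pairs = list(c(i, j), ...), singleton = index or NULL).
.allPairings <- function(n) {
  if (n == 0) return(list(list(pairs = list(), singleton = NULL)))
  if (n %% 2 == 1) {
    out <- list()
    for (s in seq_len(n)) {
      rest <- setdiff(seq_len(n), s)
      for (pm in .perfectMatchings(rest))
        out[[length(out) + 1]] <- list(pairs = pm, singleton = s)
    }
    return(out)
  }
  lapply(.perfectMatchings(seq_len(n)),
         function(pm) list(pairs = pm, singleton = NULL))
}

## perfect matchings of an even index set ((n-1)!! of them)
.perfectMatchings <- function(idx) {
  if (length(idx) == 0) return(list(list()))
  first <- idx[1]
  out <- list()
  for (j in idx[-1]) {
    rest <- setdiff(idx, c(first, j))
    for (sub in .perfectMatchings(rest))
      out[[length(out) + 1]] <- c(list(c(first, j)), sub)
  }
  out
}

## ---- tree enumeration ---------------------------------------------------

#' Enumerate all lineage trees consistent with a hierarchy assignment
#'
#' Processes hierarchy levels from the deepest (dimmest) upward. At each
#' level the working set is the observed neurons at that level plus the
#' nodes generated from the level below; all unordered pairings with at
#' most one singleton are enumerated, each pair is resolved by
#' [combineTypes()], and a pairing containing a prohibited pair is
#' discarded. A neuron/neuron pair may resolve either as an IP or as a
#' terminal self-consuming RGP division; among complete trees only those
#' using the minimum number of terminal divisions are kept (the terminal
#' reading is invoked only where required to reach a single root). A
#' singleton neuron/IP/IPP is promoted to an RGP node at the next level
#' whose unobserved sibling is the cycle-exiting RGP; a singleton RGP is a
#' dead end. Recursion continues above the brightest level as needed and
#' terminates when a single root remains. Results are canonical and
#' deduplicated.
#'
#' @param assignment A [HierarchyAssignment-class].
#' @param cells data.frame with at least `cell_id` and `intensity`
#'   (positions are carried for later proximity resolution).
#' @param cloneId Clone identifier stamped on the trees.
#' @param maxWorkingSet Abort when any level's working set exceeds this
#'   size (combinatorial guard).
#' @param maxTrees Abort when more than this many completions accumulate.
#' @return List of canonical [LineageTree-class] objects (possibly empty
#'   on reconstruction failure).
#' @export
enumerateTrees <- function(assignment, cells, cloneId = "clone",
                           maxWorkingSet = 12L, maxTrees = 20000L) {
  if (is.numeric(cells))
    cells <- data.frame(cell_id = names(assignment@levels),
                        intensity = as.numeric(cells),
                        stringsAsFactors = FALSE)
  lv <- assignment@levels
  H <- max(lv)
  obs <- vector("list", H)
  for (h in seq_len(H)) {
    ids <- names(lv)[lv == h]
    obs[[h]] <- lapply(ids, function(id)
      .newNode("NEURON", ti = NA_real_, cellId = id,
               obsIntensity = cells$intensity[match(id, cells$cell_id)]))
  }
  env <- new.env(parent = emptyenv())
  env$roots <- list()
  env$visited <- new.env(parent = emptyenv())
  .enumLevel(list(), obs, H, env, maxWorkingSet, maxTrees)
  if (length(env$roots) == 0) return(list())
  trees <- lapply(env$roots, function(root)
    canonicalizeTree(.fastTree(.rescaleTi(root, 1), cloneId = cloneId)))
  ## deduplicate by canonical topology (equal-intensity leaf exchanges
  ## describe the same division history; see resolveByProximity)
  sigs <- vapply(trees, function(t) .nodeSignature(t@root, FALSE),
                 character(1))
  trees <- trees[!duplicated(sigs)]
  ## keep only trees using the minimal number of terminal N/N divisions
  nt <- vapply(trees, function(t) .countTerminalNN(t@root), integer(1))
  trees[nt == min(nt)]
}

## recursive level processor; carry = nodes generated for level h
.enumLevel <- function(carry, obs, h, env, maxWorkingSet, maxTrees) {
  ws <- if (h >= 1 && h <= length(obs)) c(carry, obs[[h]]) else carry
  n <- length(ws)
  if (n == 0) return(invisible())
  if (n == 1 && h <= 1) {           # single root, nothing observed above
    env$roots[[length(env$roots) + 1]] <- ws[[1]]
    if (length(env$roots) > maxTrees)
      stop("enumerateTrees: candidate tree limit exceeded")
    return(invisible())
  }
  if (n > maxWorkingSet)
    stop(sprintf(
      "enumerateTrees: working set of size %d at level %d exceeds the limit of %d",
      n, h, maxWorkingSet))
  wsSig <- vapply(ws, .nodeSignature, character(1), withCells = FALSE)
  key <- paste(h, paste(sort(wsSig), collapse = "|"), sep = "#")
  if (!is.null(env$visited[[key]])) return(invisible())
  env$visited[[key]] <- TRUE
  seenPairings <- new.env(parent = emptyenv())
  for (pairing in .allPairings(n)) {
    ## pairings inducing the same multiset of signature pairs are
    ## equivalent up to exchanges of equal-intensity cells: visit one
    pkey <- paste(c(sort(vapply(pairing$pairs, function(p)
      paste(sort(wsSig[p]), collapse = "+"), character(1))),
      if (!is.null(pairing$singleton)) wsSig[pairing$singleton]),
      collapse = "|")
    if (!is.null(seenPairings[[pkey]])) next
    seenPairings[[pkey]] <- TRUE
    options <- .resolvePairing(ws, pairing)
    if (is.null(options)) next
    for (combo in options)
      .enumLevel(combo, obs, h - 1L, env, maxWorkingSet, maxTrees)
  }
  invisible()
}

## resolve one pairing into the list of alternative next-level node sets;
## NULL when the pairing contains a prohibited pair or a dead-end singleton
.resolvePairing <- function(ws, pairing) {
  perPair <- list()
  for (p in pairing$pairs) {
    a <- ws[[p[1]]]; b <- ws[[p[2]]]
    tp <- combineTypes(a$type, b$type)
    alts <- list()
    if (!is.na(tp))
      alts[[1]] <- .newNode(tp, NA_real_, children = list(a, b))
    if (a$type == "NEURON" && b$type == "NEURON")
      alts[[length(alts) + 1]] <- .newNode("RGP", NA_real_,
                                           children = list(a, b),
                                           terminal = TRUE)
    if (length(alts) == 0) return(NULL)
    perPair[[length(perPair) + 1]] <- alts
  }
  single <- NULL
  if (!is.null(pairing$singleton)) {
    s <- ws[[pairing$singleton]]
    if (s$type == "RGP") return(NULL)     # the chain cannot skip a division
    single <- .newNode("RGP", NA_real_,
                       children = list(s, .newNode("RGP", NA_real_,
                                                   exit = TRUE)))
  }
  if (length(perPair) == 0)
    return(list(list(single)))
  grid <- do.call(expand.grid,
                  c(lapply(perPair, function(x) seq_along(x)),
                    list(KEEP.OUT.ATTRS = FALSE)))
  lapply(seq_len(nrow(grid)), function(r) {
    nodes <- lapply(seq_along(perPair),
                    function(i) perPair[[i]][[grid[r, i]]])
    if (!is.null(single)) nodes[[length(nodes) + 1]] <- single
    nodes
  })
}

## assign theoretical intensities top-down (root = 1)
.rescaleTi <- function(node, ti) {
  node$ti <- ti
  if (!.isLeaf(node))
    node$children <- lapply(node$children, .rescaleTi, ti = ti / 2)
  node
}

## ---- canonical form -----------------------------------------------------

#' Canonicalize a lineage tree
#'
#' Orders every node's children by a fixed total order on (cell type,
#' subtree signature), so that trees differing only by left-right child
#' swaps canonicalize identically, while trees pairing different observed
#' neurons remain distinct. Idempotent.
#'
#' @param tree A [LineageTree-class].
#' @return The canonical [LineageTree-class].
#' @export
canonicalizeTree <- function(tree) {
  tree@root <- .canonNode(tree@root)
  tree
}

.canonNode <- function(node) {
  if (.isLeaf(node)) return(node)
  node$children <- lapply(node$children, .canonNode)
  sigs <- vapply(node$children, .nodeSignature, character(1),
                 withCells = TRUE)
  node$children <- node$children[order(sigs)]
  node
}

## ---- proximity resolution ----------------------------------------------

#' Resolve equal-intensity ambiguity by spatial proximity
#'
#' Neurons derived from the same IP lie in closer proximity than other
#' clonal neurons. When the candidate trees determine a single topology,
#' the remaining freedom is which equal-intensity neurons form sibling
#' pairs: within each intensity level, the partition of cells into
#' sibling pairs (and unpaired slots) minimizing the total Euclidean
#' distance between sibling pairs is selected. If candidate topologies
#' differ, positions are missing while a choice exists, or two distinct
#' partitions tie exactly, the clone is reported ambiguous rather than
#' guessed.
#'
#' @param trees Nonempty list of canonical topology-distinct
#'   [LineageTree-class] objects (as returned by [enumerateTrees()]).
#' @param cells data.frame with `cell_id`, `x`, `y`, `z`.
#' @return A [ReconstructionResult-class] (not yet generation-annotated).
#' @export
resolveByProximity <- function(trees, cells) {
  stopifnot(length(trees) >= 1)
  rootTypes <- vapply(trees, function(t) t@rootType, character(1))
  rootCls <- if (length(unique(rootTypes)) == 1) rootTypes[1] else "RGP"
  topo <- vapply(trees, function(t) .nodeSignature(t@root, FALSE),
                 character(1))
  if (length(unique(topo)) > 1)
    return(new("ReconstructionResult", status = "ambiguous", trees = trees,
               chosen = NULL, rootClassification = rootCls))
  tree <- trees[[1]]
  fit <- .optimizeLeafAssignment(tree, cells)
  if (identical(fit$status, "ambiguous"))
    return(new("ReconstructionResult", status = "ambiguous",
               trees = fit$trees, chosen = NULL,
               rootClassification = rootCls))
  new("ReconstructionResult",
      status = if (fit$choice) "resolved_by_proximity" else "unique",
      trees = list(fit$tree), chosen = fit$tree,
      rootClassification = rootTypes[1])
}

## Reassign observed cells to the tree's equal-intensity leaf slots so
## that the total sibling-pair distance is minimal. Returns
## list(tree, choice = whether any real choice existed) or
## list(status = "ambiguous") on exact partition ties / missing positions.
.optimizeLeafAssignment <- function(tree, cells) {
  slots <- .leafSlots(tree@root)
  byLevel <- split(seq_len(nrow(slots)), slots$ti)
  assign <- list()
  choice <- FALSE
  havePos <- all(c("x", "y", "z") %in% names(cells)) &&
    !anyNA(cells[match(slots$cellId, cells$cell_id), c("x", "y", "z")])
  buildWith <- function(assign, lv, ids, part) {
    c(assign, list(list(lv = lv, ids = ids,
                        pairs = lapply(part$pairs, function(p) ids[p]),
                        loners = ids[part$loners])))
  }
  ambiguousPair <- function(assign, lv, ids, partA, partB, restLevels) {
    ## materialize two tied (or undecidable) leaf assignments
    mk <- function(part) {
      as2 <- buildWith(assign, lv, ids, part)
      for (lv2 in restLevels)
        as2 <- c(as2, list(list(lv = lv2, ids = slots$cellId[lv2],
                                pairs = list())))
      t2 <- tree
      t2@root <- .applyAssignment(t2@root, as2, slots, cells)
      canonicalizeTree(t2)
    }
    list(status = "ambiguous", trees = list(mk(partA), mk(partB)))
  }
  for (k in seq_along(byLevel)) {
    lv <- byLevel[[k]]
    ids <- slots$cellId[lv]
    pairSlots <- unique(slots$pairKey[lv][slots$pairKey[lv] != ""])
    m <- length(pairSlots)
    n <- length(ids)
    if (m == 0 || n < 2) {
      assign[[length(assign) + 1]] <- list(lv = lv, ids = ids,
                                           pairs = list())
      next
    }
    parts <- .pairPartitions(n, m)
    if (length(parts) > 1) {
      choice <- TRUE
      rest <- byLevel[-seq_len(k)]
      if (!havePos)
        return(ambiguousPair(assign, lv, ids, parts[[1]], parts[[2]],
                             rest))
      xyz <- as.matrix(cells[match(ids, cells$cell_id),
                             c("x", "y", "z")])
      sums <- vapply(parts, function(pp)
        sum(vapply(pp$pairs, function(p)
          sqrt(sum((xyz[p[1], ] - xyz[p[2], ])^2)), numeric(1))),
        numeric(1))
      best <- which(sums <= min(sums) + 1e-9)
      if (length(best) > 1)
        return(ambiguousPair(assign, lv, ids, parts[[best[1]]],
                             parts[[best[2]]], rest))
      part <- parts[[best]]
    } else part <- parts[[1]]
    assign <- buildWith(assign, lv, ids, part)
  }
  tree@root <- .applyAssignment(tree@root, assign, slots, cells)
  list(tree = canonicalizeTree(tree), choice = choice)
}

## describe the observed-neuron leaf slots of a tree: intensity level,
## and whether the slot belongs to an observed sibling pair
.leafSlots <- function(root) {
  rows <- list()
  walk <- function(node, pairKey) {
    if (.isLeaf(node)) {
      if (node$type == "NEURON" && !is.na(node$cellId))
        rows[[length(rows) + 1]] <<- data.frame(
          cellId = node$cellId, ti = node$ti, pairKey = pairKey,
          stringsAsFactors = FALSE)
      return(invisible())
    }
    a <- node$children[[1]]; b <- node$children[[2]]
    key <- if (.isLeaf(a) && .isLeaf(b) && a$type == "NEURON" &&
               b$type == "NEURON" && !is.na(a$cellId) && !is.na(b$cellId))
      paste0("p", length(rows)) else ""
    walk(a, key); walk(b, key)
  }
  walk(root, "")
  do.call(rbind, rows)
}

## all partitions of n items into m unordered pairs plus loners
.pairPartitions <- function(n, m) {
  rec <- function(remaining, m) {
    if (m == 0)
      return(list(list(pairs = list(), loners = remaining)))
    out <- list()
    first <- remaining[1]
    ## first is a loner (only if enough items remain to fill the pairs)
    if (length(remaining) - 1 >= 2 * m) {
      for (sub in rec(remaining[-1], m))
        out[[length(out) + 1]] <- list(pairs = sub$pairs,
                                       loners = c(first, sub$loners))
    }
    for (j in remaining[-1]) {
      rest <- setdiff(remaining, c(first, j))
      for (sub in rec(rest, m - 1))
        out[[length(out) + 1]] <- list(pairs = c(list(c(first, j)),
                                                 sub$pairs),
                                       loners = sub$loners)
    }
    out
  }
  rec(seq_len(n), m)
}

## rewrite the tree's leaf cell ids according to the chosen assignment
.applyAssignment <- function(root, assign, slots, cells) {
  env <- new.env(parent = emptyenv())
  env$queues <- lapply(assign, function(a)
    list(ti = slots$ti[a$lv[1]], pairs = a$pairs,
         loners = if (is.null(a$loners)) a$ids else a$loners))
  setLeaf <- function(node, id) {
    node$cellId <- id
    i <- match(id, cells$cell_id)
    if (!is.na(i) && "intensity" %in% names(cells))
      node$obsIntensity <- cells$intensity[i]
    node$assigned <- TRUE
    node
  }
  pop <- function(ti, what) {
    for (qi in seq_along(env$queues)) {
      q <- env$queues[[qi]]
      if (abs(q$ti - ti) < 1e-12) {
        if (what == "pair" && length(q$pairs)) {
          val <- q$pairs[[1]]
          env$queues[[qi]]$pairs <- q$pairs[-1]
          return(val)
        }
        if (what == "loner" && length(q$loners)) {
          val <- q$loners[1]
          env$queues[[qi]]$loners <- q$loners[-1]
          return(val)
        }
      }
    }
    NULL
  }
  assignPairs <- function(node) {
    if (.isLeaf(node)) return(node)
    a <- node$children[[1]]; b <- node$children[[2]]
    if (.isLeaf(a) && .isLeaf(b) && a$type == "NEURON" &&
        b$type == "NEURON" && !is.na(a$cellId) && !is.na(b$cellId)) {
      pr <- pop(a$ti, "pair")
      if (!is.null(pr)) {
        node$children[[1]] <- setLeaf(a, pr[1])
        node$children[[2]] <- setLeaf(b, pr[2])
      }
      return(node)
    }
    node$children <- lapply(node$children, assignPairs)
    node
  }
  assignLoners <- function(node) {
    if (.isLeaf(node)) {
      if (node$type == "NEURON" && !is.na(node$cellId) &&
          !isTRUE(node$assigned)) {
        id <- pop(node$ti, "loner")
        if (!is.null(id)) node <- setLeaf(node, id)
      }
      node$assigned <- NULL
      return(node)
    }
    node$children <- lapply(node$children, assignLoners)
    node
  }
  assignLoners(assignPairs(root))
}

## ---- generation annotation ---------------------------------------------

#' Annotate RGP-chain generations and division patterns
#'
#' Walks the RGP self-renewal chain from the root; the k-th chain division
#' is generation k, labelled by the non-chain daughter's type (neuron ->
#' N, IP -> IP, IPP -> IPP), a terminal neuron/neuron division ->
#' NN_TERMINAL, a symmetric RGP/RGP division -> SYMMETRIC, and the exit of
#' the chain from the cycle -> EXIT at the generation after the last
#' division. Every neuron leaf inherits the generation (and pattern) of
#' the RGP division that spawned its sublineage, and all nodes receive
#' birth generations.
#'
#' @param tree A [LineageTree-class] with an RGP root.
#' @return The annotated [LineageTree-class].
#' @export
annotateGenerations <- function(tree) {
  if (tree@rootType != "RGP")
    stop("annotateGenerations: root must be an RGP")
  gens <- list()
  tree@root$birthGen <- 0L
  walk <- function(node, g) {
    a <- node$children[[1]]; b <- node$children[[2]]
    if (isTRUE(node$terminal)) {        # terminal N/N division
      gens[[length(gens) + 1]] <<- list(g = g, p = "NN_TERMINAL")
      node$children <- lapply(node$children, .annotateProgeny,
                              g = g, origin = "NN_TERMINAL", depth = 0L)
      return(node)
    }
    if (a$type == "RGP" && b$type == "RGP" &&
        !(isTRUE(a$exit) || isTRUE(b$exit))) {
      gens[[length(gens) + 1]] <<- list(g = g, p = "SYMMETRIC")
      node$children[[1]]$birthGen <- g
      node$children[[2]]$birthGen <- g
      return(node)                      # symmetric split: chain undefined
    }
    chainIdx <- which(vapply(node$children,
                             function(ch) ch$type == "RGP", logical(1)))
    if (length(chainIdx) != 1)
      stop("annotateGenerations: malformed RGP chain")
    progIdx <- 3L - chainIdx
    prog <- node$children[[progIdx]]
    pattern <- switch(prog$type, NEURON = "N", IP = "IP", IPP = "IPP",
                      stop("annotateGenerations: invalid progeny type"))
    gens[[length(gens) + 1]] <<- list(g = g, p = pattern)
    node$children[[progIdx]] <- .annotateProgeny(prog, g = g,
                                                 origin = pattern,
                                                 depth = 0L)
    chain <- node$children[[chainIdx]]
    chain$birthGen <- g
    if (isTRUE(chain$exit)) {
      gens[[length(gens) + 1]] <<- list(g = g + 1L, p = "EXIT")
      node$children[[chainIdx]] <- chain
    } else {
      node$children[[chainIdx]] <- walk(chain, g + 1L)
    }
    node
  }
  if (.isLeaf(tree@root))
    stop("annotateGenerations: root has no divisions")
  tree@root <- walk(tree@root, 1L)
  tree@generations <- data.frame(
    generation = vapply(gens, function(x) as.integer(x$g), integer(1)),
    pattern = vapply(gens, function(x) x$p, character(1)),
    stringsAsFactors = FALSE)
  tree
}

## progeny of the generation-g division: neurons inherit gen = g; birth
## generations advance one step per intervening progenitor division
.annotateProgeny <- function(node, g, origin, depth) {
  node$birthGen <- g + depth
  if (node$type == "NEURON") {
    node$gen <- g
    node$origin <- origin
    return(node)
  }
  node$children <- lapply(node$children, .annotateProgeny, g = g,
                          origin = origin, depth = depth + 1L)
  node
}

## ---- full clone reconstruction -----------------------------------------

#' Reconstruct the lineage tree of one clone
#'
#' Composes [assignHierarchies()], [enumerateTrees()], canonical
#' deduplication, [resolveByProximity()] and [annotateGenerations()].
#' Clones of 1, 2 or 4 cells with highly similar intensities are
#' classified as neuron-, IP- or IPP-labelled respectively (the label
#' landed in a progenitor or postmitotic cell rather than an RGP) and
#' flagged non-RGP.
#'
#' @param clone A [Clone-class] (or data.frame of its cells).
#' @param equalTol Relative tolerance for "highly similar" intensities
#'   (default 15 percent around the common level).
#' @param maxWorkingSet,maxTrees Enumeration guards, see
#'   [enumerateTrees()].
#' @param outlierLogTol See [assignHierarchies()].
#' @return A [ReconstructionResult-class]; the chosen tree (when any) is
#'   generation-annotated.
#' @export
reconstructClone <- function(clone, equalTol = 0.15, maxWorkingSet = 12L,
                             maxTrees = 20000L, outlierLogTol = 0.5) {
  cellsDf <- if (is.data.frame(clone)) clone else cells(clone)
  id <- if (is.data.frame(clone)) as.character(cellsDf$clone_id[1])
        else cloneId(clone)
  n <- nrow(cellsDf)
  if (n %in% c(1L, 2L, 4L) && .allSimilar(cellsDf$intensity, equalTol))
    return(.nonRgpResult(cellsDf, id))
  assignment <- assignHierarchies(cellsDf, outlierLogTol = outlierLogTol)
  if (length(assignment@outliers))
    return(new("ReconstructionResult", status = "failed", trees = list(),
               chosen = NULL, rootClassification = "RGP"))
  trees <- tryCatch(
    enumerateTrees(assignment, cellsDf, cloneId = id,
                   maxWorkingSet = maxWorkingSet, maxTrees = maxTrees),
    error = function(e) list())
  if (length(trees) == 0)
    return(new("ReconstructionResult", status = "failed", trees = list(),
               chosen = NULL, rootClassification = "RGP"))
  res <- resolveByProximity(trees, cellsDf)
  if (!is.null(res@chosen) && res@chosen@rootType == "RGP" &&
      !.isLeaf(res@chosen@root))
    res@chosen <- annotateGenerations(res@chosen)
  res
}

.allSimilar <- function(intensity, tol) {
  if (length(intensity) == 1) return(TRUE)
  mid <- exp(mean(log(intensity)))
  all(abs(intensity - mid) <= tol * mid)
}

## canonical excluded-clone result: the label hit a neuron, IP or IPP
.nonRgpResult <- function(cellsDf, id) {
  n <- nrow(cellsDf)
  leaves <- lapply(seq_len(n), function(i)
    .newNode("NEURON", NA_real_, cellId = as.character(cellsDf$cell_id[i]),
             obsIntensity = cellsDf$intensity[i]))
  root <- if (n == 1) {
    leaves[[1]]
  } else if (n == 2) {
    .newNode("IP", NA_real_, children = leaves)
  } else {
    pick <- .closestQuadPairing(cellsDf)
    ips <- lapply(pick, function(pr)
      .newNode("IP", NA_real_, children = leaves[pr]))
    .newNode("IPP", NA_real_, children = ips)
  }
  tree <- canonicalizeTree(.fastTree(.rescaleTi(root, 1), cloneId = id))
  new("ReconstructionResult", status = "unique", trees = list(tree),
      chosen = tree, rootClassification = tree@rootType)
}

## pair four similar cells into two IP sibling pairs, preferring the
## pairing with the smallest total sibling distance when positions exist
.closestQuadPairing <- function(cellsDf) {
  pairings <- list(list(c(1, 2), c(3, 4)), list(c(1, 3), c(2, 4)),
                   list(c(1, 4), c(2, 3)))
  if (!all(c("x", "y", "z") %in% names(cellsDf)) ||
      anyNA(cellsDf[, c("x", "y", "z")]))
    return(pairings[[1]])
  xyz <- as.matrix(cellsDf[, c("x", "y", "z")])
  tot <- vapply(pairings, function(p)
    sum(vapply(p, function(pr) sqrt(sum((xyz[pr[1], ] - xyz[pr[2], ])^2)),
               numeric(1))), numeric(1))
  pairings[[which.min(tot)]]
}
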