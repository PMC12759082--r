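## Independent oracles used across the suite.

## closed-form moments of the zero-truncated Poisson
ztpMean <- function(lambda) lambda / (1 - exp(-lambda))
ztpVar <- function(lambda) {
  m <- ztpMean(lambda)
  m * (1 + lambda - m)
}

## all permutations of a vector (n <= 7)
allPerms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in allPerms(v[-i]))
      out[[length(out) + 1]] <- c(v[i], rest)
  out
}

## ---- literal permutation-based enumeration oracle ----------------------
##
## Reimplements the reconstruction recursion the literal way: for every
## permutation of the working set, adjacent cells are grouped in order
## (with the trailing singleton when the count is odd), groups are
## resolved by the combination rules (neuron pairs as IP or terminal RGP,
## singleton promotion with an exiting-RGP sibling, RGP singletons
## pruned), and recursion proceeds level by level. No pairing-class
## shortcuts and no memoization. Returns the set of canonical topology
## signatures of all single-root completions, filtered to the minimal
## number of terminal divisions.

oracleNode <- function(type, children = NULL, exit = FALSE,
                       terminal = FALSE) {
  list(type = type, children = children, exit = exit, terminal = terminal)
}

oracleSig <- function(node) {
  tag <- c(RGP = "g", IPP = "a", IP = "b", NEURON = "k")[[node$type]]
  if (node$exit) tag <- paste0(tag, "!")
  if (node$terminal) tag <- paste0(tag, "*")
  if (is.null(node$children)) return(tag)
  paste0(tag, "(", paste(sort(vapply(node$children, oracleSig,
                                     character(1))), collapse = ","), ")")
}

oracleNN <- function(node) {
  if (is.null(node$children)) return(0L)
  as.integer(node$terminal) +
    sum(vapply(node$children, oracleNN, integer(1)))
}

oracleEnumerate <- function(intensities) {
  a <- assignHierarchies(intensities)
  H <- max(a@levels)
  obs <- lapply(seq_len(H), function(h)
    replicate(sum(a@levels == h), oracleNode("NEURON"),
              simplify = FALSE))
  sigs <- new.env(parent = emptyenv())
  recurse <- function(carry, h) {
    ws <- if (h >= 1) c(carry, obs[[h]]) else carry
    n <- length(ws)
    if (n == 0) return(invisible())
    if (n == 1 && h <= 1) {
      root <- ws[[1]]
      key <- oracleSig(root)
      prev <- sigs[[key]]
      sigs[[key]] <- min(c(prev, oracleNN(root)))
      return(invisible())
    }
    for (perm in allPerms(seq_len(n))) {
      nodes <- ws[perm]
      groups <- list()
      k <- 1
      while (k + 1 <= n) {
        groups[[length(groups) + 1]] <- nodes[k:(k + 1)]
        k <- k + 2
      }
      singleton <- if (k == n) nodes[[n]] else NULL
      branches <- list(list())
      ok <- TRUE
      for (gp in groups) {
        tp <- combineTypes(gp[[1]]$type, gp[[2]]$type)
        alts <- list()
        if (!is.na(tp))
          alts[[1]] <- oracleNode(tp, children = gp)
        if (gp[[1]]$type == "NEURON" && gp[[2]]$type == "NEURON")
          alts[[length(alts) + 1]] <- oracleNode("RGP", children = gp,
                                                 terminal = TRUE)
        if (length(alts) == 0) { ok <- FALSE; break }
        branches <- unlist(lapply(branches, function(b)
          lapply(alts, function(alt) c(b, list(alt)))), recursive = FALSE)
      }
      if (!ok) next
      promoted <- NULL
      if (!is.null(singleton)) {
        if (singleton$type == "RGP") next
        promoted <- oracleNode("RGP",
                               children = list(singleton,
                                               oracleNode("RGP",
                                                          exit = TRUE)))
      }
      for (b in branches)
        recurse(c(b, if (!is.null(promoted)) list(promoted)), h - 1)
    }
    invisible()
  }
  recurse(list(), H)
  all <- as.list(sigs)
  if (length(all) == 0) return(character(0))
  nn <- vapply(all, identity, numeric(1))
  sort(names(all)[nn == min(nn)])
}

## canonical partition key of a pairing (pairs + singleton) for
## comparing pairing enumerations
partitionKey <- function(pairs, singleton = NULL) {
  paste(c(sort(vapply(pairs, function(p)
    paste(sort(p), collapse = "-"), character(1))),
    if (!is.null(singleton)) paste0("s", singleton)), collapse = "|")
}

## topology signature set of package enumeration for given intensities
packageTopologies <- function(intensities) {
  trees <- enumerateTrees(assignHierarchies(intensities), intensities)
  sort(unique(vapply(trees, function(t)
    DyeTrace:::.nodeSignature(t@root, FALSE), character(1))))
}

## simulate a small clean clone and return (tree, clone) for recovery
simulateCleanClone <- function(id, sd = 0, maxSize = 10, minSize = 1) {
  size <- drawCloneSize(1)
  while (size > maxSize || size < minSize) size <- drawCloneSize(1)
  tree <- simulateLineage(pynTarget = size, cloneId = id)
  syn <- synthesizeCellTable(list(tree),
                             noise = NoiseModel(daughterFractionSd = sd),
                             dropout = FALSE, threshold = FALSE)
  list(tree = tree, clone = syn$clones[[1]])
}
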