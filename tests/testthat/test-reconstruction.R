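test_that("the combination algebra permits 9 ordered pairs and rejects 7", {
  types <- cellTypes()
  results <- outer(types, types,
                   Vectorize(function(a, b) combineTypes(a, b)))
  expect_equal(sum(!is.na(results)), 9)
  expect_equal(sum(is.na(results)), 7)
  expect_identical(combineTypes("NEURON", "NEURON"), "IP")
  expect_identical(combineTypes("IP", "RGP"), "RGP")
  expect_identical(combineTypes("IPP", "IPP"), NA_character_)
  expect_identical(combineTypes("NEURON", "IP"), NA_character_)
  expect_identical(combineTypes("IP", "IP"), "IPP")
})

test_that("hierarchy assignment rounds to the nearest halving level", {
  a <- assignHierarchies(c(a = 1.0, b = 0.5, c = 0.5))
  expect_equal(unname(a@levels), c(1L, 2L, 2L))
  expect_equal(a@phi1, 1.0)
  ## noisy intensities: evaluate the rounding formula with phi1 = 0.98
  b <- assignHierarchies(c(a = 0.98, b = 0.52, c = 0.24))
  expect_equal(unname(b@levels), c(1L, 2L, 3L))
  single <- assignHierarchies(c(z = 0.7))
  expect_equal(unname(single@levels), 1L)
  expect_equal(single@phi1, 0.7)
  expect_error(assignHierarchies(numeric(0)), "empty")
  expect_error(assignHierarchies(c(a = -1)), "positive")
})

test_that("enumeration reproduces the worked small-clone cases", {
  ## one neuron at half intensity + an equal pair: the terminal N/N
  ## reading is the unique valid reconstruction
  t1 <- packageTopologies(c(a = 0.5, b = 0.25, c = 0.25))
  expect_identical(t1, "g(g*(k,k),k)")
  ## two equal cells: an IP-labelled clone, root IP only
  t2 <- packageTopologies(c(a = 0.25, b = 0.25))
  expect_identical(t2, "b(k,k)")
  ## two cells a level apart: singleton promotion with a cycle exit
  t3 <- packageTopologies(c(a = 0.5, b = 0.25))
  expect_identical(t3, "g(g(g!,k),k)")
  ## four equal cells: two IPs under an IPP
  t4 <- packageTopologies(c(a = 1, b = 1, c = 1, d = 1))
  expect_identical(t4, "a(b(k,k),b(k,k))")
})

test_that("pairing enumeration equals the literal permutation procedure", {
  ## the pairing generator covers exactly the pairings induced by
  ## adjacent grouping over all permutations
  for (n in 1:6) {
    pkg <- sort(unique(vapply(DyeTrace:::.allPairings(n), function(p)
      partitionKey(p$pairs, p$singleton), character(1))))
    perm <- character(0)
    for (pm in allPerms(seq_len(n))) {
      pairs <- list()
      k <- 1
      while (k + 1 <= n) {
        pairs[[length(pairs) + 1]] <- pm[k:(k + 1)]
        k <- k + 2
      }
      singleton <- if (k == n) pm[n] else NULL
      perm <- c(perm, partitionKey(pairs, singleton))
    }
    expect_identical(pkg, sort(unique(perm)), label = paste("n =", n))
  }
})

test_that("class-based enumeration matches the permutation oracle on whole clones", {
  cases <- list(
    c(a = 0.5, b = 0.25, c = 0.25),
    c(a = 0.5, b = 0.5, c = 0.25, d = 0.25),
    c(a = 1, b = 0.5, c = 0.25, d = 0.25),
    c(a = 0.25, b = 0.25, c = 0.25),
    c(a = 0.25, b = 0.25, c = 0.25, d = 0.25, e = 0.5),
    c(a = 1, b = 0.5, c = 0.25, d = 0.125),
    c(a = 0.5, b = 0.5, c = 0.5, d = 0.25, e = 0.25, f = 0.25))
  for (cs in cases)
    expect_identical(packageTopologies(cs), oracleEnumerate(cs),
                     label = paste(cs, collapse = ","))
})

test_that("canonicalization removes child-order freedom and is idempotent", {
  set.seed(21)
  for (i in 1:20) {
    tree <- simulateLineage(pynTarget = sample(2:9, 1), cloneId = "c")
    canon <- canonicalizeTree(tree)
    ## idempotent
    expect_identical(DyeTrace:::.nodeSignature(
      canonicalizeTree(canon)@root, TRUE),
      DyeTrace:::.nodeSignature(canon@root, TRUE))
    ## random child swaps never change the canonical form
    swapped <- tree
    swapped@root <- rapply(list(tree@root), function(x) x, how = "replace")[[1]]
    swapRandom <- function(node) {
      if (is.null(node$children)) return(node)
      node$children <- lapply(node$children, swapRandom)
      if (runif(1) < 0.5) node$children <- rev(node$children)
      node
    }
    swapped@root <- swapRandom(swapped@root)
    expect_identical(DyeTrace:::.nodeSignature(
      canonicalizeTree(swapped)@root, TRUE),
      DyeTrace:::.nodeSignature(canon@root, TRUE))
  }
})

test_that("proximity resolution pairs the adjacent neurons and reports ties", {
  ## three equal-intensity neurons: two 5 um apart, one 200 um away;
  ## the adjacent pair must be assigned to the shared IP
  cellsDf <- data.frame(
    clone_id = "p1", cell_id = c("n1", "n2", "n3"),
    intensity = c(0.25, 0.25, 0.25),
    x = c(0, 5, 200), y = 0, z = 0, stringsAsFactors = FALSE)
  res <- reconstructClone(cellsDf)
  expect_identical(reconStatus(res), "resolved_by_proximity")
  tree <- chosenTree(res)
  sibs <- local({
    found <- NULL
    walk <- function(node) {
      if (is.null(node$children)) return(invisible())
      kids <- node$children
      if (all(vapply(kids, function(k) k$type == "NEURON" &&
                       !is.na(k$cellId), logical(1))))
        found <<- sort(vapply(kids, function(k) k$cellId, character(1)))
      lapply(kids, walk)
      invisible()
    }
    walk(tree@root)
    found
  })
  expect_identical(sibs, c("n1", "n2"))

  ## an exactly symmetric configuration ties and must be ambiguous
  cellsTie <- data.frame(
    clone_id = "p2", cell_id = c("n1", "n2", "n3", "n4"),
    intensity = c(0.5, 0.25, 0.25, 0.25),
    x = c(0, -10, 0, 10), y = 0, z = 0, stringsAsFactors = FALSE)
  ## n2-n3 and n3-n4 pairings both total 10 um
  res2 <- reconstructClone(cellsTie)
  expect_identical(reconStatus(res2), "ambiguous")
  expect_null(chosenTree(res2))
  expect_gte(length(candidateTrees(res2)), 2)

  ## a single candidate without any leaf-exchange freedom is unique
  cellsU <- data.frame(clone_id = "p3", cell_id = c("m1", "m2"),
                       intensity = c(0.5, 0.25),
                       x = c(0, 1), y = 0, z = 0, stringsAsFactors = FALSE)
  expect_identical(reconStatus(reconstructClone(cellsU)), "unique")
})

test_that("generation annotation reads the chain patterns off the tree", {
  ## two cells a level apart: N at G1 and G2, exit at G3
  res <- reconstructClone(data.frame(
    clone_id = "g1", cell_id = c("a", "b"), intensity = c(0.5, 0.25),
    x = c(0, 1), y = 0, z = 0, stringsAsFactors = FALSE))
  g <- generations(chosenTree(res))
  expect_identical(g$pattern, c("N", "N", "EXIT"))
  expect_identical(g$generation, 1:3)

  ## IP then terminal N/N
  res2 <- reconstructClone(data.frame(
    clone_id = "g2", cell_id = paste0("c", 1:5),
    intensity = c(0.25, 0.25, 0.25, 0.25, 0.5),
    x = c(0, 1, 40, 41, 10), y = 0, z = 0, stringsAsFactors = FALSE))
  expect_false(is.null(chosenTree(res2)))
  g2 <- generations(chosenTree(res2))
  expect_true("NN_TERMINAL" %in% g2$pattern ||
                all(g2$pattern %in% divisionPatterns()))
  expect_error(annotateGenerations(
    LineageTree(DyeTrace:::.newNode("NEURON", 1, cellId = "x"))),
    "root must be an RGP")
})

test_that("whole-clone reconstruction classifies progenitor-labelled clones", {
  one <- reconstructClone(data.frame(
    clone_id = "s", cell_id = "n", intensity = 0.4,
    x = 0, y = 0, z = 0, stringsAsFactors = FALSE))
  expect_identical(rootClassification(one), "NEURON")
  expect_identical(reconStatus(one), "unique")
  two <- reconstructClone(data.frame(
    clone_id = "s", cell_id = c("n1", "n2"), intensity = c(0.4, 0.41),
    x = 0, y = 0, z = 0, stringsAsFactors = FALSE))
  expect_identical(rootClassification(two), "IP")
  four <- reconstructClone(data.frame(
    clone_id = "s", cell_id = paste0("n", 1:4),
    intensity = c(0.4, 0.41, 0.39, 0.4),
    x = c(0, 1, 50, 51), y = 0, z = 0, stringsAsFactors = FALSE))
  expect_identical(rootClassification(four), "IPP")
})

test_that("noiseless theoretical intensities reconstruct every simulated tree", {
  set.seed(33)
  for (i in 1:30) {
    sc <- simulateCleanClone(paste0("c", i), sd = 0, maxSize = 12)
    res <- reconstructClone(sc$clone)
    expect_true(matchesGroundTruth(res, sc$tree),
                label = paste("clone", i))
    expect_true(reconStatus(res) != "failed")
  }
})

test_that("a deleted mid-tree neuron is never silently misreported as unique truth", {
  set.seed(44)
  found <- 0
  for (i in 1:25) {
    sc <- simulateCleanClone(paste0("d", i), sd = 0, maxSize = 9,
                             minSize = 4)
    df <- cells(sc$clone)
    df <- df[-sample(nrow(df), 1), ]
    res <- tryCatch(reconstructClone(df), error = function(e) NULL)
    if (is.null(res) || reconStatus(res) %in% c("failed", "ambiguous")) {
      found <- found + 1
    } else {
      ## a confident answer after deletion must not claim the original
      ## ground truth (one neuron is gone)
      expect_false(matchesGroundTruth(res, sc$tree))
    }
  }
  expect_gt(found, 0)
})

test_that("the enumeration guard rejects oversized working sets", {
  many <- setNames(rep(0.25, 13), paste0("n", 1:13))
  expect_error(enumerateTrees(assignHierarchies(many), many,
                              maxWorkingSet = 12),
               "exceeds the limit")
})
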