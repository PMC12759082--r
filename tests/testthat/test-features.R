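test_that("neuron classes follow the marker precedence rules", {
  expect_identical(classifyCellType("+", "-", "-", "L2/3"), "CPN")
  expect_identical(classifyCellType("-", "-", "+", "L6"), "CThPN")
  expect_identical(classifyCellType("+", "+", "-", "L5"), "HPN")
  expect_identical(classifyCellType("-", "+", "-", "L5"), "SCPN")
  expect_identical(classifyCellType("?", "?", "?", "unknown"), "unknown")
  expect_identical(classifyCellType("-", "-", "-", "SP"), "SPN")
  ## Fog2 takes precedence over co-expression
  expect_identical(classifyCellType("+", "+", "+", "L5"), "CThPN")
  ## vectorized
  expect_identical(
    classifyCellType(c("+", "-"), c("-", "+"), c("-", "-"),
                     c("L2/3", "L5")), c("CPN", "SCPN"))
})

test_that("the seven laminar classes partition layered clones", {
  mk <- function(layers) data.frame(
    clone_id = "c", cell_id = paste0("n", seq_along(layers)),
    intensity = 1, layer = layers, stringsAsFactors = FALSE)
  expect_identical(as.character(laminarClass(mk(c("L2/3", "L5")))), "SL+L5")
  expect_identical(as.character(laminarClass(mk(c("L4", "L6", "L6")))),
                   "SL+L6")
  expect_identical(as.character(laminarClass(mk(c("L2/3", "L5", "L6")))),
                   "SL+L5+L6")
  expect_identical(as.character(laminarClass(mk("L6"))), "L6-only")
  expect_identical(as.character(laminarClass(mk(c("L2/3", "L2/3")))),
                   "L2/3-only")
  ## multi-layer same-side clones map to the deepest layer, flagged
  deepOnly <- laminarClass(mk(c("L5", "L6")))
  expect_identical(as.character(deepOnly), "L6-only")
  expect_true(attr(deepOnly, "flagged"))
  expect_error(laminarClass(mk("unknown")), "known cortical layer")
  ## every combination lands in one of the seven classes
  layers <- c("L2/3", "L4", "L5", "L6")
  seven <- c("SL+L5", "SL+L6", "SL+L5+L6", "L2/3-only", "L4-only",
             "L5-only", "L6-only")
  for (n in 1:4) {
    combos <- combn(layers, n, simplify = FALSE)
    for (cb in combos)
      expect_true(as.character(laminarClass(mk(cb))) %in% seven)
  }
})

test_that("feature extraction computes the documented 20 components", {
  ## four CPN neurons in L2/3 from a single IPP division
  root <- DyeTrace:::.buildChain("IPP", 1L, ti = 1, cellPrefix = "f")
  tree <- LineageTree(root, cloneId = "f",
                      generations = data.frame(
                        generation = 1:2, pattern = c("IPP", "EXIT"),
                        stringsAsFactors = FALSE))
  df <- data.frame(clone_id = "f", cell_id = paste0("n", 1:4),
                   intensity = 0.125, x = 1:4, y = 1, z = 1,
                   rel_radial_pos = 0.2, layer = "L2/3", satb2 = "+",
                   ctip2 = "-", fog2 = "-", neuron_class = "CPN",
                   apoptotic = FALSE, region = "unknown",
                   stringsAsFactors = FALSE)
  v <- extractFeatures(df, tree)
  expect_identical(names(v), cloneFeatureNames())
  expect_equal(unname(v["cloneSize"]), 4)
  expect_equal(unname(v["fracDivIPP"]), 1)
  expect_equal(unname(v["fracNeuronsIPP"]), 1)
  expect_equal(unname(v["fracSL"]), 1)
  expect_equal(unname(v["fracCPN"]), 1)
  expect_equal(unname(v["translaminar"]), 0)
  expect_equal(unname(v["meanRelRadialPos"]), 0.2)
  ## invariant under uniform spatial translation
  df2 <- df
  df2$x <- df2$x + 500
  df2$z <- df2$z - 120
  expect_identical(extractFeatures(df2, tree), v)
  ## identical clones give identical vectors
  expect_identical(extractFeatures(df, tree), extractFeatures(df, tree))
})

test_that("Ward clustering is deterministic, order invariant and exact on blobs", {
  set.seed(71)
  blob <- rbind(matrix(rnorm(40 * 20, 0), ncol = 20),
                matrix(rnorm(40 * 20, 6), ncol = 20))
  truth <- rep(1:2, each = 40)
  cc <- clusterClones(blob, k = 2)
  expect_equal(mclust::adjustedRandIndex(cc$labels, truth), 1)
  ## permuting the input rows permutes labels consistently
  perm <- sample(nrow(blob))
  cc2 <- clusterClones(blob[perm, ], k = 2)
  agree <- mclust::adjustedRandIndex(cc2$labels, truth[perm])
  expect_equal(agree, 1)
  ## duplicated clones receive identical labels
  dup <- rbind(blob, blob[1:5, ])
  cc3 <- clusterClones(dup, k = 2)
  expect_identical(unname(cc3$labels[81:85]), unname(cc3$labels[1:5]))
  expect_error(clusterClones(blob[1:3, ], k = 5), "at least k")
})

test_that("cluster summaries aggregate exactly and find the IPP-rich stratum", {
  set.seed(72)
  pop <- simulateArchetypePopulation(12, seed = 72)
  fm <- t(vapply(seq_along(pop$clones), function(i)
    extractFeatures(pop$clones[[i]], pop$trees[[i]]), numeric(20)))
  cc <- clusterClones(fm, k = 5)
  summ <- clusterSummaries(cc, pop$clones, pop$trees)
  expect_equal(nrow(summ), 5)
  ## totals aggregate to the whole dataset
  allCells <- do.call(rbind, lapply(pop$clones, cells))
  expect_equal(sum(summ$neuronsDL + summ$neuronsSL),
               sum(allCells$layer %in% c("L2/3", "L4", "L5", "L6")))
  expect_equal(sum(summ$nClones), length(pop$clones))
  ## the cluster holding the indirect-amplification archetypes shows the
  ## highest IPP-derived neuron fraction
  ippArch <- which(pop$labels %in% c(3, 4))  # the IPP-heavy archetypes
  domCluster <- as.integer(names(which.max(table(cc$labels[ippArch]))))
  expect_equal(which.max(summ$ippNeuronFraction) %in%
                 sort(unique(cc$labels[ippArch])), TRUE)
  ## a pure-CPN superficial cluster reports the "only CPN" combination
  cpnCluster <- summ$cluster[which.max(summ$fracCPN)]
  expect_identical(summ$dominantCombo[summ$cluster == cpnCluster],
                   "only CPN")
})
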