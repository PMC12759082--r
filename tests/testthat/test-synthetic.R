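test_that("partition noise conserves parental intensity exactly", {
  set.seed(31)
  tree <- simulateLineage(pynTarget = 8, cloneId = "n")
  noisy <- assignNoisyIntensities(tree, NoiseModel(daughterFractionSd = 0.05))
  check <- function(node) {
    if (is.null(node$children)) return(invisible())
    kids <- vapply(node$children, function(k) k$obsIntensity, numeric(1))
    expect_equal(sum(kids), node$obsIntensity, tolerance = 1e-12)
    lapply(node$children, check)
    invisible()
  }
  check(noisy@root)
  ## zero noise reproduces the theoretical halving exactly
  exact <- assignNoisyIntensities(tree, NoiseModel(daughterFractionSd = 0,
                                                   rootIntensity = 1))
  walk <- function(node) {
    expect_identical(node$obsIntensity, node$ti)
    if (!is.null(node$children)) lapply(node$children, walk)
    invisible()
  }
  walk(exact@root)
})

test_that("positions follow the inside-out rule and tight sibling clusters", {
  set.seed(32)
  tree <- simulateLineage(pynTarget = 9, cloneId = "p")
  ## zero jitter: radial position strictly decreases with birth order
  flat <- assignPositions(tree, SpatialModel(radialJitterSd = 0))
  leaves <- Filter(function(l) l$type == "NEURON",
                   DyeTrace:::.collectLeaves(flat@root))
  b <- vapply(leaves, DyeTrace:::.effectiveBirthOrder, integer(1))
  rrp <- vapply(leaves, function(l) l$rrp, numeric(1))
  ord <- order(b)
  expect_true(all(diff(rrp[ord][!duplicated(b[ord])]) < 0))
  ## sibling pairs sit closer than non-sibling pairs on average
  set.seed(33)
  sibD <- c(); otherD <- c()
  for (i in 1:30) {
    t2 <- assignPositions(
      assignNoisyIntensities(simulateLineage(pynTarget = 8,
                                             cloneId = "s")),
      SpatialModel())
    lv <- Filter(function(l) l$type == "NEURON",
                 DyeTrace:::.collectLeaves(t2@root))
    if (length(lv) < 3) next
    xyz <- t(vapply(lv, function(l) c(l$x, l$y, l$z), numeric(3)))
    gen <- vapply(lv, function(l) l$gen, integer(1))
    org <- vapply(lv, function(l) l$origin, character(1))
    for (a in 1:(length(lv) - 1)) for (bb in (a + 1):length(lv)) {
      d <- sqrt(sum((xyz[a, ] - xyz[bb, ])^2))
      if (org[a] == "IP" && org[bb] == "IP" && gen[a] == gen[bb])
        sibD <- c(sibD, d)
      else otherD <- c(otherD, d)
    }
  }
  expect_lt(mean(sibD), mean(otherD))
})

test_that("layer cut points partition the unit depth interval", {
  rr <- seq(0, 1, by = 0.001)
  layers <- layerFromRrp(rr)
  expect_false(any(is.na(layers)))
  expect_identical(sort(unique(layers)), sort(c("L2/3", "L4", "L5", "L6")))
  expect_identical(layerFromRrp(c(0, 0.349, 0.35, 0.5, 0.75, 1)),
                   c("L2/3", "L2/3", "L4", "L5", "L6", "L6"))
})

test_that("marker assignment is exactly inverted by classifyCellType", {
  set.seed(35)
  trees <- lapply(1:12, function(i)
    simulateLineage(pynTarget = 2 + i %% 8, cloneId = paste0("m", i)))
  syn <- synthesizeCellTable(trees, dropout = FALSE, threshold = FALSE)
  df <- syn$cells
  called <- classifyCellType(df$satb2, df$ctip2, df$fog2, df$layer)
  expect_identical(called, df$neuron_class)
  ## degenerate table: every neuron is a marker-consistent CPN
  allCpn <- data.frame(pattern = "any",
                       layer = c("L2/3", "L4", "L5", "L6"),
                       CPN = 1, SCPN = 0, CThPN = 0, HPN = 0)
  syn2 <- synthesizeCellTable(trees[1:3], classTable = allCpn,
                              dropout = FALSE, threshold = FALSE)
  expect_true(all(syn2$cells$neuron_class == "CPN"))
  expect_true(all(syn2$cells$satb2 == "+" & syn2$cells$ctip2 == "-" &
                    syn2$cells$fog2 == "-"))
})

test_that("class frequencies follow the probability table", {
  set.seed(36)
  tab <- data.frame(pattern = "any", layer = c("L2/3", "L4", "L5", "L6"),
                    CPN = c(1, 1, 0.25, 0.5), SCPN = c(0, 0, 0.5, 0),
                    CThPN = c(0, 0, 0, 0.5), HPN = c(0, 0, 0.25, 0))
  trees <- lapply(1:400, function(i)
    simulateLineage(pynTarget = 6, cloneId = paste0("f", i)))
  syn <- synthesizeCellTable(trees, classTable = tab, dropout = FALSE,
                             threshold = FALSE)
  l5 <- syn$cells[syn$cells$layer == "L5", ]
  freq <- table(factor(l5$neuron_class, c("CPN", "SCPN", "HPN")))
  expect_lt(max(abs(freq / sum(freq) - c(0.25, 0.5, 0.25))), 0.05)
})

test_that("dropout and detection thresholding behave as specified", {
  set.seed(37)
  cellsDf <- data.frame(clone_id = "d", cell_id = paste0("c", 1:10000),
                        intensity = rep(c(10, 1), 5000),
                        stringsAsFactors = FALSE)
  ## dropout fraction approximates its rate
  out <- applyDropoutAndThreshold(cellsDf,
                                  NoiseModel(dropoutRate = 0.07,
                                             backgroundLevel = 1e-9))
  expect_lt(abs(mean(out$truth$apoptotic) - 0.07), 0.01)
  ## huge background with zero dropout empties the table
  none <- applyDropoutAndThreshold(cellsDf,
                                   NoiseModel(dropoutRate = 0,
                                              backgroundLevel = 1e9))
  expect_equal(nrow(none$observed), 0)
  ## monotone: raising the detection factor never adds cells
  lo <- applyDropoutAndThreshold(cellsDf, NoiseModel(dropoutRate = 0,
                                                     detectionFactor = 2))
  hi <- applyDropoutAndThreshold(cellsDf, NoiseModel(dropoutRate = 0,
                                                     detectionFactor = 8))
  expect_true(all(hi$observed$cell_id %in% lo$observed$cell_id))
})

test_that("the full generator is identifiable end to end without losses", {
  set.seed(38)
  nOk <- 0L
  for (i in 1:25) {
    sc <- simulateCleanClone(paste0("e", i), sd = 0.01, maxSize = 10)
    res <- reconstructClone(sc$clone)
    if (matchesGroundTruth(res, sc$tree)) nOk <- nOk + 1L
  }
  expect_identical(nOk, 25L)
})
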