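genTable <- function(patterns) {
  data.frame(generation = seq_along(patterns), pattern = patterns,
             stringsAsFactors = FALSE)
}

test_that("generation summaries tally patterns, exits and attribution", {
  gs <- summarizeGenerations(list(genTable(c("IP", "N", "EXIT"))))
  expect_equal(gs$propIP[1], 1)
  expect_equal(gs$propN[2], 1)
  expect_equal(gs$exitFraction[3], 1)
  ## an IPP division at G2 contributes four neurons to G2's output
  gs2 <- summarizeGenerations(list(genTable(c("N", "IPP", "EXIT"))))
  expect_equal(gs2$outputTotal, c(1, 4, 0))
  ## G1 frequencies of a simulated batch follow the renormalized uniform law
  set.seed(41)
  tabs <- lapply(1:4000, function(i) simulatePatternSequence())
  gs3 <- summarizeGenerations(tabs)
  sizes <- vapply(tabs, function(t)
    sum(c(N = 1, IP = 2, IPP = 4)[t$pattern[t$pattern != "EXIT"]]),
    numeric(1))
  pBig <- mean(sizes >= 4)         # all three patterns feasible
  pMid <- mean(sizes %in% 2:3)     # IP and N only
  expected <- c(IPP = pBig / 3, IP = pBig / 3 + pMid / 2,
                N = pBig / 3 + pMid / 2 + mean(sizes == 1))
  expect_equal(c(gs3$propIPP[1], gs3$propIP[1], gs3$propN[1]),
               unname(expected), tolerance = 0.03)
})

test_that("decay fitting is exact, scale invariant and flags zeros", {
  s <- data.frame(generation = 1:4, outputMean = c(8, 4, 2, 1))
  fit <- fitDecay(s)
  expect_equal(fit$lambda, -log(2), tolerance = 1e-12)
  expect_false(fit$flagged)
  ## constant series: zero decay
  s2 <- data.frame(generation = 1:5, outputMean = rep(3, 5))
  expect_equal(fitDecay(s2)$lambda, 0, tolerance = 1e-10)
  ## scaling the series leaves lambda unchanged
  s3 <- s
  s3$outputMean <- s3$outputMean * 57.3
  expect_equal(fitDecay(s3)$lambda, fit$lambda, tolerance = 1e-10)
  ## nonpositive means fall back to the log-linear fit, flagged
  s4 <- data.frame(generation = 1:4, outputMean = c(8, 4, 0, 1))
  expect_true(fitDecay(s4)$flagged)
  expect_error(fitDecay(data.frame(generation = 1:2,
                                   outputMean = c(2, 1))), "3 generations")
})

test_that("transition counting and tests behave on canonical cases", {
  ## a single N,N,N lineage: two counts in the (N, N) cell
  est <- estimateTransitions(list(genTable(c("N", "N", "N", "EXIT"))))
  expect_equal(est$counts["N", "N"], 2)
  expect_equal(sum(est$counts), 2)
  expect_true(est$exitCounts["G4"] == 1)
  ## empty rows are flagged and excluded
  expect_false(all(est$rowDefined))
  expect_null(est$matrix)
  ## identical per-intergeneration rows give homogeneity p of 1
  tabs <- rep(list(genTable(c("N", "N", "N", "N", "EXIT")),
                   genTable(c("N", "IP", "N", "IP", "EXIT")),
                   genTable(c("IP", "N", "IP", "N", "EXIT"))), 10)
  estH <- estimateTransitions(tabs, maxGeneration = 4)
  hN <- estH$homogeneity[["N"]]
  expect_false(is.null(hN))
  expect_gt(hN$p.value, 0.99)
})

test_that("the transition estimator is consistent as lineages accumulate", {
  p <- defaultTransitionMatrix()
  errAt <- function(n, seed) {
    set.seed(seed)
    tabs <- lapply(seq_len(n), function(i) simulatePatternSequence(p))
    est <- estimateTransitions(tabs, unconstrainedOnly = TRUE)
    max(abs(transProbs(est$matrix) - transProbs(p)))
  }
  e3 <- errAt(1000, 52)
  e4 <- errAt(10000, 52)
  expect_lt(e4, e3)
  expect_lt(e4, 0.02)
})

test_that("KL divergence matches closed forms and its axioms", {
  expect_equal(klDivergence(c(0.5, 0.5), c(0.25, 0.75), pseudocount = 0),
               0.5 * log(2) + 0.5 * log(2 / 3))
  expect_equal(klDivergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  ## asymmetry on the same pair
  expect_false(isTRUE(all.equal(
    klDivergence(c(0.5, 0.5), c(0.25, 0.75), 0),
    klDivergence(c(0.25, 0.75), c(0.5, 0.5), 0))))
  ## nonnegativity and finiteness on random vectors with zeros
  set.seed(61)
  for (i in 1:200) {
    p <- rpois(6, 3)
    q <- rpois(6, 3)
    d <- klDivergence(p, q)
    expect_true(is.finite(d))
    expect_gte(d, 0)
  }
  expect_error(klDivergence(c(1, 0), c(1, 0, 0)), "equal length")
})

test_that("the mixture fitter recovers parameters and flags degeneracy", {
  set.seed(62)
  sizes <- drawCloneSize(5000)
  fit <- fitPoissonMixture(sizes)
  expect_lt(max(abs(fit$weights - c(0.35, 0.65))), 0.05)
  expect_lt(abs(fit$rates[1] - 4.09), 0.3)
  expect_lt(abs(fit$rates[2] - 7.62), 0.3)
  expect_gt(fit$gof$p.value, 0.01)
  ## single-component truth fit with two components: gof not small
  set.seed(63)
  single <- rztpois(3000, 6)
  fit1 <- fitPoissonMixture(single)
  ## the two components collapse onto the single truth: the fitted
  ## mixture mean matches the one-component closed form and fits well
  mixMean <- sum(fit1$weights * ztpMean(fit1$rates))
  expect_equal(mixMean, ztpMean(6), tolerance = 0.02)
  expect_gt(fit1$gof$p.value, 0.01)
  ## all sizes equal: degenerate flag
  expect_true(fitPoissonMixture(rep(4, 30))$degenerate)
  expect_error(fitPoissonMixture(1:10), ">= 20")
})

test_that("cumulative distance analysis separates sibling-clustered clones", {
  set.seed(64)
  dominated <- 0
  for (i in 1:15) {
    tree <- simulateLineage(pynTarget = 8, cloneId = paste0("cd", i))
    syn <- synthesizeCellTable(list(tree),
                               spatial = SpatialModel(
                                 siblingClusterScale = 5,
                                 cloneColumnScale = 300),
                               dropout = FALSE, threshold = FALSE)
    cd <- cumulativeDistance(syn$clones[[1]])
    if (cd$flagged) next
    if (length(cd$other) && median(cd$within) < median(cd$other))
      dominated <- dominated + 1
  }
  expect_gt(dominated, 10)
  ## all cells at one point: both curves step at 0, KS statistic 0
  same <- Clone(data.frame(clone_id = "z", cell_id = c("a", "b", "c", "d"),
                           intensity = c(0.5, 0.5, 0.25, 0.25),
                           x = 1, y = 2, z = 3, stringsAsFactors = FALSE))
  cd0 <- cumulativeDistance(same)
  expect_equal(unname(cd0$ks$statistic), 0)
  expect_true(all(cd0$within == 0))
  ## two singleton levels: flagged undefined
  lonely <- Clone(data.frame(clone_id = "l", cell_id = c("a", "b"),
                             intensity = c(0.5, 0.25),
                             x = 0:1, y = 0, z = 0,
                             stringsAsFactors = FALSE))
  expect_true(cumulativeDistance(lonely)$flagged)
})
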