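## Population-level clonal statistics over annotated lineage trees.

.neuronOutput <- c(N = 1L, IP = 2L, IPP = 4L, NN_TERMINAL = 2L)

#' Per-generation summary of a lineage ensemble
#'
#' Tallies, for each generation g: the number of lineages dividing at g,
#' the neuron output (neurons are attributed to the generation of the RGP
#' division that spawned them, so an IPP division at G2 contributes four
#' neurons to G2; the mean is taken over all lineages of the ensemble,
#' with exited lineages contributing zero), the proportions of the
#' IPP/IP/N patterns, the fraction of lineages exiting the cycle at g,
#' and the fraction that switched pattern relative to g - 1.
#'
#' @param trees List of generation-annotated [LineageTree-class].
#' @param ntAsN Count terminal N/N divisions as N divisions.
#' @return data.frame with one row per generation.
#' @export
summarizeGenerations <- function(trees, ntAsN = TRUE) {
  gtabs <- lapply(trees, function(t) {
    g <- if (is.data.frame(t)) t else generations(t)
    if (!nrow(g)) stop("summarizeGenerations: unannotated tree")
    g
  })
  gmax <- max(vapply(gtabs, function(g) max(g$generation), integer(1)))
  rows <- lapply(seq_len(gmax), function(g) {
    pats <- vapply(gtabs, function(tab) {
      i <- match(g, tab$generation)
      if (is.na(i)) NA_character_ else tab$pattern[i]
    }, character(1))
    prev <- if (g > 1) vapply(gtabs, function(tab) {
      i <- match(g - 1L, tab$generation)
      if (is.na(i)) NA_character_ else tab$pattern[i]
    }, character(1)) else rep(NA_character_, length(gtabs))
    if (ntAsN) {
      pats[pats %in% "NN_TERMINAL"] <- "N"
      prev[prev %in% "NN_TERMINAL"] <- "N"
    }
    entered <- !is.na(pats)
    dividing <- entered & pats != "EXIT" & pats != "SYMMETRIC"
    ## per-lineage neuron output at generation g; lineages that have
    ## already exited contribute zero, so the ensemble mean decays
    out <- ifelse(dividing, .neuronOutput[ifelse(dividing, pats, "N")], 0)
    div3 <- pats[dividing & pats %in% .patternOrder]
    prop <- if (length(div3)) as.numeric(table(factor(div3,
                                                      .patternOrder))) /
      length(div3) else rep(NA_real_, 3)
    switchable <- dividing & prev %in% .patternOrder &
      pats %in% .patternOrder
    data.frame(
      generation = g,
      nLineages = sum(dividing),
      outputMean = mean(out),
      outputSd = if (length(out) > 1) sd(out) else NA_real_,
      outputTotal = sum(out),
      propIPP = prop[1], propIP = prop[2], propN = prop[3],
      exitFraction = sum(pats == "EXIT", na.rm = TRUE) / sum(entered),
      switchFraction = if (any(switchable))
        mean(pats[switchable] != prev[switchable]) else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fit an exponential decay to per-generation neuron output
#'
#' Fits y(g) = a * exp(lambda * g) to the mean neuron output per
#' generation by nonlinear least squares, initialized from the log-linear
#' fit (deterministic given the inputs). The decay index lambda is scale
#' invariant and recovers -ln 2 exactly on an exact halving series. When
#' nonpositive means are present the log-linear fit on the positive
#' entries is returned, flagged.
#'
#' @param summary Output of [summarizeGenerations()], or a data.frame
#'   with columns `generation` and `outputMean`.
#' @return List with `a`, `lambda`, `residualNorm`, `flagged`.
#' @export
fitDecay <- function(summary) {
  df <- data.frame(g = summary$generation, y = summary$outputMean)
  df <- df[is.finite(df$y), ]
  if (nrow(df) < 3) stop("fitDecay: need data for at least 3 generations")
  flagged <- any(df$y <= 0)
  pos <- df[df$y > 0, ]
  ll <- lm(log(y) ~ g, data = pos)
  start <- list(a = exp(coef(ll)[[1]]), lambda = coef(ll)[[2]])
  if (flagged) {
    return(list(a = start$a, lambda = start$lambda,
                residualNorm = sqrt(sum(residuals(ll)^2)), flagged = TRUE))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(lambda * g), data = df, start = start,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) NULL)
  if (is.null(fit)) {
    ## zero-residual or degenerate series: the log-linear start is exact
    return(list(a = start$a, lambda = start$lambda,
                residualNorm = sqrt(sum(residuals(ll)^2)),
                flagged = FALSE))
  }
  co <- coef(fit)
  list(a = co[["a"]], lambda = co[["lambda"]],
       residualNorm = sqrt(sum(residuals(fit)^2)), flagged = FALSE)
}

#' Estimate the division-pattern transition matrix
#'
#' Counts consecutive-generation pattern pairs (g -> g + 1 for
#' g < `maxGeneration`) over the three asymmetric patterns. Terminal N/N
#' divisions are mapped to N (configurable); cycle exits are excluded
#' from the 3x3 table and tallied separately. The pooled matrix is the
#' row-normalized count matrix. A chi-square test of independence on the
#' pooled table assesses whether a generation's pattern depends on the
#' previous one, and per-row homogeneity chi-square tests compare each
#' row's distribution across intergenerations.
#'
#' When the purpose is to recover the generating matrix of the
#' simulator, transitions drawn under a boundary-renormalized matrix
#' (fewer than four neurons remaining before the target division) are
#' censored draws from a different row; `unconstrainedOnly = TRUE`
#' excludes them, giving a consistent estimator of the unconstrained
#' matrix. The default (`FALSE`) pools all transitions, matching the
#' average-of-the-first-four-generations convention used on experimental
#' lineages.
#'
#' @param trees List of annotated [LineageTree-class].
#' @param maxGeneration Transitions are counted for g <
#'   `maxGeneration` (default 4: the first four generations).
#' @param ntAsN Map terminal N/N divisions to N.
#' @param unconstrainedOnly Exclude transitions whose target division was
#'   drawn under a boundary-renormalized matrix.
#' @return List with `counts` (3x3 pooled), `perGeneration` (array of
#'   per-intergeneration counts), `matrix` (pooled
#'   [TransitionMatrix-class] or NULL if a row is empty), `rowDefined`,
#'   `dependency` (chi-square htest), `homogeneity` (per-row htests),
#'   `exitCounts`.
#' @export
estimateTransitions <- function(trees, maxGeneration = 4L, ntAsN = TRUE,
                                unconstrainedOnly = FALSE) {
  gs <- seq_len(maxGeneration - 1L)
  perGen <- array(0L, dim = c(3, 3, length(gs)),
                  dimnames = list(.patternOrder, .patternOrder,
                                  paste0("G", gs, "-G", gs + 1L)))
  exitCounts <- integer(maxGeneration)
  names(exitCounts) <- paste0("G", seq_len(maxGeneration))
  for (t in trees) {
    tab <- if (is.data.frame(t)) t else generations(t)
    if (!nrow(tab)) stop("estimateTransitions: unannotated tree")
    pat <- tab$pattern
    if (ntAsN) pat[pat == "NN_TERMINAL"] <- "N"
    remainBefore <- NULL
    if (unconstrainedOnly) {
      cons <- .neuronOutput[tab$pattern]
      cons[is.na(cons)] <- 0L
      total <- sum(cons)
      ## neurons still owed before each listed generation's division
      remainBefore <- total - cumsum(c(0L, cons))[seq_len(nrow(tab))]
    }
    for (g in gs) {
      i <- match(g, tab$generation)
      j <- match(g + 1L, tab$generation)
      if (is.na(i) || is.na(j)) next
      if (unconstrainedOnly && remainBefore[j] < 4) next
      from <- pat[i]; to <- pat[j]
      if (from %in% .patternOrder && to %in% .patternOrder)
        perGen[from, to, g] <- perGen[from, to, g] + 1L
    }
    for (g in seq_len(maxGeneration)) {
      i <- match(g, tab$generation)
      if (!is.na(i) && pat[i] == "EXIT")
        exitCounts[g] <- exitCounts[g] + 1L
    }
  }
  counts <- apply(perGen, c(1, 2), sum)
  rowTot <- rowSums(counts)
  rowDefined <- rowTot > 0
  pooled <- NULL
  if (all(rowDefined)) pooled <- TransitionMatrix(counts / rowTot)
  dependency <- if (all(rowSums(counts) > 0) && all(colSums(counts) > 0))
    suppressWarnings(chisq.test(counts, correct = FALSE)) else NULL
  homogeneity <- lapply(.patternOrder, function(fr) {
    m <- t(sapply(seq_along(gs), function(g) perGen[fr, , g]))
    keep <- rowSums(m) > 0
    m <- m[keep, , drop = FALSE]
    cols <- colSums(m) > 0
    if (nrow(m) < 2 || sum(cols) < 2) return(NULL)
    suppressWarnings(chisq.test(m[, cols, drop = FALSE], correct = FALSE))
  })
  names(homogeneity) <- .patternOrder
  list(counts = counts, perGeneration = perGen, matrix = pooled,
       rowDefined = rowDefined, dependency = dependency,
       homogeneity = homogeneity, exitCounts = exitCounts)
}

#' Kullback-Leibler divergence between two discrete distributions
#'
#' Both vectors are augmented by `pseudocount` per bin and renormalized;
#' the divergence sum(p * ln(p / q)) is returned in nats. Nonnegative,
#' zero iff the distributions coincide (with pseudocount 0 this requires
#' matching supports).
#'
#' @param p,q Nonnegative weight vectors of equal length (counts or
#'   probabilities).
#' @param pseudocount Added to every bin before normalization
#'   (default 0.5).
#' @return Nonnegative divergence in nats.
#' @export
klDivergence <- function(p, q, pseudocount = 0.5) {
  if (length(p) != length(q))
    stop("klDivergence: p and q must have equal length")
  if (any(p < 0) || any(q < 0))
    stop("klDivergence: entries must be nonnegative")
  p2 <- (p + pseudocount) / sum(p + pseudocount)
  q2 <- (q + pseudocount) / sum(q + pseudocount)
  terms <- ifelse(p2 > 0, p2 * log(p2 / q2), 0)
  sum(terms)
}

## ---- zero-truncated Poisson mixture ------------------------------------

#' Zero-truncated Poisson probability mass
#' @param x Positive integers.
#' @param lambda Rate.
#' @return P(X = x) for the zero-truncated Poisson.
#' @export
dztpois <- function(x, lambda) {
  out <- dpois(x, lambda) / (1 - exp(-lambda))
  out[x < 1] <- 0
  out
}

#' Mean of the zero-truncated Poisson
#' @param lambda Rate.
#' @return lambda / (1 - exp(-lambda)).
#' @export
ztpoisMean <- function(lambda) lambda / (1 - exp(-lambda))

## solve ztpoisMean(lambda) = m for lambda (m > 1)
.ztpoisRateForMean <- function(m) {
  if (m <= 1 + 1e-12) return(1e-8)
  uniroot(function(l) ztpoisMean(l) - m, lower = 1e-8,
          upper = max(m * 2, 10), extendInt = "upX", tol = 1e-12)$root
}

#' Fit a zero-truncated Poisson mixture to clone sizes
#'
#' EM with a deterministic quantile-split initialization: the sample is
#' split at its median and each half's mean seeds one component's rate.
#' Convergence when the log-likelihood improves by less than `tol`
#' (default 1e-8), capped at 500 iterations. A component whose weight
#' collapses below 1e-6 flags a degenerate (effectively reduced-k) fit.
#' Goodness of fit is assessed by a chi-square on size bins pooled from
#' the tail so that every expected count is at least 5, with
#' degrees of freedom = bins - 1 - free parameters.
#'
#' @param sizes Integer clone sizes (all >= 1), at least 20 of them.
#' @param k Number of components (default 2).
#' @param tol,maxIter EM stopping controls.
#' @return List with `weights`, `rates` (sorted increasing), `logLik`,
#'   `iterations`, `degenerate`, `gof` (list with `statistic`, `df`,
#'   `p.value`, `bins`).
#' @export
fitPoissonMixture <- function(sizes, k = 2L, tol = 1e-8, maxIter = 500L) {
  sizes <- as.integer(sizes)
  if (length(sizes) < 20) stop("fitPoissonMixture: need >= 20 observations")
  if (any(sizes < 1)) stop("fitPoissonMixture: sizes must be >= 1")
  if (length(unique(sizes)) == 1) {
    return(list(weights = 1, rates = .ztpoisRateForMean(sizes[1]),
                logLik = NA_real_, iterations = 0L, degenerate = TRUE,
                gof = NULL))
  }
  qs <- quantile(sizes, probs = seq(0, 1, length.out = k + 1), type = 1)
  rates <- vapply(seq_len(k), function(i) {
    grp <- sizes[sizes >= qs[i] & sizes <= qs[i + 1]]
    .ztpoisRateForMean(mean(grp))
  }, numeric(1))
  rates <- pmax(rates + seq_len(k) * 1e-3, 1e-6)  # break exact ties
  weights <- rep(1 / k, k)
  ll <- -Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    dens <- vapply(seq_len(k), function(j)
      weights[j] * dztpois(sizes, rates[j]), numeric(length(sizes)))
    tot <- rowSums(dens)
    newLl <- sum(log(tot))
    resp <- dens / tot
    weights <- colMeans(resp)
    for (j in seq_len(k)) {
      if (weights[j] > 1e-12) {
        m <- sum(resp[, j] * sizes) / sum(resp[, j])
        rates[j] <- .ztpoisRateForMean(m)
      }
    }
    if (newLl - ll < tol || iter >= maxIter) {
      ll <- newLl
      break
    }
    ll <- newLl
  }
  ord <- order(rates)
  rates <- rates[ord]
  weights <- weights[ord]
  degenerate <- any(weights < 1e-6)
  gof <- .mixtureGof(sizes, weights, rates)
  list(weights = weights, rates = rates, logLik = ll, iterations = iter,
       degenerate = degenerate, gof = gof)
}

.mixtureGof <- function(sizes, weights, rates) {
  n <- length(sizes)
  xmax <- max(sizes)
  probs <- vapply(seq_len(xmax), function(x)
    sum(weights * dztpois(x, rates)), numeric(1))
  probs[xmax] <- probs[xmax] + max(0, 1 - sum(probs))  # fold the tail in
  expected <- n * probs
  observed <- tabulate(sizes, nbins = xmax)
  ## pool from the tail until every expected count reaches 5
  bins <- list()
  accO <- 0; accE <- 0
  for (x in seq_len(xmax)) {
    accO <- accO + observed[x]; accE <- accE + expected[x]
    if (accE >= 5 && (x == xmax ||
                      sum(expected[(x + 1):xmax]) >= 5)) {
      bins[[length(bins) + 1]] <- c(accO, accE)
      accO <- 0; accE <- 0
    }
  }
  if (accE > 0) {  # leftover tail folded into the last bin
    last <- bins[[length(bins)]]
    bins[[length(bins)]] <- last + c(accO, accE)
  }
  m <- do.call(rbind, bins)
  nfree <- 2 * length(rates) - 1
  df <- nrow(m) - 1 - nfree
  stat <- sum((m[, 1] - m[, 2])^2 / m[, 2])
  list(statistic = stat, df = df,
       p.value = if (df > 0) pchisq(stat, df, lower.tail = FALSE)
       else NA_real_,
       bins = nrow(m))
}

## ---- cumulative distance analysis --------------------------------------

#' Cumulative distance analysis of same- versus different-level neurons
#'
#' Splits a clone's neuron pairs into those sharing a dye-intensity
#' hierarchy level (group M, pooled over levels with at least two cells)
#' and all remaining pairs (group N), computes both empirical cumulative
#' distance curves and compares them with a two-sample
#' Kolmogorov-Smirnov test. Shorter cumulative distances reflect spatial
#' clustering (same-IP siblings), longer ones dispersal.
#'
#' @param clone A [Clone-class] with positions.
#' @param assignment Optional [HierarchyAssignment-class] (computed from
#'   the clone's intensities when missing).
#' @return List with `within`, `other` (sorted pair distances),
#'   `withinEcdf`, `otherEcdf`, `ks` (htest or NULL), `flagged`.
#' @export
cumulativeDistance <- function(clone, assignment = NULL) {
  df <- cells(clone)
  if (is.null(assignment)) assignment <- assignHierarchies(df)
  lv <- assignment@levels[as.character(df$cell_id)]
  xyz <- as.matrix(df[, c("x", "y", "z")])
  if (anyNA(xyz)) stop("cumulativeDistance: positions required")
  n <- nrow(df)
  within <- numeric(0); other <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (lv[i] == lv[j]) within <- c(within, d)
      else other <- c(other, d)
    }
  }
  if (length(within) == 0) {
    return(list(within = within, other = other, withinEcdf = NULL,
                otherEcdf = NULL, ks = NULL, flagged = TRUE))
  }
  ks <- if (length(other))
    suppressWarnings(ks.test(within, other)) else NULL
  list(within = sort(within), other = sort(other),
       withinEcdf = ecdf(within),
       otherEcdf = if (length(other)) ecdf(other) else NULL,
       ks = ks, flagged = FALSE)
}
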