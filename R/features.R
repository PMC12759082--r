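## Per-clone cell-type calling, laminar classification, feature
## extraction and Ward clustering.

#' Call the excitatory neuron class from markers and layer
#'
#' Precedence: Fog2+ is a corticothalamic projection neuron (CThPN);
#' otherwise Satb2+/Ctip2+ co-expression marks a heterogeneous projection
#' neuron (HPN); otherwise Ctip2+ a subcerebral projection neuron (SCPN);
#' otherwise Satb2+ a callosal projection neuron (CPN); marker-negative
#' cells located in the subplate are subplate projection neurons (SPN);
#' anything else is unknown. Exactly inverts the synthetic marker
#' assignment of [assignClassesAndMarkers()].
#'
#' @param satb2,ctip2,fog2 Marker status `"+"`, `"-"` or `"?"`
#'   (vectorized).
#' @param layer Layer label(s).
#' @return Character vector of neuron classes.
#' @export
classifyCellType <- function(satb2, ctip2, fog2, layer = "unknown") {
  n <- max(length(satb2), length(ctip2), length(fog2), length(layer))
  satb2 <- rep_len(satb2, n); ctip2 <- rep_len(ctip2, n)
  fog2 <- rep_len(fog2, n); layer <- rep_len(layer, n)
  out <- rep("unknown", n)
  out[fog2 == "+"] <- "CThPN"
  hpn <- fog2 != "+" & satb2 == "+" & ctip2 == "+"
  out[hpn] <- "HPN"
  scpn <- fog2 != "+" & ctip2 == "+" & satb2 != "+"
  out[scpn] <- "SCPN"
  cpn <- fog2 != "+" & satb2 == "+" & ctip2 != "+"
  out[cpn] <- "CPN"
  out[out == "unknown" & layer == "SP"] <- "SPN"
  out
}

.deepLayers <- c("L5", "L6")
.superficialLayers <- c("L2/3", "L4")

#' Laminar class of a clone
#'
#' Deep layers (DL) are L5 and L6; superficial layers (SL) are L2/3 and
#' L4. Clones occupying both sides are translaminar, subtyped by which
#' deep layers they occupy (`SL+L5`, `SL+L6`, `SL+L5+L6`); clones
#' confined to one side are spatially restricted (`L2/3-only`,
#' `L4-only`, `L5-only`, `L6-only`), with multi-layer same-side clones
#' mapped to their deepest occupied layer and flagged. The seven classes
#' partition all clones with at least one layer-classified neuron.
#'
#' @param clone A [Clone-class] or cell-table data.frame.
#' @return Character label, with attribute `flagged` for multi-layer
#'   same-side clones.
#' @export
laminarClass <- function(clone) {
  df <- if (is.data.frame(clone)) clone else cells(clone)
  layers <- unique(df$layer[df$layer %in% c(.deepLayers,
                                            .superficialLayers)])
  if (length(layers) == 0)
    stop("laminarClass: no neurons with a known cortical layer")
  dl <- intersect(layers, .deepLayers)
  sl <- intersect(layers, .superficialLayers)
  if (length(dl) && length(sl)) {
    lab <- if (setequal(dl, c("L5", "L6"))) "SL+L5+L6"
    else if (dl == "L5") "SL+L5" else "SL+L6"
    return(structure(lab, flagged = FALSE))
  }
  side <- if (length(dl)) dl else sl
  deepest <- side[which.max(match(side, c("L2/3", "L4", "L5", "L6")))]
  structure(paste0(deepest, "-only"), flagged = length(side) > 1)
}

#' Names of the 20 per-clone features
#' @return Character vector of feature names.
#' @export
cloneFeatureNames <- function() {
  c("cloneSize", "nGenerations", "fracDivN", "fracDivIP", "fracDivIPP",
    "fracNeuronsN", "fracNeuronsIP", "fracNeuronsIPP",
    "fracL23", "fracL4", "fracL5", "fracL6", "fracDL", "fracSL",
    "fracCPN", "fracCThPN", "fracSCPN", "fracHPN",
    "translaminar", "meanRelRadialPos")
}

#' Extract the 20-feature vector of a clone
#'
#' Features span the three lineage aspects used for clonal
#' classification: division patterns (clone size, generation count,
#' fractions of N/IP/IPP divisions and of neurons they produced), laminar
#' distribution (per-layer and deep/superficial fractions, translaminar
#' indicator, mean relative radial position) and excitatory neuron types
#' (class fractions). Undefined components (e.g. no layer-classified
#' cells) are imputed as 0 and flagged. Features are invariant under
#' uniform spatial translation of the clone.
#'
#' @param clone A [Clone-class] (observed cells).
#' @param tree The clone's annotated [LineageTree-class].
#' @param ntAsN Count terminal N/N divisions as N.
#' @return Named numeric vector of length 20, with attribute `flagged`.
#' @export
extractFeatures <- function(clone, tree, ntAsN = TRUE) {
  df <- if (is.data.frame(clone)) clone else cells(clone)
  gens <- generations(tree)
  pat <- gens$pattern
  if (ntAsN) pat[pat == "NN_TERMINAL"] <- "N"
  div <- pat[pat %in% .patternOrder]
  nDiv <- length(div)
  flagged <- FALSE
  fracDiv <- if (nDiv) as.numeric(table(factor(div, .patternOrder))) / nDiv
  else {
    flagged <- TRUE
    rep(0, 3)
  }
  ## neurons attributed to their spawning division pattern
  leaves <- Filter(function(l) l$type == "NEURON",
                   .collectLeaves(tree@root))
  org <- vapply(leaves, function(l) l$origin, character(1))
  if (ntAsN) org[org == "NN_TERMINAL"] <- "N"
  org <- org[org %in% .patternOrder]
  fracNeur <- if (length(org))
    as.numeric(table(factor(org, .patternOrder))) / length(org)
  else {
    flagged <- TRUE
    rep(0, 3)
  }
  layered <- df$layer[df$layer %in% c(.superficialLayers, .deepLayers)]
  if (length(layered)) {
    fl <- as.numeric(table(factor(layered,
                                  c("L2/3", "L4", "L5", "L6")))) /
      length(layered)
    dl <- sum(fl[3:4]); sl <- sum(fl[1:2])
    trans <- as.numeric(dl > 0 && sl > 0)
  } else {
    flagged <- TRUE
    fl <- rep(0, 4); dl <- 0; sl <- 0; trans <- 0
  }
  classed <- df$neuron_class[df$neuron_class %in%
                               c("CPN", "CThPN", "SCPN", "HPN")]
  fc <- if (length(classed))
    as.numeric(table(factor(classed, c("CPN", "CThPN", "SCPN", "HPN")))) /
    length(classed)
  else {
    flagged <- TRUE
    rep(0, 4)
  }
  rrp <- df$rel_radial_pos[is.finite(df$rel_radial_pos)]
  meanRrp <- if (length(rrp)) mean(rrp) else {
    flagged <- TRUE
    0
  }
  v <- c(nrow(df), max(c(0L, gens$generation[pat %in%
                                               c(.patternOrder)])),
         fracDiv[match(c("N", "IP", "IPP"), .patternOrder)],
         fracNeur[match(c("N", "IP", "IPP"), .patternOrder)],
         fl, dl, sl, fc[1], fc[2], fc[3], fc[4], trans, meanRrp)
  names(v) <- cloneFeatureNames()
  structure(v, flagged = flagged)
}

#' Ward clustering of clone feature vectors
#'
#' Features are standardized per dimension to mean 0 / SD 1 (constant
#' dimensions dropped), clones linked by Ward's method on Euclidean
#' distances, and the dendrogram cut at `k` clusters (default 5).
#' Deterministic and invariant to input order.
#'
#' @param features Matrix or data.frame of feature vectors (one clone
#'   per row) as from [extractFeatures()].
#' @param k Number of clusters.
#' @return List with `labels` (integer vector, names preserved),
#'   `linkage` (the hclust object), `scaledFeatures`.
#' @export
clusterClones <- function(features, k = 5L) {
  m <- as.matrix(features)
  if (nrow(m) < k)
    stop("clusterClones: need at least k clones")
  sds <- apply(m, 2, sd)
  m2 <- scale(m[, sds > 0, drop = FALSE])
  hc <- hclust(dist(m2), method = "ward.D2")
  labels <- cutree(hc, k = k)
  names(labels) <- rownames(m)
  list(labels = labels, linkage = hc, scaledFeatures = m2)
}

#' Per-cluster summary of clonal composition
#'
#' For each cluster: deep- versus superficial-layer neuron counts, neuron
#' class composition, the dominant class combination (only CPN;
#' CThPN+CPN; CThPN+SCPN/HPN+CPN; other) and the mean fraction of neurons
#' derived from IPP divisions. Summaries aggregate exactly to the
#' whole-dataset totals.
#'
#' @param result Output of [clusterClones()].
#' @param clones List of [Clone-class] in the same order as the feature
#'   rows.
#' @param trees Matching list of annotated [LineageTree-class].
#' @return data.frame with one row per cluster.
#' @export
clusterSummaries <- function(result, clones, trees) {
  labels <- result$labels
  rows <- lapply(sort(unique(labels)), function(cl) {
    idx <- which(labels == cl)
    dfs <- lapply(clones[idx], function(c)
      if (is.data.frame(c)) c else cells(c))
    all <- do.call(rbind, dfs)
    dlN <- sum(all$layer %in% .deepLayers)
    slN <- sum(all$layer %in% .superficialLayers)
    combo <- table(vapply(dfs, .classCombo, character(1)))
    classCounts <- table(factor(all$neuron_class,
                                c("CPN", "CThPN", "SCPN", "HPN", "SPN",
                                  "unknown")))
    ippFrac <- mean(vapply(trees[idx], .ippNeuronFraction, numeric(1)),
                    na.rm = TRUE)
    data.frame(cluster = cl, nClones = length(idx),
               neuronsDL = dlN, neuronsSL = slN,
               fracCPN = as.numeric(classCounts["CPN"]) / nrow(all),
               fracCThPN = as.numeric(classCounts["CThPN"]) / nrow(all),
               fracSCPN = as.numeric(classCounts["SCPN"]) / nrow(all),
               fracHPN = as.numeric(classCounts["HPN"]) / nrow(all),
               dominantCombo = names(combo)[which.max(combo)],
               ippNeuronFraction = ippFrac,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.classCombo <- function(df) {
  present <- unique(df$neuron_class[df$neuron_class %in%
                                      c("CPN", "CThPN", "SCPN", "HPN")])
  if (setequal(present, "CPN")) return("only CPN")
  if (setequal(present, c("CPN", "CThPN"))) return("CThPN+CPN")
  if ("CPN" %in% present && "CThPN" %in% present &&
      any(c("SCPN", "HPN") %in% present)) return("CThPN+SCPN/HPN+CPN")
  "other"
}

.ippNeuronFraction <- function(tree) {
  leaves <- Filter(function(l) l$type == "NEURON",
                   .collectLeaves(tree@root))
  if (!length(leaves)) return(NA_real_)
  org <- vapply(leaves, function(l) l$origin, character(1))
  mean(org == "IPP", na.rm = TRUE)
}
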