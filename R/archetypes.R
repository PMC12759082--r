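## Parameterized clone archetypes: five contrasting lineage behaviours
## used to validate clonal clustering on a population with known
## structure.

#' Definitions of the five clone archetypes
#'
#' Each archetype specifies a transition matrix, a clone-size model, a
#' radial window (the band of relative radial positions its neurons
#' occupy) and a class-probability table, jointly producing clones with
#' contrasting division patterns, laminar distributions and neuron-type
#' compositions.
#'
#' @return Named list of archetype parameter sets.
#' @export
archetypeDefinitions <- function() {
  tbl <- function(...) .validateClassTable(
    data.frame(pattern = "any", ..., stringsAsFactors = FALSE))
  list(
    balancedTranslaminar = list(
      transitions = defaultTransitionMatrix(),
      sizeModel = CloneSizeModel(c(0.5, 0.5), c(6, 10)),
      rrpWindow = c(0.25, 0.58),
      classTable = tbl(layer = c("L2/3", "L4", "L5", "L6"),
                       CPN = c(1, 1, 1, 0.5), SCPN = c(0, 0, 0, 0),
                       CThPN = c(0, 0, 0, 0.5), HPN = c(0, 0, 0, 0))),
    deepDirect = list(
      transitions = TransitionMatrix(rbind(c(0.02, 0.08, 0.9),
                                           c(0.02, 0.08, 0.9),
                                           c(0.02, 0.08, 0.9))),
      sizeModel = CloneSizeModel(1, 1.8),
      rrpWindow = c(0.76, 0.99),
      classTable = tbl(layer = "L6", CPN = 0, SCPN = 0,
                       CThPN = 1, HPN = 0)),
    deepIndirect = list(
      transitions = TransitionMatrix(rbind(c(0.6, 0.25, 0.15),
                                           c(0.55, 0.3, 0.15),
                                           c(0.55, 0.25, 0.2))),
      sizeModel = CloneSizeModel(1, 11),
      rrpWindow = c(0.5, 0.99),
      classTable = tbl(layer = c("L5", "L6"),
                       CPN = c(1, 1), SCPN = c(0, 0),
                       CThPN = c(0, 0), HPN = c(0, 0))),
    superficialIndirect = list(
      transitions = TransitionMatrix(rbind(c(0.55, 0.25, 0.2),
                                           c(0.45, 0.35, 0.2),
                                           c(0.45, 0.25, 0.3))),
      sizeModel = CloneSizeModel(1, 9),
      rrpWindow = c(0.01, 0.42),
      classTable = tbl(layer = c("L2/3", "L4"),
                       CPN = c(1, 1), SCPN = c(0, 0),
                       CThPN = c(0, 0), HPN = c(0, 0))),
    layer5Restricted = list(
      transitions = TransitionMatrix(rbind(c(0.02, 0.58, 0.4),
                                           c(0.02, 0.68, 0.3),
                                           c(0.02, 0.58, 0.4))),
      sizeModel = CloneSizeModel(1, 6),
      rrpWindow = c(0.52, 0.73),
      classTable = tbl(layer = "L5", CPN = 0, SCPN = 0.1,
                       CThPN = 0, HPN = 0.9)))
}

#' Simulate a labelled population from the five clone archetypes
#'
#' Simulates `nPerArchetype` clean clones (no dropout, no detection loss)
#' from each archetype, remaps their relative radial positions into the
#' archetype's radial window, and draws classes/markers from the
#' archetype's table. Ground-truth archetype labels are returned for
#' cluster-recovery benchmarking.
#'
#' @param nPerArchetype Clones per archetype.
#' @param seed Seed for the whole population.
#' @param minSize Minimum clone size (smaller draws are rejected):
#'   one- and two-neuron clones carry almost no archetype signal.
#' @param noise,spatial Generator models (defaults as documented).
#' @return List with `clones`, `trees`, `labels` (integer archetype ids)
#'   and `archetypes` (the definitions used).
#' @export
simulateArchetypePopulation <- function(nPerArchetype = 24, seed = 1,
                                        minSize = 3,
                                        noise = NoiseModel(),
                                        spatial = SpatialModel()) {
  set.seed(seed)
  defs <- archetypeDefinitions()
  clones <- list(); trees <- list(); labels <- integer(0)
  for (a in seq_along(defs)) {
    def <- defs[[a]]
    ts <- lapply(seq_len(nPerArchetype), function(i) {
      size <- drawCloneSize(1, def$sizeModel)
      while (size < minSize) size <- drawCloneSize(1, def$sizeModel)
      simulateLineage(def$transitions, pynTarget = size,
                      cloneId = sprintf("arch%d_c%d", a, i))
    })
    syn <- synthesizeCellTable(ts, noise = noise, spatial = spatial,
                               dropout = FALSE, threshold = FALSE)
    for (cl in syn$clones) {
      df <- cells(cl)
      df <- .remapRadial(df, def$rrpWindow, def$classTable)
      clones[[length(clones) + 1]] <- Clone(df)
      labels <- c(labels, a)
    }
    ## keep trees aligned with the observed clone order
    ids <- vapply(syn$clones, cloneId, character(1))
    tids <- vapply(syn$trees, function(t) t@cloneId, character(1))
    trees <- c(trees, syn$trees[match(ids, tids)])
  }
  list(clones = clones, trees = trees, labels = labels,
       archetypes = defs)
}

## squeeze relative radial positions into a window and redraw
## layer-consistent classes and markers from the archetype's table; the
## generator's effective depth range (about 0.2-0.9) is first normalized
## so the window is actually filled
.remapRadial <- function(df, window, classTable) {
  norm <- pmin(1, pmax(0, (df$rel_radial_pos - 0.2) / 0.7))
  df$rel_radial_pos <- window[1] + (window[2] - window[1]) * norm
  df$y <- df$rel_radial_pos * 1000
  df$layer <- layerFromRrp(df$rel_radial_pos)
  for (i in seq_len(nrow(df))) {
    row <- classTable[classTable$layer == df$layer[i], , drop = FALSE]
    cls <- if (nrow(row) == 0) "CPN"
    else sample(c("CPN", "SCPN", "CThPN", "HPN"), 1,
                prob = as.numeric(row[1, c("CPN", "SCPN", "CThPN",
                                           "HPN")]))
    df$neuron_class[i] <- cls
    mk <- .classMarkers[[cls]]
    df$satb2[i] <- mk[["satb2"]]
    df$ctip2[i] <- mk[["ctip2"]]
    df$fog2[i] <- mk[["fog2"]]
  }
  df
}
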