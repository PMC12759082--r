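## Run configuration: class tables and YAML/JSON config files.

#' Default neuron-class probability table
#'
#' Probabilities of the four excitatory projection classes per
#' (division pattern, layer). The default is uniform over the classes
#' compatible with each layer (SCPN and HPN are layer-5 types, CThPN is a
#' layer-6 type, CPN occurs in all layers) and independent of the division
#' pattern; rows must sum to 1.
#'
#' @return data.frame with columns `pattern`, `layer`, `CPN`, `SCPN`,
#'   `CThPN`, `HPN`.
#' @export
defaultClassTable <- function() {
  data.frame(
    pattern = "any",
    layer = c("L2/3", "L4", "L5", "L6"),
    CPN   = c(1, 1, 1 / 3, 1 / 2),
    SCPN  = c(0, 0, 1 / 3, 0),
    CThPN = c(0, 0, 0, 1 / 2),
    HPN   = c(0, 0, 1 / 3, 0),
    stringsAsFactors = FALSE)
}

.validateClassTable <- function(tab) {
  need <- c("pattern", "layer", "CPN", "SCPN", "CThPN", "HPN")
  if (!all(need %in% names(tab)))
    stop("class table must have columns ", paste(need, collapse = ", "))
  p <- as.matrix(tab[, c("CPN", "SCPN", "CThPN", "HPN")])
  if (any(p < 0) || any(abs(rowSums(p) - 1) > 1e-8))
    stop("class table config error: each probability row must sum to 1")
  invisible(tab)
}

#' Read a run configuration file
#'
#' Accepts YAML or JSON mirroring the [RunConfig-class] slots. Unset
#' fields keep their documented defaults; all probabilities are validated
#' into `[0, 1]` at load time.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A validated [RunConfig-class].
#' @export
readRunConfig <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  for (f in c("seed", "batchSize", "nBatches", "clusterK", "maxWorkingSet"))
    if (!is.null(raw[[f]])) args[[f]] <- as.integer(raw[[f]])
  for (f in c("equalTol")) if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  if (!is.null(raw$ntAsN)) args$ntAsN <- isTRUE(raw$ntAsN)
  if (!is.null(raw$sizeModel))
    args$sizeModel <- CloneSizeModel(weights = raw$sizeModel$weights,
                                     rates = raw$sizeModel$rates)
  if (!is.null(raw$transitions))
    args$transitions <- TransitionMatrix(
      matrix(unlist(raw$transitions), nrow = 3, byrow = TRUE))
  if (!is.null(raw$noise)) args$noise <- do.call(NoiseModel, raw$noise)
  if (!is.null(raw$spatial)) args$spatial <- do.call(SpatialModel, raw$spatial)
  if (!is.null(raw$layerCuts)) {
    lc <- unlist(raw$layerCuts)
    names(lc) <- c("L2/3", "L4", "L5", "L6")
    args$layerCuts <- lc
  }
  if (!is.null(raw$classTable)) {
    args$classTable <- .validateClassTable(
      as.data.frame(raw$classTable, stringsAsFactors = FALSE))
  }
  cfg <- do.call(RunConfig, args)
  validObject(cfg)
  cfg
}
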