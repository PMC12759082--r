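## Cell-table and tree file I/O.

.cellTableColumns <- c("clone_id", "cell_id", "intensity", "x", "y", "z",
                       "rel_radial_pos", "layer", "satb2", "ctip2", "fog2",
                       "neuron_class", "apoptotic", "region")

#' Read a per-cell observation table
#'
#' The cell table is UTF-8, tab-delimited, one header row, with columns
#' `clone_id, cell_id, intensity, x, y, z, rel_radial_pos, layer, satb2,
#' ctip2, fog2, neuron_class, apoptotic, region`. Marker status is coded
#' `"+"`, `"-"`, `"?"`; unknown categorical fields are `"unknown"`.
#'
#' @param path Path to a tab-delimited cell table.
#' @return List of [Clone-class] objects, one per distinct `clone_id`, in
#'   order of first appearance.
#' @export
readCellTable <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character", check.names = FALSE,
                   fileEncoding = "UTF-8")
  missing <- setdiff(.cellTableColumns, names(df))
  if (length(missing))
    stop("cell table schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  df <- df[, .cellTableColumns]
  for (col in c("intensity", "x", "y", "z", "rel_radial_pos"))
    df[[col]] <- as.numeric(df[[col]])
  df$apoptotic <- as.logical(df$apoptotic)
  .validateCellTable(df)
  clones <- lapply(split(df, factor(df$clone_id, unique(df$clone_id))),
                   function(sub) {
                     reg <- unique(sub$region)
                     Clone(sub, region = if (length(reg) == 1 &&
                                             reg %in% .regions) reg
                           else "unknown")
                   })
  names(clones) <- unique(df$clone_id)
  clones
}

.validateCellTable <- function(df) {
  bad <- which(!is.finite(df$intensity) | df$intensity <= 0)
  if (length(bad))
    stop("cell table integrity error: nonpositive intensity in row(s) ",
         paste(bad, collapse = ", "))
  key <- paste(df$clone_id, df$cell_id, sep = "\r")
  if (anyDuplicated(key))
    stop("cell table integrity error: duplicate (clone_id, cell_id) in row(s) ",
         paste(which(duplicated(key)), collapse = ", "))
  if (!all(df$layer %in% .layerLevels))
    stop("cell table schema error: unknown layer label")
  for (m in c("satb2", "ctip2", "fog2"))
    if (!all(df[[m]] %in% .markerLevels))
      stop("cell table schema error: marker status must be '+', '-' or '?'")
  if (!all(df$neuron_class %in% .neuronClasses))
    stop("cell table schema error: unknown neuron class")
  known <- df$layer != "unknown"
  rr <- df$rel_radial_pos[known]
  if (any(is.finite(rr) & (rr < 0 | rr > 1)))
    stop("cell table integrity error: rel_radial_pos outside [0, 1]")
  invisible(TRUE)
}

#' Write a per-cell observation table
#'
#' @param x List of [Clone-class] objects or a data.frame in the cell
#'   table schema.
#' @param path Output path (tab-delimited, UTF-8).
#' @return `path`, invisibly.
#' @export
writeCellTable <- function(x, path) {
  df <- if (is.data.frame(x)) x else do.call(rbind, lapply(x, cells))
  df <- df[, .cellTableColumns]
  for (col in c("intensity", "x", "y", "z", "rel_radial_pos"))
    df[[col]] <- sprintf("%.17g", df[[col]])  # bit-exact round trip
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

## ---- trees --------------------------------------------------------------

#' Write a lineage tree to a file
#'
#' The structured JSON format is canonical and lossless; Newick is an
#' export-only format whose per-node annotations (cell type, generation,
#' theoretical intensity) travel in bracketed comment blocks, because
#' Newick cannot natively carry typed per-node fields.
#'
#' @param tree A [LineageTree-class].
#' @param path Output file path.
#' @param format `"json"` (canonical, round-trips via [readTree()]) or
#'   `"newick"`.
#' @return `path`, invisibly.
#' @export
writeTree <- function(tree, path, format = c("json", "newick")) {
  format <- match.arg(format)
  validObject(tree)
  if (format == "json") {
    payload <- list(clone_id = tree@cloneId, root_type = tree@rootType,
                    generations = tree@generations,
                    root = .nodeToList(tree@root))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  } else {
    writeLines(paste0(.nodeToNewick(tree@root), ";"), path)
  }
  invisible(path)
}

#' @rdname writeTree
#' @return `readTree` returns the [LineageTree-class] stored at `path`.
#' @export
readTree <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  gen <- emptyGenerations()
  if (length(payload$generations)) {
    gl <- payload$generations
    gen <- data.frame(
      generation = vapply(gl, function(r) as.integer(r$generation),
                          integer(1)),
      pattern = vapply(gl, function(r) as.character(r$pattern),
                       character(1)),
      stringsAsFactors = FALSE)
  }
  LineageTree(.listToNode(payload$root), cloneId = payload$clone_id,
              generations = gen)
}

.nodeToList <- function(node) {
  out <- list(type = node$type, ti = node$ti)
  for (f in c("cellId", "obsIntensity", "birthGen", "gen", "origin"))
    if (!is.na(node[[f]])) out[[f]] <- node[[f]]
  if (isTRUE(node$exit)) out$exit <- TRUE
  if (isTRUE(node$terminal)) out$terminal <- TRUE
  if (!.isLeaf(node)) out$children <- lapply(node$children, .nodeToList)
  out
}

.listToNode <- function(x) {
  .newNode(type = x$type, ti = as.numeric(x$ti),
           children = if (!is.null(x$children))
             lapply(x$children, .listToNode),
           cellId = if (!is.null(x$cellId)) x$cellId else NA_character_,
           obsIntensity = if (!is.null(x$obsIntensity))
             as.numeric(x$obsIntensity) else NA_real_,
           exit = isTRUE(x$exit), terminal = isTRUE(x$terminal),
           birthGen = if (!is.null(x$birthGen)) as.integer(x$birthGen)
             else NA_integer_,
           gen = if (!is.null(x$gen)) as.integer(x$gen) else NA_integer_,
           origin = if (!is.null(x$origin)) x$origin else NA_character_)
}

.nodeToNewick <- function(node) {
  ann <- sprintf("[&type=%s,ti=%.10g%s%s%s]", node$type, node$ti,
                 if (!is.na(node$gen)) sprintf(",gen=%d", node$gen) else "",
                 if (isTRUE(node$exit)) ",exit=1" else "",
                 if (isTRUE(node$terminal)) ",terminal=1" else "")
  label <- if (!is.na(node$cellId)) gsub("[,();:\\[\\]]", "_", node$cellId)
           else ""
  if (.isLeaf(node)) return(paste0(label, ann))
  paste0("(", .nodeToNewick(node$children[[1]]), ",",
         .nodeToNewick(node$children[[2]]), ")", label, ann)
}
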