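# Plain-text persistence: sparse event TSV for rasters, CSV and a JSON
# container for parameters.

#' Write / read a raster as a sparse event table
#'
#' TSV with header \code{time<TAB>neuron}, 0-based indices, one row per
#' spike.
#'
#' @param raster a \code{\link{SpikeRaster}}.
#' @param path file path.
#' @return \code{readRasterTSV}: a \code{SpikeRaster}.
#' @export
writeRasterTSV <- function(raster, path) {
  x <- raster@spikes
  ev <- which(x == 1, arr.ind = TRUE)
  df <- data.frame(time = ev[, "row"] - 1L, neuron = ev[, "col"] - 1L)
  df <- df[order(df$time, df$neuron), ]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param nSteps,nNeurons dimensions of the raster being read back.
#' @rdname writeRasterTSV
#' @export
readRasterTSV <- function(path, nSteps, nNeurons) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  x <- matrix(0L, nSteps, nNeurons)
  if (nrow(df)) x[cbind(df$time + 1L, df$neuron + 1L)] <- 1L
  spikeRaster(x)
}

#' Bundled parameter container
#'
#' Writes weights, thresholds, the network configuration and the seed into
#' a single JSON file, so one file reproduces the parameter state of a run.
#'
#' @param params a \code{\link{SynapticParameters}}.
#' @param path file path.
#' @param config optional \code{\link{NetworkConfig}} stored alongside.
#' @param seed optional seed stored alongside.
#' @return \code{readParametersJSON}: list with \code{params}, and
#'   \code{config}/\code{seed} when present.
#' @export
writeParametersJSON <- function(params, path, config = NULL, seed = NULL) {
  obj <- list(weights = params@weights, thresholds = params@thresholds)
  if (!is.null(config))
    obj$config <- list(nNeurons = config@nNeurons, pMax = config@pMax,
                       p0 = config@p0, nExternal = config@nExternal)
  if (!is.null(seed)) obj$seed <- seed
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeParametersJSON
#' @export
readParametersJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(params = synapticParameters(obj$weights, obj$thresholds))
  if (!is.null(obj$config))
    out$config <- networkConfig(obj$config$nNeurons, obj$config$pMax,
                                obj$config$p0, obj$config$nExternal)
  if (!is.null(obj$seed)) out$seed <- obj$seed
  out
}

#' Weight matrix / threshold vector CSV
#'
#' @param params a \code{\link{SynapticParameters}}.
#' @param weightPath,thresholdPath file paths.
#' @return \code{readParametersCSV}: a \code{SynapticParameters}.
#' @export
writeParametersCSV <- function(params, weightPath, thresholdPath) {
  utils::write.table(params@weights, weightPath, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(params@thresholds, thresholdPath, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(weightPath)
}

#' @rdname writeParametersCSV
#' @export
readParametersCSV <- function(weightPath, thresholdPath) {
  w <- as.matrix(utils::read.table(weightPath, sep = ","))
  dimnames(w) <- NULL
  h <- as.numeric(utils::read.table(thresholdPath, sep = ",")[[1]])
  synapticParameters(w, h)
}

#' Export a chain graph as an edge-list TSV
#'
#' Columns \code{pre}, \code{post}, \code{weight}, \code{depth} (first-reach
#' depth of the postsynaptic node).
#'
#' @param graph a \code{\link{ChainGraph}}.
#' @param path file path.
#' @export
writeChainTSV <- function(graph, path) {
  depth <- graph@nodes$depth[match(graph@edges$post, graph@nodes$neuron)]
  df <- cbind(graph@edges, depth = depth)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a receptive-field map as a PGM contact sheet
#'
#' Quantizes the rescaled patches (numeric, mean 128, max deviation 127) to
#' integer gray levels 1..255 and tiles them into one image; degenerate
#' neurons render as blank tiles.
#'
#' @param map a \code{\link{ReceptiveFieldMap}}.
#' @param path file path.
#' @param nCol tiles per row.
#' @export
writeReceptiveFieldPGM <- function(map, path, nCol = 10) {
  side <- map@side
  n <- nrow(map@rescaled)
  nRow <- ceiling(n / nCol)
  pad <- 2L
  sheet <- matrix(0, nRow * (side + pad) + pad, nCol * (side + pad) + pad)
  for (i in seq_len(n)) {
    if (map@degenerate[i]) next
    patch <- matrix(round(map@rescaled[i, ]), side, side)
    r0 <- ((i - 1) %/% nCol) * (side + pad) + pad
    c0 <- ((i - 1) %% nCol) * (side + pad) + pad
    sheet[r0 + seq_len(side), c0 + seq_len(side)] <- patch
  }
  writePGM(sheet / 255, path)
}
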