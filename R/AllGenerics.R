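#' Accessors
#'
#' Small accessor generics for the core containers.
#'
#' @param object an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("synapticWeights", function(object) standardGeneric("synapticWeights"))
#' @rdname accessors
#' @export
setMethod("synapticWeights", "SynapticParameters", function(object) object@weights)

#' @rdname accessors
#' @export
setGeneric("thresholds", function(object) standardGeneric("thresholds"))
#' @rdname accessors
#' @export
setMethod("thresholds", "SynapticParameters", function(object) object@thresholds)

#' @rdname accessors
#' @export
setGeneric("nRecurrent", function(object) standardGeneric("nRecurrent"))
#' @rdname accessors
#' @export
setMethod("nRecurrent", "SynapticParameters", function(object) nrow(object@weights))
#' @rdname accessors
#' @export
setMethod("nRecurrent", "NetworkConfig", function(object) as.integer(object@nNeurons))

#' @rdname accessors
#' @export
setGeneric("nExternal", function(object) standardGeneric("nExternal"))
#' @rdname accessors
#' @export
setMethod("nExternal", "SynapticParameters",
          function(object) ncol(object@weights) - nrow(object@weights))
#' @rdname accessors
#' @export
setMethod("nExternal", "NetworkConfig", function(object) as.integer(object@nExternal))

#' @rdname accessors
#' @export
setGeneric("spikes", function(object) standardGeneric("spikes"))
#' @rdname accessors
#' @export
setMethod("spikes", "SpikeRaster", function(object) object@spikes)

#' @rdname accessors
#' @export
setGeneric("membraneInputs", function(object) standardGeneric("membraneInputs"))
#' @rdname accessors
#' @export
setMethod("membraneInputs", "SpikeRaster", function(object) object@inputs)

#' @rdname accessors
#' @export
setGeneric("burstSizes", function(object) standardGeneric("burstSizes"))
#' @rdname accessors
#' @export
setMethod("burstSizes", "BurstCatalog", function(object) object@sizes)

#' @rdname accessors
#' @export
setGeneric("burstDurations", function(object) standardGeneric("burstDurations"))
#' @rdname accessors
#' @export
setMethod("burstDurations", "BurstCatalog", function(object) object@durations)

#' @rdname accessors
#' @export
setGeneric("sizeHistogram", function(object) standardGeneric("sizeHistogram"))
#' Occurrence probability per burst size
#' @rdname accessors
#' @export
setMethod("sizeHistogram", "BurstCatalog", function(object) {
  tab <- table(object@sizes)
  p <- as.numeric(tab) / length(object@sizes)
  names(p) <- names(tab)
  p
})

#' @rdname accessors
#' @export
setGeneric("combinedSignal", function(object) standardGeneric("combinedSignal"))
#' The net modulation gamma1 - gamma2 - gamma3 - gamma4
#' @rdname accessors
#' @export
setMethod("combinedSignal", "GlobalSignals", function(object)
  object@gamma1 - object@gamma2 - object@gamma3 - object@gamma4)

setMethod("show", "NetworkConfig", function(object) {
  cat(sprintf("NetworkConfig: %d recurrent + %d external neurons, pMax = %g, p0 = %g\n",
              object@nNeurons, object@nExternal, object@pMax, object@p0))
})

setMethod("show", "SynapticParameters", function(object) {
  n <- nrow(object@weights)
  cat(sprintf("SynapticParameters: %d recurrent neurons, %d external inputs\n",
              n, ncol(object@weights) - n))
  cat(sprintf("  weight range [%.4g, %.4g], threshold range [%.4g, %.4g]\n",
              min(object@weights), max(object@weights),
              min(object@thresholds), max(object@thresholds)))
})

setMethod("show", "SpikeRaster", function(object) {
  cat(sprintf("SpikeRaster: %d steps x %d neurons, %d spikes (rate %.4g)%s\n",
              nrow(object@spikes), ncol(object@spikes), sum(object@spikes),
              mean(object@spikes),
              if (is.null(object@inputs)) "" else ", membrane inputs recorded"))
})

setMethod("show", "BurstCatalog", function(object) {
  cat(sprintf("BurstCatalog: %d bursts, sizes 1..%s\n", length(object@sizes),
              if (length(object@sizes)) max(object@sizes) else "-"))
})

setMethod("show", "GlobalSignals", function(object) {
  cat(sprintf("GlobalSignals: g1 = %.4g, g2 = %.4g, g3 = %.4g, g4 = %.4g, combined = %.4g\n",
              object@gamma1, object@gamma2, object@gamma3, object@gamma4,
              combinedSignal(object)))
})

setMethod("show", "SequenceCensus", function(object) {
  cat(sprintf("SequenceCensus over %d steps (%d distinct patterns):\n",
              object@window, object@nPatterns))
  print(object@census)
})

setMethod("show", "ChainGraph", function(object) {
  cat(sprintf("ChainGraph: %d nodes, %d strong edges (w > %g), depth <= %d\n",
              nrow(object@nodes), nrow(object@edges), object@threshold,
              object@maxDepth))
})

setMethod("show", "ImageSet", function(object) {
  sides <- vapply(object@images, nrow, integer(1))
  cat(sprintf("ImageSet: %d images (%s), side %s\n", length(object@images),
              object@provenance, paste(unique(sides), collapse = "/")))
})
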