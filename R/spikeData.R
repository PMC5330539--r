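#' Assemble a SpikeData raster
#'
#' Low-level constructor used by the simulator, the surrogate generators
#' and the raster reader.  Spike times are sorted per neuron.
#'
#' @param spikes list of numeric spike-time vectors (ms), one per neuron.
#' @param label character vector of \code{"E"}/\code{"I"} labels.
#' @param duration raster duration (ms).
#' @param params provenance: a \code{NetworkParams} or a descriptive list.
#' @return a \code{\link{SpikeData}} object.
#' @export
spikeData <- function(spikes, label, duration, params = list(origin = "user")) {
  spikes <- lapply(spikes, function(s) sort(as.numeric(s)))
  new("SpikeData", spikes = spikes, label = as.character(label),
      duration = as.numeric(duration), params = params)
}

#' @rdname SpikeData-class
#' @export
setMethod("spikeTimes", "SpikeData", function(x) x@spikes)

#' @rdname SpikeData-class
#' @export
setMethod("popLabels", "SpikeData", function(x) x@label)

#' @rdname SpikeData-class
#' @export
setMethod("nNeurons", "SpikeData", function(x) length(x@spikes))

#' @rdname SpikeData-class
#' @export
setMethod("rasterDuration", "SpikeData", function(x) x@duration)

#' @rdname SpikeData-class
#' @export
setMethod("firingRate", "SpikeData", function(x, population = "E") {
  idx <- .popIndex(x, population)
  n_spk <- sum(lengths(x@spikes[idx]))
  n_spk / length(idx) / (x@duration / 1000)
})

setMethod("show", "SpikeData", function(object) {
  nE <- sum(object@label == "E")
  nI <- sum(object@label == "I")
  cat("SpikeData:", length(object@spikes), "neurons (E =", nE, ", I =", nI,
      "),", round(object@duration / 1000, 3), "s\n")
  cat("  total spikes:", sum(lengths(object@spikes)), "\n")
  if (nE > 0)
    cat("  mean excitatory rate:", round(firingRate(object, "E"), 3), "Hz\n")
})

# indices of neurons in a population ("E", "I" or "all")
.popIndex <- function(x, population = c("E", "I", "all")) {
  population <- match.arg(population)
  if (population == "all") seq_along(x@spikes)
  else which(x@label == population)
}
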