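#' @rdname SpikeData-class
#' @param x a \code{SpikeData} object.
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))

#' @rdname SpikeData-class
#' @export
setGeneric("popLabels", function(x) standardGeneric("popLabels"))

#' @rdname SpikeData-class
#' @export
setGeneric("nNeurons", function(x) standardGeneric("nNeurons"))

#' @rdname SpikeData-class
#' @export
setGeneric("rasterDuration", function(x) standardGeneric("rasterDuration"))

#' @rdname SpikeData-class
#' @param population which population to summarise: \code{"E"}, \code{"I"}
#'   or \code{"all"}.
#' @export
setGeneric("firingRate", function(x, population = "E")
  standardGeneric("firingRate"))

#' @rdname AvalancheSet-class
#' @param x an \code{AvalancheSet}.
#' @export
setGeneric("avalancheSizes", function(x) standardGeneric("avalancheSizes"))

#' @rdname AvalancheSet-class
#' @export
setGeneric("avalancheDurations", function(x)
  standardGeneric("avalancheDurations"))

#' @rdname AvalancheSet-class
#' @export
setGeneric("waitingTimes", function(x) standardGeneric("waitingTimes"))

#' @rdname PowerLawFit-class
#' @param x a \code{PowerLawFit}.
#' @export
setGeneric("plExponent", function(x) standardGeneric("plExponent"))

#' @rdname PowerLawFit-class
#' @export
setGeneric("plDistance", function(x) standardGeneric("plDistance"))

#' Plug-in entropy of a pattern ensemble
#'
#' @param x a \code{\link{PatternEnsemble}} (or a list of them, for which
#'   the subset-averaged entropy is returned).
#' @return entropy in bits.
#' @export
setGeneric("patternEntropy", function(x) standardGeneric("patternEntropy"))
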