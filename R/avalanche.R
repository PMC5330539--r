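#' Extract neuronal avalanches from a spike raster
#'
#' Bins the pooled spikes of the chosen population (excitatory by
#' convention for spike-based avalanche analysis) into half-open windows
#' \eqn{[k\delta t, (k+1)\delta t)} and identifies avalanches as maximal
#' runs of consecutive non-empty bins flanked by empty bins.  The size of
#' an avalanche is the number of distinct neurons firing during the run
#' (default) or the total spike count; durations are reported in bins, and
#' waiting times as the number of empty bins between consecutive
#' avalanches times \eqn{\delta t}.
#'
#' @param x a \code{\link{SpikeData}} raster.
#' @param delta_t bin width \eqn{\delta t} (ms); sensible values range
#'   from the integration step up to about 1 ms.  The default 0.1 ms sits
#'   near the mean population inter-event interval of the reference
#'   network, the standard choice for spike-based avalanche binning.
#' @param population population whose spikes define the avalanches.
#' @param size \code{"neurons"} (distinct participating neurons, default)
#'   or \code{"spikes"} (total spike count).
#' @return an \code{\link{AvalancheSet}}.  An empty raster yields an empty
#'   set with a warning.
#' @examples
#' r <- generateSurrogate("poisson", n_neurons = 20, rate = 20,
#'                        duration = 2, seed = 1)
#' av <- extractAvalanches(r, delta_t = 1)
#' length(avalancheSizes(av))
#' @export
extractAvalanches <- function(x, delta_t = 0.1, population = "E",
                              size = c("neurons", "spikes")) {
  size <- match.arg(size)
  stopifnot(is(x, "SpikeData"), delta_t > 0)
  idx <- .popIndex(x, population)
  nb <- as.integer(floor(x@duration / delta_t))
  tt <- unlist(x@spikes[idx], use.names = FALSE)
  nn <- rep.int(idx, lengths(x@spikes[idx]))
  keep <- tt < nb * delta_t
  tt <- tt[keep]; nn <- nn[keep]
  if (!length(tt)) {
    warning("raster has no spikes in population '", population,
            "'; returning an empty AvalancheSet")
    return(new("AvalancheSet", sizes = integer(), sizesSpikes = integer(),
               durations = integer(), startBin = integer(),
               waiting = numeric(), binWidth = delta_t, sizeDef = size,
               nBins = nb))
  }
  b <- as.integer(floor(tt / delta_t))
  ub <- sort(unique(b))
  run_of_ub <- cumsum(c(1L, as.integer(diff(ub) > 1L)))
  nrun <- run_of_ub[length(run_of_ub)]
  run_first <- ub[!duplicated(run_of_ub)]
  run_last <- ub[!duplicated(run_of_ub, fromLast = TRUE)]
  durations <- run_last - run_first + 1L

  run_of_spike <- run_of_ub[match(b, ub)]
  sizes_spikes <- tabulate(run_of_spike, nbins = nrun)
  key <- !duplicated(run_of_spike * (max(nn) + 1) + nn)
  sizes_neurons <- tabulate(run_of_spike[key], nbins = nrun)

  waiting <- if (nrun > 1)
    (run_first[-1] - run_last[-nrun] - 1L) * delta_t else numeric()

  new("AvalancheSet",
      sizes = as.integer(if (size == "neurons") sizes_neurons
                         else sizes_spikes),
      sizesSpikes = as.integer(sizes_spikes),
      durations = as.integer(durations),
      startBin = as.integer(run_first),
      waiting = as.numeric(waiting),
      binWidth = delta_t, sizeDef = size, nBins = nb)
}

#' @rdname AvalancheSet-class
#' @export
setMethod("avalancheSizes", "AvalancheSet", function(x) x@sizes)

#' @rdname AvalancheSet-class
#' @export
setMethod("avalancheDurations", "AvalancheSet", function(x) x@durations)

#' @rdname AvalancheSet-class
#' @export
setMethod("waitingTimes", "AvalancheSet", function(x) x@waiting)

setMethod("show", "AvalancheSet", function(object) {
  cat("AvalancheSet:", length(object@sizes), "avalanches (bin",
      object@binWidth, "ms, size =", object@sizeDef, ")\n")
  if (length(object@sizes))
    cat("  sizes: median", median(object@sizes), ", max",
        max(object@sizes), "; mean duration",
        round(mean(object@durations), 2), "bins\n")
})
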