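#' Windowed population spike patterns from sampled neuron subsets
#'
#' Tiles the raster into consecutive non-overlapping windows of
#' \eqn{\Delta\tau} ms (the final partial window is dropped) and, for each
#' of \code{n_samples} seeded random subsets of \code{n} excitatory
#' neurons, records the per-window pattern: in the binary scenario a
#' neuron contributes 1 if it fired at least once in the window, in the
#' analog scenario its spike count (capped at 10, the most a neuron
#' respecting the 2-ms refractory period can realistically place in a
#' 20-ms window).  Energy bookkeeping (mean spikes per window) always uses
#' the uncapped counts, since every emitted spike costs energy regardless
#' of the encoding.
#'
#' @param x a \code{\link{SpikeData}} raster.
#' @param window pattern window \eqn{\Delta\tau} (ms).
#' @param n neurons per sampled subset.
#' @param scenario \code{"binary"} or \code{"analog"}.
#' @param n_samples number of random subsets.
#' @param seed RNG seed for subset sampling.
#' @param population population sampled (excitatory by convention).
#' @param count_cap cap on per-window spike counts in the analog pattern.
#' @return a list of \code{\link{PatternEnsemble}} objects, one per
#'   subset.
#' @examples
#' r <- generateSurrogate("poisson", n_neurons = 60, rate = 3,
#'                        duration = 10, seed = 1)
#' ens <- makePatterns(r, n = 20, scenario = "binary", n_samples = 5,
#'                     seed = 2)
#' patternEntropy(ens)
#' @export
makePatterns <- function(x, window = 20, n = 40,
                         scenario = c("binary", "analog"),
                         n_samples = 100, seed = NULL, population = "E",
                         count_cap = 10) {
  scenario <- match.arg(scenario)
  stopifnot(is(x, "SpikeData"), window > 0)
  idx <- .popIndex(x, population)
  if (n > length(idx))
    stop("n = ", n, " exceeds the population size ", length(idx))
  Tw <- as.integer(floor(x@duration / window))
  if (Tw < 1) stop("raster shorter than one pattern window")

  counts <- .spikeCountMatrix(x, idx, window, Tw)   # sparse: neuron x window

  .withSeed(seed, {
    lapply(seq_len(n_samples), function(s) {
      sub <- sort(sample.int(length(idx), n))
      M <- as.matrix(counts[sub, , drop = FALSE])   # n x Tw, uncapped
      m <- mean(colSums(M))
      mn <- mean(colSums(M > 0))
      P <- if (scenario == "binary") (M > 0) + 0L else pmin(M, count_cap)
      keys <- do.call(paste, c(as.data.frame(t(P)), list(sep = ",")))
      tab <- table(keys)
      new("PatternEnsemble", scenario = scenario, window = window,
          n = as.integer(n), neurons = as.integer(idx[sub]),
          counts = setNames(as.integer(tab), names(tab)),
          Tw = Tw, m = m, mn = mn)
    })
  })
}

# neuron x window spike-count matrix for the given neuron indices,
# windows tiling [0, Tw * window)
.spikeCountMatrix <- function(x, idx, window, Tw) {
  tt <- unlist(x@spikes[idx], use.names = FALSE)
  rr <- rep.int(seq_along(idx), lengths(x@spikes[idx]))
  w <- floor(tt / window) + 1
  keep <- w <= Tw
  Matrix::sparseMatrix(i = rr[keep], j = w[keep], x = 1,
                       dims = c(length(idx), Tw))
}

#' @rdname patternEntropy
#' @export
setMethod("patternEntropy", "PatternEnsemble", function(x) {
  p <- x@counts / x@Tw
  -sum(p * log2(p))
})

#' @rdname patternEntropy
#' @export
setMethod("patternEntropy", "list", function(x) {
  mean(vapply(x, patternEntropy, numeric(1)))
})

setMethod("show", "PatternEnsemble", function(object) {
  cat("PatternEnsemble (", object@scenario, "): n = ", object@n, ", ",
      object@Tw, " windows of ", object@window, " ms, ",
      length(object@counts), " distinct patterns\n", sep = "")
  cat("  m =", round(object@m, 3), ", m_n =", round(object@mn, 3), "\n")
})

#' Empty-pattern probability: observed vs independent-firing prediction
#'
#' The fraction of windows in which none of the sampled neurons fired,
#' compared with the prediction for independently firing neurons at the
#' matched mean spiking-neuron count,
#' \eqn{p_0 = (1 - m_n/n)^n \approx e^{-m_n}}.  Close agreement indicates
#' that, bursting aside, neurons fire near-independently.
#'
#' @param ensembles a \code{\link{PatternEnsemble}} or list of them
#'   (subset-averaged).
#' @return list with \code{p0_observed}, \code{p0_predicted} and the
#'   exponential approximation \code{p0_exp}.
#' @export
emptyPatternProbability <- function(ensembles) {
  if (is(ensembles, "PatternEnsemble")) ensembles <- list(ensembles)
  obs <- vapply(ensembles, function(e) {
    key0 <- paste(rep("0", e@n), collapse = ",")
    cnt <- e@counts[key0]
    (if (is.na(cnt)) 0 else cnt) / e@Tw
  }, numeric(1))
  mn <- mean(vapply(ensembles, function(e) e@mn, numeric(1)))
  n <- ensembles[[1]]@n
  list(p0_observed = mean(obs),
       p0_predicted = (1 - mn / n)^n,
       p0_exp = exp(-mn))
}
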