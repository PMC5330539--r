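#' Binned population activity
#'
#' Number of spikes across a population per time bin (default 1 ms), the
#' basis of the autocorrelation, spectrum and avalanche analyses.
#'
#' @slot counts spike counts per bin.
#' @slot bin bin width (ms).
#' @slot population \code{"E"}, \code{"I"} or \code{"all"}.
#' @exportClass PopulationActivity
setClass("PopulationActivity",
  slots = c(counts = "numeric", bin = "numeric", population = "character")
)

setMethod("show", "PopulationActivity", function(object) {
  cat("PopulationActivity (", object@population, "): ",
      length(object@counts), " bins of ", object@bin, " ms, mean ",
      round(mean(object@counts), 3), " spikes/bin\n", sep = "")
})

#' @rdname PopulationActivity-class
#' @param x a \code{\link{SpikeData}} raster.
#' @param bin bin width (ms).
#' @param population population to pool (\code{"all"}, \code{"E"},
#'   \code{"I"}).
#' @return a \code{PopulationActivity} with
#'   \code{floor(duration/bin)} bins.
#' @export
populationActivity <- function(x, bin = 1, population = "all") {
  stopifnot(is(x, "SpikeData"), bin > 0)
  idx <- .popIndex(x, population)
  nb <- floor(x@duration / bin)
  tt <- unlist(x@spikes[idx], use.names = FALSE)
  cnt <- if (length(tt)) {
    b <- floor(tt / bin) + 1
    tabulate(b[b <= nb], nbins = nb)
  } else rep(0L, nb)
  new("PopulationActivity", counts = as.numeric(cnt), bin = bin,
      population = population)
}

#' Coefficient of variation of inter-spike intervals
#'
#' \code{isiCV} computes CV = SD/mean of one spike train's inter-spike
#' intervals, using the population (divide-by-N) standard deviation.
#' Trains with fewer than three spikes (fewer than two intervals) are
#' undefined and return \code{NA}.  \code{meanISICV} averages the CV over
#' all defined neurons of a population: values near 1 indicate
#' Poisson-like irregular firing, values well above 1 bursting, values
#' near 0 clock-like firing.
#'
#' @param spikes numeric vector of one neuron's spike times (ms).
#' @return \code{isiCV}: a single CV value, or \code{NA} if undefined.
#' @examples
#' isiCV(c(0, 10, 30))  # intervals 10, 20 -> 1/3
#' @export
isiCV <- function(spikes) {
  if (length(spikes) < 3) return(NA_real_)
  isi <- diff(spikes)
  mu <- mean(isi)
  sdev <- sqrt(mean((isi - mu)^2))
  sdev / mu
}

#' @rdname isiCV
#' @param x a \code{\link{SpikeData}} raster.
#' @param population population over which to average.
#' @return \code{meanISICV}: the population-mean CV, excluding undefined
#'   neurons.
#' @export
meanISICV <- function(x, population = "E") {
  idx <- .popIndex(x, population)
  cvs <- vapply(x@spikes[idx], isiCV, numeric(1))
  mean(cvs, na.rm = TRUE)
}

#' Pairwise spike-train synchrony index
#'
#' Average pair coherence over randomly sampled neuron pairs.  Each train
#' is binarised into 0/1 per \code{bin} (default 1 ms); for a pair
#' \eqn{(i, j)} the coherence is
#' \deqn{K_{ij} = \frac{\sum_k B_i(k) B_j(k)}
#'   {\sqrt{\sum_k B_i(k)\,\sum_k B_j(k)}},}
#' the probability of spiking together within a bin, normalised by the
#' geometric mean of the spike counts (set
#' \code{normalization = "product"} for the plain-product denominator
#' \eqn{\sum B_i \sum B_j}).  Pairs involving a silent neuron are skipped.
#'
#' @param x a \code{\link{SpikeData}} raster.
#' @param population population from which pairs are drawn.
#' @param n_pairs number of random distinct pairs to sample.
#' @param bin bin width (ms).
#' @param seed RNG seed for pair sampling.
#' @param normalization \code{"geometric"} (default) or \code{"product"}.
#' @return mean pairwise coherence in \eqn{[0, 1]}.
#' @export
synchronyIndex <- function(x, population = "E", n_pairs = 2000, bin = 1,
                           seed = NULL,
                           normalization = c("geometric", "product")) {
  normalization <- match.arg(normalization)
  idx <- .popIndex(x, population)
  active <- idx[lengths(x@spikes[idx]) > 0]
  if (length(active) < 2)
    stop("need at least 2 active neurons in population '", population, "'")
  nb <- floor(x@duration / bin)
  # occupied-bin index sets, sorted and unique, one per active neuron
  binsets <- lapply(x@spikes[active], function(tt) {
    b <- floor(tt / bin)
    unique(b[b < nb])
  })
  .withSeed(seed, {
    na <- length(active)
    nmax <- na * (na - 1) / 2
    if (n_pairs >= nmax) {
      # enumerate every distinct pair (deterministic, relabel-invariant)
      np <- nmax
      i1 <- rep.int(seq_len(na - 1), (na - 1):1)
      i2 <- unlist(lapply(seq_len(na - 1), function(i) (i + 1):na),
                   use.names = FALSE)
    } else {
      np <- n_pairs
      i1 <- sample.int(na, np, replace = TRUE)
      i2 <- sample.int(na - 1, np, replace = TRUE)
      i2 <- ifelse(i2 >= i1, i2 + 1L, i2)  # distinct pair, uniform
    }
    ks <- vapply(seq_len(np), function(p) {
      a <- binsets[[i1[p]]]
      b <- binsets[[i2[p]]]
      num <- length(.intersectSortedInt(a, b))
      den <- if (normalization == "geometric")
        sqrt(length(a) * length(b)) else length(a) * length(b)
      num / den
    }, numeric(1))
    mean(ks)
  })
}

# intersection of two sorted integer vectors
.intersectSortedInt <- function(a, b) a[a %in% b]

#' Autocorrelation of the population activity
#'
#' Mean-centred autocorrelation of the binned population activity,
#' normalised by the squared mean activity and the number of bins:
#' \deqn{AC(\tau) = \frac{1}{\langle A\rangle^2 T}
#'   \sum_t \big(A(t+\tau)-\langle A\rangle\big)
#'          \big(A(t)-\langle A\rangle\big).}
#' A constant activity gives \eqn{AC \equiv 0}; at zero lag
#' \eqn{AC(0) = \mathrm{Var}(A)/\langle A\rangle^2}; periodic activity
#' produces local maxima at multiples of its period.
#'
#' @param activity a \code{\link{PopulationActivity}}.
#' @param max_lag maximum lag (ms).
#' @return data.frame with columns \code{lag} (ms) and \code{ac}.
#' @export
populationAutocorrelation <- function(activity, max_lag = 100) {
  stopifnot(is(activity, "PopulationActivity"))
  A <- activity@counts
  if (all(A == 0)) stop("population activity is identically zero")
  Tn <- length(A)
  mu <- mean(A)
  z <- A - mu
  lags <- 0:floor(max_lag / activity@bin)
  ac <- vapply(lags, function(L) {
    sum(z[seq_len(Tn - L)] * z[seq_len(Tn - L) + L]) / (mu^2 * Tn)
  }, numeric(1))
  data.frame(lag = lags * activity@bin, ac = ac)
}

#' Averaged cross-correlogram of neuron pairs
#'
#' For randomly sampled ordered pairs, the firing rate of one neuron is
#' histogrammed relative to the spike times of the other, and averaged
#' over pairs.  Independent trains give a flat curve at the mean rate of
#' the target neurons; synchrony concentrates mass around zero lag.
#'
#' @param x a \code{\link{SpikeData}} raster.
#' @param n_pairs number of random ordered pairs.
#' @param window half-width of the lag window (ms).
#' @param bin lag-histogram bin (ms).
#' @param seed RNG seed for pair sampling.
#' @param population population from which pairs are drawn.
#' @return data.frame with columns \code{lag} (bin centres, ms) and
#'   \code{rate} (Hz).
#' @export
crossCorrelogram <- function(x, n_pairs = 2000, window = 50, bin = 1,
                             seed = NULL, population = "E") {
  idx <- .popIndex(x, population)
  active <- idx[lengths(x@spikes[idx]) > 0]
  if (length(active) < 2) stop("raster has fewer than 2 active neurons")
  edges <- seq(-window, window, by = bin)
  centers <- edges[-1] - bin / 2
  counts <- numeric(length(centers))
  nref <- 0
  .withSeed(seed, {
    np <- n_pairs
    i1 <- sample(active, np, replace = TRUE)
    i2 <- sample(active, np, replace = TRUE)
    swap <- i1 == i2
    while (any(swap)) {          # resample collisions
      i2[swap] <- sample(active, sum(swap), replace = TRUE)
      swap <- i1 == i2
    }
    for (p in seq_len(np)) {
      ti <- x@spikes[[i1[p]]]
      tj <- x@spikes[[i2[p]]]
      lo <- findInterval(ti - window, tj)
      hi <- findInterval(ti + window, tj)
      keep <- hi > lo
      if (any(keep)) {
        d <- unlist(lapply(which(keep), function(q)
          tj[(lo[q] + 1):hi[q]] - ti[q]), use.names = FALSE)
        d <- d[d >= -window & d < window]
        bidx <- floor((d + window) / bin) + 1
        counts <- counts + tabulate(bidx, nbins = length(centers))
      }
      nref <- nref + length(ti)
    }
  })
  rate <- counts / nref / (bin / 1000)
  data.frame(lag = centers, rate = rate)
}
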