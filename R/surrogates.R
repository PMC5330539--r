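#' Seeded surrogate spike rasters with known statistical structure
#'
#' Generators for rasters whose ground-truth statistics are known in
#' closed form, used to validate every analysis stage without running the
#' network:
#' \describe{
#'   \item{\code{"poisson"}}{independent homogeneous Poisson trains of
#'     the given rate (ISI CV 1, pairwise 1-ms synchrony about
#'     \eqn{rate \times 0.001}).}
#'   \item{\code{"gamma_renewal"}}{renewal trains with gamma ISIs of
#'     shape \code{shape}, so the ISI CV is \eqn{1/\sqrt{shape}}.}
#'   \item{\code{"jittered_sync"}}{each neuron copies the events of a
#'     hidden mother Poisson train with probability \code{c_copy}
#'     (optionally jittered) and adds independent background spikes, so
#'     pairwise synchrony is tunable through \code{c_copy}.}
#'   \item{\code{"branching"}}{a discrete-time branching process: each
#'     active unit in a bin triggers Poisson(\code{sigma}) units in the
#'     next bin; silent bins restart activity with one initiating unit at
#'     rate \code{drive}; units are mapped to neuron indices round-robin.
#'     At \code{sigma = 1} the avalanche sizes follow the critical
#'     branching law \eqn{P(s) \sim s^{-3/2}}.}
#' }
#'
#' @param kind surrogate family (see above).
#' @param n_neurons number of neurons.
#' @param rate per-neuron firing rate (Hz) for the renewal families and
#'   the mother train.
#' @param duration raster length (s).
#' @param seed RNG seed.
#' @param shape gamma ISI shape parameter \eqn{k}.
#' @param c_copy copy probability of mother events.
#' @param jitter_ms Gaussian jitter SD applied to copied events (ms).
#' @param sigma branching parameter (mean offspring per active unit).
#' @param drive per-bin probability of initiating an avalanche when the
#'   process is silent.
#' @param bin branching-process bin width (ms).
#' @param max_size truncation of the avalanche-size support: an
#'   avalanche whose cumulative unit count exceeds this is discarded
#'   from the raster, so the generated sizes follow the branching law
#'   conditioned on size at most \code{max_size} (and critical and
#'   supercritical runs stay finite).
#' @return a \code{\link{SpikeData}} raster; all neurons labelled
#'   \code{"E"}.
#' @examples
#' r <- generateSurrogate("gamma_renewal", n_neurons = 10, rate = 10,
#'                        duration = 20, shape = 4, seed = 1)
#' meanISICV(r)  # ~ 0.5
#' @export
generateSurrogate <- function(kind = c("poisson", "gamma_renewal",
                                       "jittered_sync", "branching"),
                              n_neurons = 100, rate = 5, duration = 10,
                              seed = NULL, shape = 1, c_copy = 0.5,
                              jitter_ms = 0, sigma = 1, drive = 0.05,
                              bin = 1, max_size = 10000) {
  kind <- match.arg(kind)
  stopifnot(n_neurons >= 1, duration > 0, rate >= 0,
            c_copy >= 0, c_copy <= 1, sigma > 0)
  dur_ms <- duration * 1000
  tag <- list(origin = "surrogate", kind = kind, rate = rate,
              shape = shape, c_copy = c_copy, sigma = sigma, seed = seed)
  spikes <- .withSeed(seed, switch(kind,
    poisson = lapply(seq_len(n_neurons), function(i)
      .renewalTrain(dur_ms, function(n) rexp(n, rate / 1000))),
    gamma_renewal = lapply(seq_len(n_neurons), function(i)
      .renewalTrain(dur_ms, function(n)
        rgamma(n, shape = shape, rate = shape * rate / 1000))),
    jittered_sync = {
      mother <- .renewalTrain(dur_ms, function(n) rexp(n, rate / 1000))
      lapply(seq_len(n_neurons), function(i) {
        copied <- mother[runif(length(mother)) < c_copy]
        if (jitter_ms > 0 && length(copied))
          copied <- copied + rnorm(length(copied), sd = jitter_ms)
        bg <- .renewalTrain(dur_ms, function(n)
          rexp(n, max(1e-12, rate * (1 - c_copy)) / 1000))
        tt <- sort(c(copied, bg))
        unique(tt[tt >= 0 & tt < dur_ms])
      })
    },
    branching = .branchingRaster(n_neurons, dur_ms, sigma, drive, bin,
                                 max_size)
  ))
  spikeData(spikes, rep("E", n_neurons), dur_ms, tag)
}

# renewal train on [0, dur_ms): cumulative sums of ISIs drawn by `risi`
.renewalTrain <- function(dur_ms, risi) {
  out <- numeric(0)
  t0 <- 0
  repeat {
    block <- max(32, ceiling((dur_ms - t0) * 2e-3 / 1e-3))
    isi <- risi(block)
    tt <- t0 + cumsum(isi)
    out <- c(out, tt[tt < dur_ms])
    t0 <- tt[length(tt)]
    if (t0 >= dur_ms) break
  }
  out
}

# discrete branching process mapped to neuron indices round-robin; spikes
# of one bin are spread strictly inside the bin so that avalanche
# extraction at the same bin width recovers the generated runs exactly.
# Avalanches exceeding max_size total units are discarded (truncation).
.branchingRaster <- function(n_neurons, dur_ms, sigma, drive, bin,
                             max_size) {
  nb <- floor(dur_ms / bin)
  chunks_n <- list()
  chunks_t <- list()
  nc <- 0L
  av_n <- list()
  av_t <- list()
  na <- 0L
  a <- 0L
  unit <- 0L
  cum <- 0L
  for (k in seq_len(nb)) {
    a <- if (a == 0L) {
      cum <- 0L
      if (runif(1) < drive) 1L else 0L
    } else {
      as.integer(rpois(1, sigma * a))
    }
    if (a > 0L) {
      cum <- cum + a
      na <- na + 1L
      av_n[[na]] <- (unit + seq_len(a) - 1L) %% n_neurons + 1L
      av_t[[na]] <- (k - 1) * bin + bin * seq_len(a) / (a + 1)
      unit <- unit + a
      if (cum > max_size) {      # truncated: discard this avalanche
        av_n <- list()
        av_t <- list()
        na <- 0L
        a <- 0L
      }
    } else if (na > 0L) {        # natural extinction: commit
      nc <- nc + 1L
      chunks_n[[nc]] <- unlist(av_n, use.names = FALSE)
      chunks_t[[nc]] <- unlist(av_t, use.names = FALSE)
      av_n <- list()
      av_t <- list()
      na <- 0L
    }
  }
  if (na > 0L) {                 # cut by end of recording: commit
    nc <- nc + 1L
    chunks_n[[nc]] <- unlist(av_n, use.names = FALSE)
    chunks_t[[nc]] <- unlist(av_t, use.names = FALSE)
  }
  nn <- unlist(chunks_n, use.names = FALSE)
  tt <- unlist(chunks_t, use.names = FALSE)
  if (is.null(nn)) nn <- integer()
  if (is.null(tt)) tt <- numeric()
  unname(split(tt, factor(nn, levels = seq_len(n_neurons))))
}
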