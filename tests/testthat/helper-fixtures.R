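# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

# full-size reference-state raster, memoised across test files
referenceRaster <- function(tau_de, tau_di, duration = 51, seed = 42) {
  key <- paste("ref", tau_de, tau_di, duration, seed, sep = "_")
  if (!exists(key, envir = .fixture_cache)) {
    p <- networkParams(tau_de = tau_de, tau_di = tau_di,
                       duration = duration, discard = 1, seed = seed)
    assign(key, simulateNetwork(p), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

referenceAnalysis <- function(tau_de, tau_di, duration = 51, seed = 42) {
  key <- paste("ana", tau_de, tau_di, duration, seed, sep = "_")
  if (!exists(key, envir = .fixture_cache)) {
    a <- analyzeRaster(referenceRaster(tau_de, tau_di, duration, seed),
                       n_samples = 100, seed = seed)
    assign(key, a, envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small raster with spikes at prescribed (neuron, time) pairs
rasterFromSpikes <- function(neuron, time, n_neurons, duration,
                             label = rep("E", n_neurons)) {
  spikes <- unname(split(time, factor(neuron, levels = seq_len(n_neurons))))
  spikeData(spikes, label, duration)
}

# pattern ensemble with a prescribed count table (for arithmetic checks)
ensembleFromCounts <- function(counts, n, Tw = sum(counts), m = 1, mn = 1,
                               scenario = "binary", window = 20) {
  new("PatternEnsemble", scenario = scenario, window = window,
      n = as.integer(n), neurons = seq_len(n),
      counts = setNames(as.integer(counts), names(counts)),
      Tw = as.integer(Tw), m = m, mn = mn)
}
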