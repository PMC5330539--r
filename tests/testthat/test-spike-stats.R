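test_that("ISI CV handles the textbook cases", {
  expect_equal(isiCV(c(0, 10, 20, 30)), 0)
  expect_equal(isiCV(c(0, 10, 30)), 1 / 3)   # population-SD convention
  expect_true(is.na(isiCV(c(0, 10))))
})

test_that("CV of renewal surrogates recovers the theory", {
  g <- generateSurrogate("gamma_renewal", n_neurons = 2, rate = 50,
                         duration = 120, shape = 4, seed = 2)
  expect_equal(meanISICV(g), 1 / sqrt(4), tolerance = 0.05)
  po <- generateSurrogate("poisson", n_neurons = 2, rate = 50,
                          duration = 120, seed = 2)
  expect_equal(meanISICV(po), 1, tolerance = 0.05)
})

test_that("pair coherence is 1 for identical and 0 for disjoint trains", {
  tt <- seq(0.5, 900, by = 7)
  r_same <- rasterFromSpikes(rep(1:2, each = length(tt)), c(tt, tt),
                             2, 1000)
  expect_equal(synchronyIndex(r_same, n_pairs = 10, seed = 1), 1)
  r_disj <- rasterFromSpikes(rep(1:2, each = length(tt)), c(tt, tt + 3),
                             2, 1000)
  expect_equal(synchronyIndex(r_disj, n_pairs = 10, seed = 1), 0)
})

test_that("independent Poisson pairs cohere at about rate times bin", {
  po <- generateSurrogate("poisson", n_neurons = 40, rate = 10,
                          duration = 60, seed = 3)
  expect_equal(synchronyIndex(po, n_pairs = 500, seed = 4), 0.010,
               tolerance = 0.15)
})

test_that("synchrony is invariant to neuron relabelling", {
  po <- generateSurrogate("poisson", n_neurons = 20, rate = 10,
                          duration = 30, seed = 5)
  perm <- sample(seq_len(20))
  shuffled <- spikeData(spikeTimes(po)[perm], popLabels(po)[perm],
                        rasterDuration(po))
  # full pair set (n_pairs above the maximum) removes sampling noise
  expect_equal(synchronyIndex(po, n_pairs = 1e4, seed = 1),
               synchronyIndex(shuffled, n_pairs = 1e4, seed = 1),
               tolerance = 1e-12)
})

test_that("more copying from a mother train raises synchrony", {
  lowc <- generateSurrogate("jittered_sync", n_neurons = 20, rate = 10,
                            duration = 30, c_copy = 0.2, seed = 6)
  highc <- generateSurrogate("jittered_sync", n_neurons = 20, rate = 10,
                             duration = 30, c_copy = 0.8, seed = 6)
  expect_gt(synchronyIndex(highc, n_pairs = 400, seed = 1),
            2 * synchronyIndex(lowc, n_pairs = 400, seed = 1))
})

test_that("population autocorrelation obeys its defining identities", {
  act <- new("PopulationActivity", counts = rep(5, 1000), bin = 1,
             population = "E")
  expect_true(all(populationAutocorrelation(act, 20)$ac == 0))
  set.seed(1)
  act2 <- new("PopulationActivity", counts = rpois(5000, 4), bin = 1,
              population = "E")
  ac <- populationAutocorrelation(act2, 20)
  A <- act2@counts
  expect_equal(ac$ac[1], mean((A - mean(A))^2) / mean(A)^2,
               tolerance = 1e-12)
  # strict periodicity: maxima at multiples of the period
  act3 <- new("PopulationActivity", counts = rep(c(5, 0, 0, 0), 500),
              bin = 1, population = "E")
  ac3 <- populationAutocorrelation(act3, 12)
  peaks <- ac3$lag[which(diff(sign(diff(ac3$ac))) == -2) + 1]
  expect_equal(peaks, c(4, 8))
  expect_error(populationAutocorrelation(
    new("PopulationActivity", counts = rep(0, 100), bin = 1,
        population = "E")), "zero")
})

test_that("cross-correlogram is flat for independent trains, peaked for identical", {
  po <- generateSurrogate("poisson", n_neurons = 30, rate = 5,
                          duration = 120, seed = 7)
  cc <- crossCorrelogram(po, n_pairs = 300, seed = 8)
  expect_equal(mean(cc$rate), 5, tolerance = 0.1)
  expect_lt(diff(range(cc$rate)) / mean(cc$rate), 0.5)
  tt <- seq(0.5, 990, by = 11)
  ident <- rasterFromSpikes(rep(1:2, each = length(tt)), c(tt, tt), 2, 1000)
  cci <- crossCorrelogram(ident, n_pairs = 4, seed = 1)
  expect_lte(abs(cci$lag[which.max(cci$rate)]), 0.5)
  empty <- spikeData(list(numeric(), numeric()), c("E", "E"), 1000)
  expect_error(crossCorrelogram(empty), "active")
})
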