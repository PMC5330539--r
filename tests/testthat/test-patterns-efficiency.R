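test_that("binary and analog encodings map window counts as specified", {
  # one neuron, two spikes inside the first 20-ms window
  r <- rasterFromSpikes(neuron = c(1, 1, 2), time = c(3, 9, 25),
                        n_neurons = 2, duration = 40)
  bin <- makePatterns(r, window = 20, n = 2, scenario = "binary",
                      n_samples = 1, seed = 1)[[1]]
  ana <- makePatterns(r, window = 20, n = 2, scenario = "analog",
                      n_samples = 1, seed = 1)[[1]]
  expect_setequal(names(bin@counts), c("1,0", "0,1"))
  expect_setequal(names(ana@counts), c("2,0", "0,1"))
  expect_equal(bin@m, 1.5)    # energy still counts both spikes
  expect_equal(bin@mn, 1)
})

test_that("a silent raster maps every window to the empty pattern", {
  r <- spikeData(rep(list(numeric()), 5), rep("E", 5), 200)
  ens <- makePatterns(r, window = 20, n = 3, scenario = "binary",
                      n_samples = 2, seed = 1)
  expect_identical(names(ens[[1]]@counts), "0,0,0")
  expect_equal(patternEntropy(ens), 0)
  p0 <- emptyPatternProbability(ens)
  expect_equal(p0$p0_observed, 1)
  expect_equal(p0$p0_predicted, 1)
})

test_that("Poisson rasters give the expected mean analog count", {
  po <- generateSurrogate("poisson", n_neurons = 50, rate = 5,
                          duration = 50, seed = 2)
  ens <- makePatterns(po, window = 20, n = 30, scenario = "analog",
                      n_samples = 10, seed = 3)
  m_per_neuron <- mean(vapply(ens, function(e) e@m, numeric(1))) / 30
  expect_equal(m_per_neuron, 5 * 0.020, tolerance = 0.05)
})

test_that("plug-in entropy reproduces enumerable cases", {
  all_same <- ensembleFromCounts(c(`1,0` = 100), n = 2)
  expect_equal(patternEntropy(all_same), 0)
  four <- ensembleFromCounts(setNames(rep(25L, 4),
                                      c("0,0", "0,1", "1,0", "1,1")), n = 2)
  expect_equal(patternEntropy(four), 2)
})

test_that("plug-in entropy matches product-form entropy for independent neurons", {
  set.seed(9)
  n <- 5; Tw <- 1e5; pr <- 0.2
  M <- matrix(rbinom(n * Tw, 1, pr), n, Tw)
  keys <- do.call(paste, c(as.data.frame(t(M)), list(sep = ",")))
  ens <- ensembleFromCounts(table(keys), n = n, Tw = Tw,
                            m = mean(colSums(M)), mn = mean(colSums(M)))
  expect_equal(patternEntropy(ens), n * binaryEntropy(pr),
               tolerance = 0.01)
  # entropy bounds
  expect_lte(patternEntropy(ens), log2(length(ens@counts)) + 1e-12)
  expect_lte(log2(length(ens@counts)), log2(Tw))
})

test_that("efficiency arithmetic follows eta = H/(m + n r)", {
  four <- ensembleFromCounts(setNames(rep(25L, 4),
                                      c(paste(rep("0", 40), collapse = ","),
                                        "1", "2", "3")),
                             n = 40, m = 1, mn = 1)
  r0 <- patternEfficiency(four, r = 0)
  expect_equal(r0@H, 2)
  expect_equal(r0@etaSim, 2)
  r5 <- patternEfficiency(four, r = 0.05)
  expect_equal(r5@etaSim, 2 / 3)
})

test_that("burst decomposition identities hold to machine precision", {
  po <- generateSurrogate("poisson", n_neurons = 60, rate = 4,
                          duration = 50, seed = 4)
  for (scn in c("binary", "analog")) {
    ens <- makePatterns(po, n = 40, scenario = scn, n_samples = 10,
                        seed = 5)
    for (r in c(0, 0.005, 0.1)) {
      rpt <- patternEfficiency(ens, r = r)
      dec <- reductionDecomposition(rpt)
      lhs <- dec$R_B + dec$R_S
      rhs <- etaOpt(rpt@mn / rpt@n, r, scn) - rpt@H / (rpt@m + rpt@n * r)
      expect_equal(lhs, rhs, tolerance = 1e-12)
      if (r == 0)
        expect_equal(lhs, etaOpt(rpt@mn / rpt@n, 0, scn) - rpt@H / rpt@m,
                     tolerance = 1e-12)
    }
  }
})

test_that("burst level drives R_B as the algebra dictates", {
  no_burst <- ensembleFromCounts(c(`1,0` = 50, `0,1` = 50), n = 2,
                                 m = 1, mn = 1)
  expect_equal(reductionDecomposition(patternEfficiency(no_burst))$R_B, 0)
  burst2 <- ensembleFromCounts(c(`2,0` = 50, `0,2` = 50), n = 2,
                               m = 2, mn = 1, scenario = "analog")
  rpt <- patternEfficiency(burst2, r = 0)
  expect_equal(reductionDecomposition(rpt)$R_B, rpt@etaSim)  # B = 2
})

test_that("empty-pattern probability matches independent-firing theory", {
  expect_equal((1 - 2 / 40)^40, 0.1285, tolerance = 1e-3)
  expect_equal(exp(-2), 0.1353, tolerance = 1e-3)
  po <- generateSurrogate("poisson", n_neurons = 60, rate = 3,
                          duration = 60, seed = 5)
  ens <- makePatterns(po, n = 40, scenario = "binary", n_samples = 20,
                      seed = 6)
  p0 <- emptyPatternProbability(ens)
  expect_equal(p0$p0_observed, p0$p0_predicted, tolerance = 0.05)
})

test_that("pattern construction is deterministic and guards its domain", {
  po <- generateSurrogate("poisson", n_neurons = 30, rate = 5,
                          duration = 10, seed = 6)
  e1 <- makePatterns(po, n = 10, scenario = "binary", n_samples = 3,
                     seed = 7)
  e2 <- makePatterns(po, n = 10, scenario = "binary", n_samples = 3,
                     seed = 7)
  expect_identical(lapply(e1, function(e) e@counts),
                   lapply(e2, function(e) e@counts))
  expect_error(makePatterns(po, n = 50, scenario = "binary"), "exceeds")
})
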