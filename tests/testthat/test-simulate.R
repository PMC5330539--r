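test_that("without drive the membrane relaxes to the leak potential", {
  p <- networkParams(N = 25L, f_ex = 0, duration = 1, discard = 0,
                     seed = 1)
  s <- simulateNetwork(p, record = 1L)
  expect_identical(sum(lengths(spikeTimes(s))), 0L)
  tr <- attr(s, "trace")
  expect_equal(tr@V[nrow(tr@V), 1], -70, tolerance = 1e-6)
  expect_true(all(tr@V <= p@theta + 1e-9))
  expect_true(all(tr@G_E >= 0) && all(tr@G_I >= 0))
})

test_that("clamped-conductance firing matches the closed-form LIF rate", {
  p <- networkParams(N = 5L, C = 0, f_ex = 0, duration = 11, discard = 1,
                     seed = 3)
  s <- simulateNetwork(p, clamp_G_E = 0.5)
  gE <- 0.5
  vinf <- (p@V_L + gE * p@E_E) / (1 + gE)
  for (pop in c("E", "I")) {
    tau <- if (pop == "E") p@tau_E else p@tau_I
    trp <- if (pop == "E") p@t_rp_E else p@t_rp_I
    isi <- tau / (1 + gE) *
      log((vinf - p@V_reset) / (vinf - p@theta)) + trp
    expect_equal(firingRate(s, pop), 1000 / isi, tolerance = 0.02)
  }
})

test_that("no ISI undercuts the refractory period", {
  s <- referenceRaster(4, 10)
  lab <- popLabels(s)
  minisi <- function(idx) min(unlist(lapply(spikeTimes(s)[idx], function(t)
    if (length(t) > 1) min(diff(t)) else Inf)))
  expect_gte(minisi(which(lab == "E")), 2)
  expect_gte(minisi(which(lab == "I")), 1)
})

test_that("identical parameters and seed give bit-identical rasters", {
  p <- networkParams(N = 100L, duration = 2, discard = 0.5, seed = 9)
  top <- buildNetwork(p, seed = 2)
  s1 <- simulateNetwork(p, top, seed = 9)
  s2 <- simulateNetwork(p, top, seed = 9)
  expect_identical(spikeTimes(s1), spikeTimes(s2))
  s3 <- simulateNetwork(p, top, seed = 10)
  expect_false(identical(spikeTimes(s1), spikeTimes(s3)))
})

test_that("halving the step changes reference-state rates by < 5%", {
  for (st in list(c(6, 6), c(4, 10), c(2, 14))) {
    r05 <- simulateNetwork(networkParams(tau_de = st[1], tau_di = st[2],
                                         duration = 11, discard = 1,
                                         dt = 0.05, seed = 5))
    r025 <- simulateNetwork(networkParams(tau_de = st[1], tau_di = st[2],
                                          duration = 11, discard = 1,
                                          dt = 0.025, seed = 5))
    expect_equal(firingRate(r05, "all"), firingRate(r025, "all"),
                 tolerance = 0.05)
  }
})

test_that("excitatory and inhibitory currents cancel in the balanced state", {
  p <- networkParams(tau_de = 6, tau_di = 6, duration = 6, discard = 1,
                     seed = 3)
  s <- simulateNetwork(p, record = c(1L, 2001L))
  tr <- attr(s, "trace")
  for (j in 1:2) {
    V <- tr@V[, j]
    iE <- tr@G_E[, j] * (p@E_E - V)
    iI <- tr@G_I[, j] * (p@E_I - V)
    expect_lt(abs(mean(iE + iI)) / mean(abs(iE)), 0.3)
  }
})

test_that("the current-based variant integrates and fires irregularly", {
  p <- networkParams(tau_de = 4, tau_di = 10, duration = 4, discard = 1,
                     seed = 2, model_variant = "current")
  s <- simulateNetwork(p)
  expect_gt(firingRate(s, "E"), 0.5)
  expect_gt(meanISICV(s, "E"), 0.5)
})

test_that("topology inconsistent with parameters is rejected", {
  p <- networkParams(N = 100L)
  top <- buildNetwork(networkParams(N = 50L), seed = 1)
  expect_error(simulateNetwork(p, top), "topology")
})
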