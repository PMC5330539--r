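test_that("an empirical distribution equal to the fit has distance zero", {
  # sizes drawn exactly proportional to a discrete power law
  supp <- 1:50
  w <- supp^(-1.5)
  counts <- round(w / sum(w) * 1e5)
  sizes <- rep(supp, counts)
  fit <- fitPowerLaw(sizes)
  expect_lt(plDistance(fit), 0.01)
  expect_equal(plExponent(fit), 1.5, tolerance = 0.01)
  expect_equal(sum(fit@pFit), 1, tolerance = 1e-12)
})

test_that("the exponent is recovered from power-law samples", {
  s <- samplePowerLaw(1e5, alpha = 1.5, s_max = 1000, seed = 1)
  fit <- fitPowerLaw(s)
  expect_equal(plExponent(fit), 1.5, tolerance = 0.02)
  expect_lt(plDistance(fit), 0.1)
  # least-squares on log-binned mass agrees roughly
  fit2 <- fitPowerLaw(s, method = "logbin-ls")
  expect_equal(plExponent(fit2), 1.5, tolerance = 0.15)
})

test_that("a geometric size distribution is far from any power law", {
  set.seed(4)
  g <- stats::rgeom(1e5, 0.2) + 1
  s <- samplePowerLaw(1e5, alpha = 1.5, s_max = 1000, seed = 1)
  expect_gt(plDistance(fitPowerLaw(g)), 5 * plDistance(fitPowerLaw(s)))
})

test_that("MLE matches an independent likelihood grid search", {
  s <- samplePowerLaw(2e4, alpha = 1.8, s_max = 500, seed = 2)
  fit <- fitPowerLaw(s)
  grid <- seq(1.2, 2.4, by = 1e-4)
  ll <- vapply(grid, function(a) {
    z <- sum((1:max(s))^(-a))
    -length(s) * log(z) - a * sum(log(s))
  }, numeric(1))
  expect_equal(plExponent(fit), grid[which.max(ll)], tolerance = 1e-3)
})

test_that("degenerate inputs are rejected", {
  expect_error(fitPowerLaw(rep(3L, 100)), "degenerate")
  expect_error(fitPowerLaw(integer()), "no avalanche")
  expect_error(fitPowerLaw(c(0L, 1L, 2L)), ">= 1")
})

test_that("criticalitySweep tabulates distances and flags failures", {
  sets <- list(
    crit = extractAvalanches(generateSurrogate("branching", n_neurons = 50,
                                               duration = 100, sigma = 1,
                                               seed = 3), delta_t = 1,
                             size = "spikes"),
    bad = NULL)
  tab <- criticalitySweep(sets)
  expect_identical(nrow(tab), 2L)
  expect_false(tab$flagged[1])
  expect_true(tab$flagged[2])
  expect_true(is.finite(tab$D[1]))
  one <- criticalitySweep(sets["crit"])
  expect_identical(nrow(one), 1L)
})
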