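test_that("optimal efficiency evaluates the closed forms", {
  expect_equal(etaOpt(0.5, r = 0, scenario = "binary"), 2)
  expect_equal(etaOpt(0.5, r = 0.5, scenario = "binary"), 1)
  expect_equal(etaOpt(1, r = 0, scenario = "analog"), 2)
  expect_error(etaOpt(1.2, r = 0, scenario = "binary"), "0 < rho < 1")
  expect_error(etaOpt(-1, r = 0, scenario = "analog"), "rho > 0")
})

test_that("optimal pattern distributions normalise and hit the mean", {
  for (rho in c(0.05, 0.3)) {
    b <- optimalPatternDistribution(rho, n = 40, scenario = "binary")
    expect_equal(sum(b$Pk), 1, tolerance = 1e-12)
    expect_equal(sum(as.numeric(names(b$Pk)) * b$Pk), 40 * rho,
                 tolerance = 1e-10)
    a <- optimalPatternDistribution(rho, n = 40, scenario = "analog",
                                    k_max = 2000)
    expect_equal(sum(a$Pk), 1, tolerance = 1e-8)
    expect_equal(sum(as.numeric(names(a$Pk)) * a$Pk), 40 * rho,
                 tolerance = 1e-6)
  }
})

test_that("binary optimal entropy equals n f(rho) by enumeration", {
  for (n in c(5, 12)) {
    rho <- 0.23
    p_m <- (1 - rho)^(n - 0:n) * rho^(0:n)
    H <- -sum(choose(n, 0:n) * p_m * log2(p_m))
    expect_equal(H, n * binaryEntropy(rho), tolerance = 1e-12)
  }
})

test_that("analog optimal entropy matches exhaustive enumeration", {
  n <- 3; rho <- 0.5
  rp <- rho / (1 + rho)
  counts <- expand.grid(s1 = 0:10, s2 = 0:10, s3 = 0:10)
  mi <- rowSums(counts)
  pi <- (1 - rp)^n * rp^mi
  H_enum <- -sum(pi * log2(pi))
  lambda <- -n * log(n / (rho * n + n))
  mu <- -log(rho * n / (rho * n + n))
  H_closed <- (lambda + mu * rho * n) * log2(exp(1))
  expect_equal(H_enum, H_closed, tolerance = 1e-4)  # geometric truncation
})

test_that("the optimal activity level solves the stationarity condition", {
  expect_equal(as.numeric(rhoM(1, "analog")), 1, tolerance = 1e-9)
  r0 <- rhoM(0, "binary")
  expect_equal(as.numeric(r0), 0)
  expect_true(isTRUE(attr(r0, "limit")))
  # monotone in r, with the documented limits
  for (scn in c("binary", "analog")) {
    rr <- c(0.005, 0.01, 0.05, 0.1, 1, 10)
    rho <- vapply(rr, function(r) as.numeric(rhoM(r, scn)), numeric(1))
    expect_true(all(diff(rho) > 0))
  }
  expect_lt(abs(as.numeric(rhoM(1e6, "binary")) - 0.5), 1e-3)
  expect_lt(as.numeric(rhoM(1e-4, "binary")), 0.01)
})

test_that("theory curves carry the optimum consistently", {
  tc <- theoryCurve("binary", r = 0.1)
  expect_equal(tc$eta_opt, etaOpt(tc$rho, 0.1, "binary"))
  rho_m <- attr(tc, "rho_m")
  expect_equal(attr(tc, "v_m"), rho_m / 0.020, tolerance = 1e-9)
  # the true optimum dominates the tabulated grid
  expect_lte(max(tc$eta_opt), etaOpt(rho_m, 0.1, "binary") + 1e-12)
  expect_gt(max(tc$eta_opt), etaOpt(rho_m, 0.1, "binary") - 1e-4)
})
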