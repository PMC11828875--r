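test_that("annual variation returns mean and n-1 SD", {
  expect_equal(annualVariation(c(100, 100, 100)), c(mean = 100, sd = 0))
  expect_equal(annualVariation(c(90, 100, 110)), c(mean = 100, sd = 10))
  expect_error(annualVariation(5), "at least 2")
})

test_that("Latin hypercube draws occupy every stratum exactly once", {
  for (n in c(4L, 8L, 17L, 32L)) {
    for (mode in c("uniform", "midpoint")) {
      d <- lhsNormalDraws(c(0, 10, -3), c(1, 2, 0.5), n, seed = n,
                          mode = mode)
      expect_equal(dim(d), c(n, 3L))
      for (j in 1:3) {
        p <- stats::pnorm(d[, j], c(0, 10, -3)[j], c(1, 2, 0.5)[j])
        expect_setequal(floor(p * n), 0:(n - 1)) # one draw per stratum
      }
    }
  }
})

test_that("LHS draws are deterministic, respect sd = 0, and calibrate", {
  d1 <- lhsNormalDraws(c(1, 2), c(0.5, 0), 100, seed = 5L)
  d2 <- lhsNormalDraws(c(1, 2), c(0.5, 0), 100, seed = 5L)
  expect_identical(d1, d2)
  expect_equal(d1[, 2], rep(2, 100))
  big <- lhsNormalDraws(0, 1, 10000, seed = 6L)
  expect_lt(abs(mean(big)), 0.05)
  expect_lt(abs(stats::sd(big) - 1), 0.05)
})

test_that("zero input SDs collapse the Monte Carlo onto the point estimate", {
  rate <- 1 - exp(-(3e-4 + 2e-5 * exp(0.1 * 0:94)))
  stats0 <- list(popMean = rep(1000, 95), popSD = rep(0, 95),
                 rateMean = rate, rateSD = rep(0, 95))
  mc <- monteCarloEstimates(stats0, nTrials = 100L, seed = 1L)
  r <- mc$LE_0
  expect_equal(r@median, r@point, tolerance = 1e-9)
  expect_equal(r@upper - r@lower, 0, tolerance = 1e-9)
  # continuity: tiny SDs keep the median within 1e-3 years of the point
  statsEps <- stats0
  statsEps$rateSD <- rep(1e-6, 95) * rate
  mcEps <- monteCarloEstimates(statsEps, nTrials = 200L, seed = 2L)
  expect_lt(abs(mcEps$LE_0@median - r@point), 1e-3)
  # percentile ordering is an invariant of every run
  expect_lte(mcEps$LE_0@lower, mcEps$LE_0@median)
  expect_lte(mcEps$LE_0@median, mcEps$LE_0@upper)
})

test_that("the point estimate falls inside the UI across replicate seeds", {
  rate <- 1 - exp(-(3e-4 + 2e-5 * exp(0.1 * 0:94)))
  st <- list(popMean = rep(5000, 95), popSD = rep(50, 95),
             rateMean = rate, rateSD = rate * 0.05)
  inside <- vapply(1:50, function(s) {
    r <- monteCarloEstimates(st, nTrials = 200L, seed = s)$LE_0
    r@lower <= r@point && r@point <= r@upper
  }, TRUE)
  expect_gte(mean(inside), 0.95)
})

test_that("period differences report median, UI and a significance flag", {
  a <- new("MCResult", label = "a", point = 10, median = 10, lower = 9,
           upper = 11, nTrials = 1000L, seed = 1L,
           trials = rnorm(1000, 10, 0.1), significant = NA)
  bT <- a@trials + 1.0 + rnorm(1000, 0, 0.05)
  b <- new("MCResult", label = "b", point = 11, median = stats::median(bT),
           lower = stats::quantile(bT, 0.025)[[1]],
           upper = stats::quantile(bT, 0.975)[[1]], nTrials = 1000L,
           seed = 2L, trials = bT, significant = NA)
  d <- periodDifference(a, b)
  expect_equal(d@median, 1.0, tolerance = 0.05)
  expect_true(d@significant)
  expect_equal(d@point, 1.0)
  expect_error(periodDifference(rnorm(10), rnorm(11)), "length")

  # identical deterministic inputs: zero difference, zero-width UI
  z <- periodDifference(rep(2, 100), rep(2, 100))
  expect_equal(c(z@median, z@lower, z@upper), c(0, 0, 0))
  expect_false(z@significant)
})

test_that("i.i.d. trial sets rarely flag a significant difference", {
  set.seed(99)
  flags <- vapply(1:50, function(i) {
    periodDifference(rnorm(500), rnorm(500))@significant
  }, TRUE)
  expect_gte(mean(!flags), 0.9)
})

test_that("district-group CIs follow mean +/- 1.96 SE", {
  ci <- groupCI(c(1, 1, 1), rep("g", 3))
  expect_equal(c(ci$ciLower, ci$ciUpper), c(1, 1))
  ci2 <- groupCI(c(0, 2), rep("g", 2))
  expect_equal(ci2$mean, 1)
  expect_equal(ci2$se, 1)
  expect_equal(ci2$ciLower, -0.96)
  expect_equal(ci2$ciUpper, 2.96)
  expect_error(groupCI(c(1, 2, 3), c("a", "b", "b")), "at least 2")
})

test_that("95% UIs cover a realized rate draw at the nominal rate", {
  # calibration: the MC trial distribution and an independent draw from
  # the same per-age normal law are exchangeable, so the 2.5-97.5
  # percentile band must cover the realized-draw LE ~95% of the time
  rate <- 1 - exp(-(3e-4 + 2e-5 * exp(0.1 * 0:94)))
  sdv <- rate * 0.05
  st <- list(popMean = rep(5000, 95), popSD = rep(50, 95),
             rateMean = rate, rateSD = sdv)
  nRep <- 200L
  covered <- logical(nRep)
  for (i in seq_len(nRep)) {
    set.seed(20000 + i)
    mStar <- pmin(pmax(rnorm(95, rate, sdv), 0), 1)
    truth <- leFromRates(mStar)[["0"]]
    r <- monteCarloEstimates(st, nTrials = 1000L, seed = 30000 + i)$LE_0
    covered[i] <- r@lower <= truth && truth <= r@upper
  }
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})
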