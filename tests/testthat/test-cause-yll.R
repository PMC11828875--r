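test_that("cause deletion follows the proportional-elimination closed form", {
  qs <- constantQ(0.2)
  del <- deleteCause(qs, rep(0.5, 111))
  expect_equal(qValues(del)[["10"]], 1 - 0.8^0.5, tolerance = 1e-12)
  expect_equal(qValues(del)[["10"]], 0.105573, tolerance = 1e-5)
  # identity and sole-cause limits
  expect_equal(qValues(deleteCause(qs, rep(0, 111))), qValues(qs))
  allCause <- deleteCause(qs, rep(1, 111))
  expect_equal(unname(qValues(allCause)[1:110]), rep(0, 110))
  expect_error(deleteCause(qs, rep(1.2, 111)), "outside")
})

test_that("YLL from constant schedules matches the geometric-series oracle", {
  qs <- constantQ(0.5)
  a <- flatA()
  del <- deleteCause(qs, rep(0.5, 111))
  expect_equal(qValues(del)[["3"]], 1 - sqrt(0.5), tolerance = 1e-12)
  res <- yll(qs, del, ages = c(0L, 40L, 65L), aSchedule = a)
  # e0 = 1.5; deleted e0 = (1+r)/(2(1-r)), r = sqrt(0.5)
  r <- sqrt(0.5)
  expect_equal(unname(yllValues(res)[["0"]]),
               (1 + r) / (2 * (1 - r)) - 1.5, tolerance = 1e-6)
  expect_equal(unname(yllValues(res)[["0"]]), 1.414214, tolerance = 1e-5)
  # f = 0 gives YLL identically zero
  res0 <- yll(qs, deleteCause(qs, rep(0, 111)), aSchedule = a)
  expect_equal(unname(yllValues(res0)), rep(0, 3), tolerance = 1e-12)
})

test_that("YLL is non-negative and monotone in the cause fractions", {
  set.seed(23)
  for (i in 1:10) {
    q <- c(runif(110) * 0.4, 1)
    qs <- new("QSchedule", q = q, source = rep("observed", 111),
              stratum = list())
    f1 <- runif(111) * 0.5
    f2 <- pmin(f1 + runif(111) * 0.3, 1)
    y1 <- yllValues(yll(qs, deleteCause(qs, f1)))
    y2 <- yllValues(yll(qs, deleteCause(qs, f2)))
    expect_true(all(y1 >= -1e-12))
    expect_true(all(y2 >= y1 - 1e-12)) # pointwise-larger f, larger YLL
  }
})

test_that("joint deletion of two disjoint causes dominates each alone", {
  set.seed(29)
  q <- c(runif(110) * 0.3, 1)
  qs <- new("QSchedule", q = q, source = rep("observed", 111),
            stratum = list())
  f <- runif(111) * 0.3
  g <- runif(111) * 0.3
  yF <- yllValues(yll(qs, deleteCause(qs, f)))[["0"]]
  yG <- yllValues(yll(qs, deleteCause(qs, g)))[["0"]]
  yFG <- yllValues(yll(qs, deleteCause(qs, f + g)))[["0"]]
  expect_gte(yFG, max(yF, yG) - 1e-12)
})

test_that("cause fractions come from the cube with tail carry-forward", {
  dmap <- tinyDistrictMap()
  rec <- data.frame(
    sex = factor(rep("male", 8), levels = c("male", "female")),
    age = c(70L, 70L, 92L, 92L, 92L, 92L, 3L, 100L),
    icd10 = c("C34", "A41", "C18", "C61", "A41", "E14", "A41", "A41"),
    municipality = rep("M01", 8),
    year = rep(2008L, 8))
  cube <- aggregateDeaths(rec, dmap, list(pre = 2006:2010))
  f <- causeFraction(cube, "pre", "male", "cancer")
  expect_equal(unname(f[["70"]]), 0.5)     # 1 cancer of 2 deaths
  expect_equal(unname(f[["4"]]), 0)        # no deaths at age 4
  expect_equal(unname(f[["3"]]), 0)        # all-other age
  expect_equal(unname(f[["92"]]), 0.5)     # 2 of 4
  # ages beyond the reliable band inherit the pooled 90-94 fraction
  expect_equal(unname(f[["100"]]), 0.5)
  expect_equal(unname(f[["110"]]), 0.5)
})

test_that("deleting a known proportional hazard share recovers the no-cause LE", {
  # competing-risks oracle: if a cause is a constant share s of the
  # hazard, the cause-deleted LE must match the analytic LE under
  # hazard (1 - s) h(x).
  cfg <- scenarioConfig(nDistricts = 1L, districtPopulations = 400000,
                        periods = list(pre = 2006:2010), seed = 31L)
  model <- cfg@model
  share <- 0.30
  mix <- model@causeMix
  mix[, ] <- 0
  mix[, "cancer"] <- share
  mix[, "other"] <- 1 - share
  model@causeMix <- mix
  pop <- generatePopulation(cfg)
  deaths <- simulateDeaths(pop, model, seed = 32L, periods = cfg@periods)
  dmap <- districtMap(c("1" = "1"))
  cube <- aggregateDeaths(deaths, dmap, cfg@periods)
  dAll <- apply(deathCounts(cube)["pre", , "male", , "all", drop = FALSE],
                4, sum)
  pBar <- apply(populationCounts(pop)[, "male", , , drop = FALSE], 3,
                sum) / 5
  qs <- extendTail(mortalityRates(dAll, pBar, years = 5,
                                  method = "direct"))
  f <- causeFraction(cube, "pre", "male", "cancer")
  res <- yll(qs, deleteCause(qs, f), ages = 0L)
  leDel <- lifeExpectancy(res@tableDeleted, 0)

  reduced <- model
  mix2 <- model@causeMix
  mix2[, "cancer"] <- 0
  mix2[, "other"] <- 1 - share
  # renormalise: deleted hazard is (1 - share) of the total
  reduced@causeMix <- mix2 / rowSums(mix2)
  reduced@lambda <- model@lambda * (1 - share)
  reduced@alpha <- model@alpha * (1 - share)
  analytic <- analyticLifeExpectancy(reduced, "male")
  expect_lt(abs(leDel - analytic), 0.2)
})
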