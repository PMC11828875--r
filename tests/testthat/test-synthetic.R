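test_that("population generation conserves totals and is seed-deterministic", {
  cfg <- scenarioConfig(nDistricts = 2L,
                        districtPopulations = c(10000, 10000),
                        periods = list(pre = 2006:2007), seed = 7L)
  pop <- generatePopulation(cfg)
  a <- populationCounts(pop)
  # district-year totals equal the configured total up to pyramid
  # rounding and the small (SD 0.01) year effect
  totals <- apply(a, c(1, 4), sum)
  expect_true(all(abs(totals - 10000) < 10000 * 0.05))
  expect_identical(populationCounts(generatePopulation(cfg)), a)
  cfg2 <- scenarioConfig(nDistricts = 2L,
                         districtPopulations = c(10000, 10000),
                         periods = list(pre = 2006:2007), seed = 8L)
  expect_false(identical(populationCounts(generatePopulation(cfg2)), a))
})

test_that("degenerate hazards give zero or total mortality", {
  cfg <- scenarioConfig(nDistricts = 1L, districtPopulations = 5000,
                        periods = list(pre = 2006:2007), seed = 9L)
  pop <- generatePopulation(cfg)
  noDeath <- mortalityModel(lambda = 0,
                            alpha = c(male = 0, female = 0), beta = 0.1)
  expect_equal(nrow(simulateDeaths(pop, noDeath, seed = 1L)), 0L)

  # a hazard so large that q is numerically 1 kills every resident
  certain <- mortalityModel(lambda = 100,
                            alpha = c(male = 0, female = 0), beta = 0,
                            yearEffectSD = 0)
  deaths <- simulateDeaths(pop, certain, seed = 1L)
  expect_equal(nrow(deaths), sum(populationCounts(pop)))
})

test_that("cell-level death counts are binomial with the model probability", {
  # one age, q = 1 - exp(-h) = 0.01, population 10000: across 200
  # replicate seeds the mean death count must sit within 3 SE of 100
  h <- -log(1 - 0.01)
  model <- mortalityModel(lambda = h, alpha = c(male = 0, female = 0),
                          beta = 0, yearEffectSD = 0)
  a <- array(0, dim = c(1, 2, 111, 1),
             dimnames = list(district = "1", sex = c("male", "female"),
                             age = as.character(0:110), year = "2006"))
  a["1", "male", "51", "2006"] <- 10000
  pop <- new("PopulationTable", counts = a)
  counts <- vapply(1:200, function(s)
    nrow(simulateDeaths(pop, model, seed = s)), 0)
  se <- sqrt(10000 * 0.01 * 0.99)           # binomial SD per replicate
  expect_lt(abs(mean(counts) - 100), 3 * se / sqrt(200))
  expect_gt(stats::sd(counts), 0)
})

test_that("stratum death rates recover the model q within binomial error", {
  cfg <- scenarioConfig(nDistricts = 1L, districtPopulations = 2.1e6,
                        periods = list(pre = 2006:2010), seed = 41L)
  model <- cfg@model
  model@yearEffectSD <- 0   # isolate binomial sampling
  pop <- generatePopulation(cfg)
  deaths <- simulateDeaths(pop, model, seed = 42L)
  ages <- 0:94
  dBy <- tabulate(deaths$age[deaths$sex == "male"] + 1L, nbins = 111)
  nBy <- apply(populationCounts(pop)[, "male", , , drop = FALSE], 3, sum)
  qTrue <- 1 - exp(-(model@lambda + model@alpha[["male"]] *
                       exp(model@beta * ages)))
  qHat <- (dBy / nBy)[ages + 1]
  tol <- 4 * sqrt(qTrue * (1 - qTrue) / nBy[ages + 1])
  expect_gte(mean(abs(qHat - qTrue) < tol), 0.95)
})

test_that("simulated records carry valid ICD-10 codes in the right buckets", {
  cfg <- scenarioConfig(nDistricts = 1L, districtPopulations = 50000,
                        periods = list(pre = 2006:2007), seed = 43L)
  pop <- generatePopulation(cfg)
  deaths <- simulateDeaths(pop, cfg@model, seed = 44L,
                           periods = cfg@periods)
  expect_gt(nrow(deaths), 0)
  expect_true(all(grepl("^[A-Z][0-9]{2}$", deaths$icd10)))
  groups <- defaultCauseGroups()
  # old-age deaths should include every configured bucket
  hits <- vapply(groups, function(g) sum(matchCauseGroup(deaths$icd10, g)),
                 0)
  expect_true(all(hits > 0))
  expect_true(all(deaths$year %in% 2006:2007))
})

test_that("large-sample simulated life expectancy matches the analytic oracle", {
  # ~8e6 person-years per sex stratum; year effect off so realized
  # hazards equal the analytic model's
  cfg <- scenarioConfig(nDistricts = 1L, districtPopulations = 3.2e6,
                        periods = list(pre = 2006:2010), seed = 45L,
                        model = mortalityModel(yearEffectSD = 0))
  pop <- generatePopulation(cfg)
  deaths <- simulateDeaths(pop, cfg@model, seed = 46L)
  for (s in c("male", "female")) {
    dBy <- tabulate(deaths$age[deaths$sex == s] + 1L, nbins = 111)
    pBar <- apply(populationCounts(pop)[, s, , , drop = FALSE], 3, sum) / 5
    qs <- extendTail(mortalityRates(dBy, pBar, years = 5,
                                    method = "direct"))
    est <- lifeExpectancy(buildLifeTable(qs), 0)
    expect_lt(abs(est - analyticLifeExpectancy(cfg@model, s)), 0.2)
  }
})
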