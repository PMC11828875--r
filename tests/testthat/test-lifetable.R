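test_that("occurrence-exposure conversion matches the closed form", {
  deaths <- rep(0, 111); pop <- rep(1000, 111)
  deaths[51] <- 10
  qs <- mortalityRates(deaths, pop, years = 1, method = "central")
  # m = 0.01, q = m / (1 + 0.5 m)
  expect_equal(qValues(qs)[["50"]], 0.01 / (1 + 0.5 * 0.01),
               tolerance = 1e-12)
  expect_equal(qValues(qs)[["50"]], 0.0099502, tolerance = 1e-5)
  expect_equal(qValues(qs)[["10"]], 0)
  # probabilities are clipped into [0,1]
  deaths[51] <- 1000
  qs2 <- mortalityRates(deaths, pop, years = 1, method = "direct")
  expect_lte(qValues(qs2)[["50"]], 1)
  expect_error(mortalityRates(deaths, rep(0, 111)), "zero population")
})

test_that("empty cells are interpolated and flagged", {
  deaths <- c(rep(2, 95), rep(0, 16))
  pop <- c(rep(1000, 95), rep(0, 16))
  pop[31] <- 0; deaths[31] <- 0
  qs <- mortalityRates(deaths, pop, years = 1)
  expect_equal(qSource(qs)[["30"]], "interpolated")
  # log-linear interpolation between equal neighbours is flat
  expect_equal(qValues(qs)[["30"]], qValues(qs)[["29"]], tolerance = 1e-9)
  expect_true(all(qSource(qs)[96:111] == "missing"))
})

test_that("Gompertz tail extrapolation recovers an exact Gompertz input", {
  a <- flatA()
  m <- rep(NA_real_, 111)
  ages <- 80:94
  m[ages + 1] <- 0.05 * exp(0.09 * (ages - 80))
  q <- m / (1 + 0.5 * m)
  q[1:80] <- 0.001
  qs <- new("QSchedule", q = ifelse(is.na(q), NA, q),
            source = c(rep("observed", 95), rep("missing", 16)),
            stratum = list())
  ext <- extendTail(qs, aSchedule = a)
  m95 <- 0.05 * exp(0.09 * 15)
  expect_equal(m95, 0.19287, tolerance = 1e-4)
  q95 <- qValues(ext)[["95"]]
  expect_equal(q95 / (1 - 0.5 * q95), m95, tolerance = 1e-6)
  expect_equal(qValues(ext)[["110"]], 1)
  expect_true(all(qSource(ext)[96:111] == "estimated-tail"))
})

test_that("constant rates extrapolate flat and sparse fits error", {
  a <- flatA()
  q <- rep(0.1, 111); q[96:111] <- NA
  qs <- new("QSchedule", q = q,
            source = c(rep("observed", 95), rep("missing", 16)),
            stratum = list())
  ext <- extendTail(qs, aSchedule = a)
  expect_equal(unname(qValues(ext)[96:110]), rep(0.1, 15),
               tolerance = 1e-10)
  qs2 <- new("QSchedule", q = c(rep(NA, 93), 0.1, 0.2, rep(NA, 16)),
             source = c(rep("missing", 93), "observed", "observed",
                        rep("missing", 16)), stratum = list())
  expect_error(extendTail(qs2), "at least 3")
})

test_that("life-table closed forms hold (geometric, degenerate, immortal)", {
  a <- flatA()
  lt <- buildLifeTable(constantQ(0.5), aSchedule = a)
  expect_equal(lifeExpectancy(lt, 0), 1.5, tolerance = 1e-9)
  # memorylessness of a constant-q table
  expect_equal(lifeExpectancy(lt, 5), 1.5, tolerance = 1e-9)

  qDie <- constantQ(0.5); qDie@q[1] <- 1
  ltDie <- buildLifeTable(qDie, aSchedule = a)
  expect_equal(lifeExpectancy(ltDie, 0), 0.5)
  # with the infant convention a_0 = 0.1, e_0 = a_0
  ltInf <- buildLifeTable(qDie, aSchedule = defaultASchedule())
  expect_equal(lifeExpectancy(ltInf, 0), 0.1)

  immortal <- new("QSchedule", q = c(rep(0, 110), 1),
                  source = rep("observed", 111), stratum = list())
  ltIm <- buildLifeTable(immortal, aSchedule = a)
  expect_equal(lifeExpectancy(ltIm, 0), 110.5) # omega + a_omega
  # at omega with q_omega = 1, e = a_omega
  expect_equal(lifeExpectancy(ltIm, 110), 0.5)
})

test_that("life-table columns respect their defining inequalities", {
  set.seed(7)
  for (i in 1:10) {
    q <- c(runif(110)^3, 1)
    qs <- new("QSchedule", q = q, source = rep("observed", 111),
              stratum = list())
    lt <- buildLifeTable(qs)
    tb <- lifeTableColumns(lt)
    expect_true(all(diff(tb$l) <= 1e-9))
    expect_true(all(tb$L <= tb$l + 1e-9))
    expect_true(all(tb$L >= c(tb$l[-1], 0) - 1e-9))
    alive <- tb$l > 0
    expect_true(all(tb$e[alive] > 0))
    expect_true(all(diff(tb$T[alive]) < 0))
  }
})

test_that("e_0 equals the brute-force death-age expectation to 1e-10", {
  set.seed(11)
  for (i in 1:25) {
    q <- c(runif(110), 1)
    a <- c(runif(1, 0.05, 0.5), rep(0.5, 110))
    qs <- new("QSchedule", q = q, source = rep("observed", 111),
              stratum = list())
    lt <- buildLifeTable(qs, aSchedule = a)
    expect_equal(lifeExpectancy(lt, 0), bruteForceE0(q, a),
                 tolerance = 1e-10)
  }
})

test_that("raising any single q_x never increases expectancy at ages <= x", {
  set.seed(13)
  q <- c(runif(110) * 0.3, 1)
  base <- buildLifeTable(new("QSchedule", q = q,
    source = rep("observed", 111), stratum = list()))
  for (x in c(0L, 17L, 56L, 90L)) {
    q2 <- q
    q2[x + 1] <- min(1, q2[x + 1] + 0.2)
    lt2 <- buildLifeTable(new("QSchedule", q = q2,
      source = rep("observed", 111), stratum = list()))
    for (y in c(0L, min(x, 10L))) {
      expect_lte(lifeExpectancy(lt2, y), lifeExpectancy(base, y) + 1e-12)
    }
  }
})

test_that("with a = 0.5 everywhere e_0 is the trapezoidal survival integral", {
  set.seed(17)
  q <- c(runif(110) * 0.5, 1)
  a <- flatA()
  lt <- buildLifeTable(new("QSchedule", q = q,
    source = rep("observed", 111), stratum = list()), aSchedule = a)
  l <- lifeTableColumns(lt)$l / 1e5
  trapz <- sum((l + c(l[-1], 0)) / 2)
  expect_equal(lifeExpectancy(lt, 0), trapz, tolerance = 1e-10)
})
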