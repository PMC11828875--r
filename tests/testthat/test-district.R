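test_that("district aggregation weights by population except financial index", {
  dmap <- districtMap(c(M01 = "1", M02 = "1", M03 = "2", M04 = "2"),
                      evacuatedDistricts = "2")
  muni <- data.frame(
    municipality = c("M01", "M02", "M03", "M04"),
    population = c(1000, 3000, 500, 500),
    income = c(2, 4, 5, 7),
    financial_capability_index = c(1, 3, 0.4, 0.8))
  out <- aggregateCharacteristics(muni, dmap)
  d1 <- out[out$district == "1", ]
  expect_equal(d1$income, (1000 * 2 + 3000 * 4) / 4000)  # 3.5
  expect_equal(d1$financial_capability_index, 2)          # simple mean
  expect_equal(d1$evacuated, 0L)
  expect_equal(out[out$district == "2", ]$evacuated, 1L)
  # single-municipality district is the identity
  dmap3 <- districtMap(c(M01 = "1", M02 = "2", M03 = "3"))
  muni3 <- data.frame(municipality = c("M01", "M02", "M03"),
                      population = c(10, 20, 30), income = c(1, 2, 3),
                      financial_capability_index = c(.1, .2, .3))
  out3 <- aggregateCharacteristics(muni3, dmap3)
  expect_equal(out3$income, c(1, 2, 3))
  muni$population[1:2] <- 0
  expect_error(aggregateCharacteristics(muni, dmap), "zero total")
})

test_that("changes are computed against the pre-disaster period", {
  expect_equal(unname(deltaVsPre(c(pre = 78.57, early = 79.49))),
               0.92, tolerance = 1e-9)
  expect_equal(unname(deltaVsPre(c(pre = 1.09, late = 0.82))[["late"]]),
               -0.27, tolerance = 1e-9)
  expect_equal(unname(deltaVsPre(c(pre = 5, early = 5, late = 5))),
               c(0, 0))
  expect_error(deltaVsPre(c(early = 1)), "missing reference")
})

test_that("Pearson effect sizes match hand-computed values", {
  expect_equal(effectSizeContinuous(1:5, 1:5)$r, 1)
  expect_equal(effectSizeContinuous(1:5, -2 * (1:5) + 3)$r, -1)
  row <- effectSizeContinuous(c(0, 0, 1, 1), c(1, 2, 3, 4))
  expect_equal(row$r, 0.894427, tolerance = 1e-6)
  expect_equal(row$df, 2L)
  # cross-check t and p against the reference implementation
  ct <- stats::cor.test(c(0, 0, 1, 1), c(1, 2, 3, 4))
  expect_equal(row$t, unname(ct$statistic), tolerance = 1e-12)
  expect_equal(row$p, ct$p.value, tolerance = 1e-12)
  expect_error(effectSizeContinuous(c(1, 1, 1), 1:3), "constant")
  expect_error(effectSizeContinuous(1:2, 1:2), "at least 3")
})

test_that("group comparison equals pooled t.test and the point-biserial identity", {
  set.seed(37)
  for (i in 1:20) {
    evac <- rnorm(3); nonevac <- rnorm(11)
    row <- groupCompare(evac, nonevac)
    tt <- stats::t.test(evac, nonevac, var.equal = TRUE)
    expect_equal(row$t, unname(tt$statistic), tolerance = 1e-9)
    expect_equal(row$p, tt$p.value, tolerance = 1e-9)
    # identity with Pearson correlation against the 0/1 coding
    y <- c(evac, nonevac)
    x <- c(rep(1, 3), rep(0, 11))
    expect_equal(row$r, stats::cor(x, y), tolerance = 1e-12)
  }
  expect_error(groupCompare(1, 1:5), "at least 2")
})

test_that("significance flags fire exactly when |r| > 0.5", {
  rows <- rbind(
    groupCompareFromSummary(1.64, 0.458, 3, 0.88, 0.422, 11),
    groupCompareFromSummary(-0.02, 0.324, 3, -0.22, 0.102, 11),
    groupCompareFromSummary(-0.65, 0.097, 3, -0.25, 0.120, 11))
  expect_equal(rows$significant, abs(rows$r) > 0.5)
  expect_equal(rows$significant, c(TRUE, FALSE, TRUE))
})
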