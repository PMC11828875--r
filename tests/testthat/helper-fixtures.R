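# Shared fixture builders and independent oracles.

# a QSchedule with constant q (closing age forced to 1)
constantQ <- function(q, omega = 110L, stratum = list()) {
  new("QSchedule", q = c(rep(q, omega), 1),
      source = rep("observed", omega + 1L), stratum = stratum)
}

flatA <- function(omega = 110L) rep(0.5, omega + 1L)

# Brute-force life expectancy at birth: expectation of (age at death +
# fraction a lived in the death year), enumerating the death-age
# distribution directly. Independent of the l/L/T column construction.
bruteForceE0 <- function(q, a) {
  n <- length(q)
  surv <- cumprod(c(1, 1 - q[-n]))      # P(alive at exact age x)
  pDie <- surv * q                       # P(die in year x), x < omega
  pDie[n] <- surv[n]                     # table closure: all die at omega
  sum(pDie * ((seq_len(n) - 1L) + a))
}

# write a small deaths CSV, returns the path
writeDeathsCSV <- function(rows, path = tempfile(fileext = ".csv")) {
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  path
}

# a two-municipality, two-district map
tinyDistrictMap <- function() {
  districtMap(c(M01 = "1", M02 = "1", M03 = "2"),
              evacuatedDistricts = "2")
}

# annual deaths/pop matrices for one stratum of a simulated scenario
annualStratumData <- function(deaths, pop, sex, years, district = NULL) {
  pc <- populationCounts(pop)
  dn <- if (is.null(district)) dimnames(pc)[[1]] else district
  dBy <- sapply(as.character(years), function(y) {
    idx <- deaths$year == as.integer(y) & deaths$sex == sex &
      (if (is.null(district)) TRUE else deaths$municipality %in% district)
    tabulate(deaths$age[idx] + 1L, nbins = 111L)
  })
  pBy <- sapply(as.character(years), function(y)
    apply(pc[dn, sex, , y, drop = FALSE], 3, sum))
  list(deaths = dBy, pop = pBy)
}
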