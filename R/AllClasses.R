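#' @import methods
NULL

#' ICD-10 cause-of-death group
#'
#' A named group of inclusive ICD-10 3-character code ranges, e.g. heart
#' disease as I05-I09, I20-I25, I30-I52. Subcodes (a dot and one or two
#' trailing characters) never affect membership: grouping is at 3-character
#' resolution.
#'
#' @slot name single character, the group label.
#' @slot ranges data.frame with columns \code{letter} (single upper-case
#'   letter), \code{lo}, \code{hi} (integer 0-99, inclusive bounds on the
#'   two-digit part). Ranges within a group must not overlap and each range
#'   spans a single letter.
#' @seealso [causeGroup()], [defaultCauseGroups()], [matchCauseGroup()]
#' @export
setClass("CauseGroup",
  representation(name = "character", ranges = "data.frame"))

setValidity("CauseGroup", function(object) {
  r <- object@ranges
  if (length(object@name) != 1L || !nzchar(object@name))
    return("'name' must be a single non-empty string")
  if (!all(c("letter", "lo", "hi") %in% names(r)))
    return("'ranges' needs columns letter, lo, hi")
  if (any(!grepl("^[A-Z]$", r$letter)))
    return("range letters must be single upper-case letters")
  if (any(r$lo < 0 | r$hi > 99 | r$lo > r$hi))
    return("range bounds must satisfy 0 <= lo <= hi <= 99")
  # overlap check within each letter
  for (L in unique(r$letter)) {
    rr <- r[r$letter == L, , drop = FALSE]
    rr <- rr[order(rr$lo), , drop = FALSE]
    if (nrow(rr) > 1L && any(rr$lo[-1L] <= rr$hi[-nrow(rr)]))
      return(sprintf("overlapping ranges within letter %s", L))
  }
  TRUE
})

#' Municipality-to-district mapping
#'
#' Maps each municipality code to exactly one district and records which
#' districts contained mandatory evacuation-order zones.
#'
#' @slot map named character vector: names are municipality codes, values
#'   are district ids.
#' @slot evacuated named logical vector: names are district ids, value TRUE
#'   for districts that include evacuation-ordered areas.
#' @seealso [districtMap()], [readDistrictMap()]
#' @export
setClass("DistrictMap",
  representation(map = "character", evacuated = "logical"))

setValidity("DistrictMap", function(object) {
  if (is.null(names(object@map)) || anyDuplicated(names(object@map)))
    return("'map' must be named by unique municipality codes")
  if (is.null(names(object@evacuated)))
    return("'evacuated' must be named by district ids")
  if (!all(object@map %in% names(object@evacuated)))
    return("every mapped district must appear in 'evacuated'")
  if (!all(names(object@evacuated) %in% object@map))
    return("districts with no municipality are not allowed")
  TRUE
})

#' Registry population counts
#'
#' Person counts by district, sex, single year of age and calendar year,
#' following the March-31 resident-registry convention.
#'
#' @slot counts 4-d numeric array, dims district x sex x age x year, with
#'   complete dimnames; sex levels are "male","female"; ages "0".."110".
#' @seealso [readPopulation()], [generatePopulation()]
#' @export
setClass("PopulationTable", representation(counts = "array"))

setValidity("PopulationTable", function(object) {
  a <- object@counts
  if (length(dim(a)) != 4L)
    return("'counts' must be a 4-d array (district, sex, age, year)")
  if (is.null(dimnames(a)) || any(vapply(dimnames(a), is.null, logical(1))))
    return("'counts' must have complete dimnames")
  if (!identical(dimnames(a)[[2L]], c("male", "female")))
    return("sex dimension must be c('male','female')")
  if (any(a < 0)) return("population counts must be non-negative")
  TRUE
})

#' Death counts by period, district, sex, age and cause bucket
#'
#' The aggregation of individual death records: a 5-d count array whose
#' cause dimension carries the configured cause groups, an "other" bucket
#' and the all-cause margin "all". For every cell the named groups plus
#' "other" sum to "all".
#'
#' @slot counts 5-d array, dims period x district x sex x age x cause.
#' @slot periods named list of integer calendar-year vectors, one per
#'   period level.
#' @seealso [aggregateDeaths()]
#' @export
setClass("DeathCountCube",
  representation(counts = "array", periods = "list"))

setValidity("DeathCountCube", function(object) {
  a <- object@counts
  if (length(dim(a)) != 5L)
    return("'counts' must be 5-d (period, district, sex, age, cause)")
  dn <- dimnames(a)
  if (is.null(dn) || any(vapply(dn, is.null, logical(1))))
    return("'counts' must have complete dimnames")
  if (!"all" %in% dn[[5L]]) return("cause dimension must include 'all'")
  if (!"other" %in% dn[[5L]]) return("cause dimension must include 'other'")
  if (any(a < 0) || any(a != round(a)))
    return("counts must be non-negative integers")
  if (!identical(sort(names(object@periods)), sort(dn[[1L]])))
    return("'periods' names must match the period dimension")
  groups <- setdiff(dn[[5L]], "all")
  tot <- apply(a[, , , , groups, drop = FALSE], 1:4, sum)
  if (max(abs(as.vector(tot) -
              as.vector(a[, , , , "all", drop = FALSE]))) > 0)
    return("cause buckets + other must sum to 'all' in every cell")
  TRUE
})

#' Single-year-of-age mortality probability schedule
#'
#' Probabilities of dying within the year of age, q_x for x = 0..omega
#' (default omega 110), for one stratum. Each age carries a source flag:
#' "observed" for directly estimated rates, "estimated-age0" for the
#' infant convention, "estimated-tail" for the Gompertz-extrapolated open
#' ages, "interpolated" for empty cells filled from neighbours, and
#' "missing" for tail ages not yet extended.
#'
#' @slot q numeric vector of length omega+1, each in [0,1] (NA allowed only
#'   where flagged "missing").
#' @slot source character vector, same length as q.
#' @slot stratum named list of labels (e.g. district, sex, period).
#' @seealso [mortalityRates()], [extendTail()], [buildLifeTable()]
#' @export
setClass("QSchedule",
  representation(q = "numeric", source = "character", stratum = "list"))

setValidity("QSchedule", function(object) {
  if (length(object@q) != length(object@source))
    return("'q' and 'source' must have equal length")
  ok <- is.na(object@q) | (object@q >= 0 & object@q <= 1)
  if (!all(ok)) return("q values must lie in [0,1]")
  if (any(is.na(object@q) & object@source != "missing"))
    return("NA q values are only allowed where source == 'missing'")
  bad <- setdiff(unique(object@source),
    c("observed", "estimated-age0", "estimated-tail", "interpolated",
      "missing"))
  if (length(bad)) return(sprintf("unknown source flag '%s'", bad[1L]))
  TRUE
})

#' Complete period life table
#'
#' Columns per age x: mortality probability q, survivors l, deaths d,
#' person-years L, cumulative person-years T, and remaining life expectancy
#' e = T/l. The table is closed at its last age omega, where all remaining
#' survivors die and contribute a_omega person-years each.
#'
#' @slot table data.frame with columns age, q, l, d, L, T, e.
#' @slot radix numeric, l_0 (default 100000).
#' @slot a numeric fraction-of-year-lived schedule used to build the table.
#' @slot stratum named list of labels.
#' @seealso [buildLifeTable()], [lifeExpectancy()]
#' @export
setClass("LifeTable",
  representation(table = "data.frame", radix = "numeric", a = "numeric",
    stratum = "list"))

setValidity("LifeTable", function(object) {
  tb <- object@table
  need <- c("age", "q", "l", "d", "L", "T", "e")
  if (!all(need %in% names(tb))) return("table needs columns age,q,l,d,L,T,e")
  if (any(diff(tb$l) > 1e-9)) return("l_x must be non-increasing")
  if (any(tb$l < -1e-9)) return("l_x must be non-negative")
  TRUE
})

#' Monte Carlo uncertainty result
#'
#' Point estimate, trial median and 2.5th-97.5th percentile uncertainty
#' interval for one quantity (a life expectancy, a YLL, or a period
#' difference of either).
#'
#' @slot label character description of the quantity.
#' @slot point numeric point estimate (from unperturbed inputs; NA for
#'   differences of medians).
#' @slot median numeric trial median.
#' @slot lower,upper numeric 2.5th and 97.5th percentiles.
#' @slot nTrials integer number of Monte Carlo trials.
#' @slot seed integer seed used.
#' @slot trials numeric vector of trial values (kept for downstream
#'   difference computations).
#' @slot significant logical: for differences, TRUE when the UI excludes 0;
#'   NA otherwise.
#' @seealso [monteCarloEstimates()], [periodDifference()]
#' @export
setClass("MCResult",
  representation(label = "character", point = "numeric", median = "numeric",
    lower = "numeric", upper = "numeric", nTrials = "integer",
    seed = "integer", trials = "numeric", significant = "logical"))

setValidity("MCResult", function(object) {
  if (!is.na(object@lower) && !is.na(object@upper)) {
    if (object@lower > object@median + 1e-12 ||
        object@median > object@upper + 1e-12)
      return("must satisfy lower <= median <= upper")
  }
  TRUE
})

#' Gompertz-Makeham synthetic mortality model
#'
#' Generating law for the synthetic vital-registration module. The baseline
#' hazard at age x is lambda + alpha_sex * exp(beta * x), plus an additive
#' age-0 bump, scaled by a per-district frailty multiplier. The hazard is
#' split across cause groups by age-band cause-mix proportions, optionally
#' rescaled per period/cause/district (e.g. a post-disaster improvement in
#' cerebrovascular mortality concentrated in evacuated districts).
#'
#' @slot lambda non-negative background (Makeham) hazard.
#' @slot alpha named numeric ("male","female"), senescent hazard level > 0.
#' @slot beta non-negative log-slope of hazard per year of age.
#' @slot infantBump additive hazard at age 0 (default 0).
#' @slot districtEffect named numeric multiplier per district (default 1).
#' @slot causeMix matrix ageBand x cause of proportions summing to 1 per
#'   band; rownames like "0-9",...,"100-110"; colnames the cause names plus
#'   "other".
#' @slot causeMultiplier NULL or 3-d array period x cause x district of
#'   hazard multipliers applied to each cause's share.
#' @slot yearEffectSD SD of a lognormal year-level multiplier on the hazard
#'   (annual fluctuation beyond binomial noise).
#' @seealso [mortalityModel()], [simulateDeaths()], [analyticLifeExpectancy()]
#' @export
setClass("MortalityModel",
  representation(lambda = "numeric", alpha = "numeric", beta = "numeric",
    infantBump = "numeric", districtEffect = "numeric", causeMix = "matrix",
    causeMultiplier = "ANY", yearEffectSD = "numeric"))

setValidity("MortalityModel", function(object) {
  if (object@lambda < 0) return("lambda must be >= 0")
  if (any(object@alpha < 0)) return("alpha must be >= 0")
  if (!all(c("male", "female") %in% names(object@alpha)))
    return("alpha must be named for both sexes")
  if (object@beta < 0) return("beta must be >= 0")
  mix <- object@causeMix
  if (any(mix < 0)) return("cause-mix proportions must be >= 0")
  if (any(abs(rowSums(mix) - 1) > 1e-8))
    return("cause-mix proportions must sum to 1 in every age band")
  if (!"other" %in% colnames(mix))
    return("causeMix must include an 'other' column")
  TRUE
})

#' Synthetic-scenario configuration
#'
#' Everything the generator needs: the district/municipality layout, age
#' pyramid, periods, the mortality model and the root seed. A given seed
#' fixes all downstream randomness.
#'
#' @slot muniPerDistrict integer vector: municipalities per district
#'   (names are district ids).
#' @slot districtPopulations named numeric: total persons per district-year.
#' @slot propMale numeric in (0,1).
#' @slot pyramidShape numeric length 2, beta-density shape parameters for
#'   the age pyramid over 0..110.
#' @slot periods named list of integer year vectors (>= 2 years each so
#'   annual-variation SDs are estimable).
#' @slot seed integer root seed.
#' @slot model a [MortalityModel-class].
#' @seealso [scenarioConfig()], [generatePopulation()], [simulateDeaths()]
#' @export
setClass("ScenarioConfig",
  representation(muniPerDistrict = "integer",
    districtPopulations = "numeric", propMale = "numeric",
    pyramidShape = "numeric", periods = "list", seed = "integer",
    model = "MortalityModel"))

setValidity("ScenarioConfig", function(object) {
  if (is.null(names(object@muniPerDistrict)))
    return("muniPerDistrict must be named by district id")
  if (!identical(names(object@muniPerDistrict),
                 names(object@districtPopulations)))
    return("district names must agree between layout and populations")
  if (object@propMale <= 0 || object@propMale >= 1)
    return("propMale must be in (0,1)")
  if (any(vapply(object@periods, length, 1L) < 2L))
    return("each period needs at least 2 years (annual-variation SDs)")
  yrs <- unlist(object@periods)
  if (anyDuplicated(yrs)) return("periods must be disjoint")
  TRUE
})

#' Cause-deleted life expectancy comparison
#'
#' Holds the all-cause and cause-deleted life tables for one stratum and
#' cause, and the YLL (deleted minus all-cause expectancy) at the
#' requested ages.
#'
#' @slot cause character cause-group name.
#' @slot yll named numeric, YLL in years at each requested age.
#' @slot tableAll,tableDeleted the two [LifeTable-class] objects.
#' @seealso [yll()]
#' @export
setClass("YLLResult",
  representation(cause = "character", yll = "numeric",
    tableAll = "LifeTable", tableDeleted = "LifeTable"))
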