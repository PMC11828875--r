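# Synthetic vital-registration generator: Gompertz-Makeham mortality with
# age-band cause mixes, binomial deaths on a registry population, and a
# district/municipality layout mirroring the study design (14 districts,
# 59 municipalities, three multi-year periods, two sexes, ages 0-110).

.AGE_BANDS <- c("0-9", "10-19", "20-29", "30-39", "40-49", "50-59",
                "60-69", "70-79", "80-89", "90-99", "100-110")

.bandOfAge <- function(age) .AGE_BANDS[pmin(age %/% 10L, 10L) + 1L]

# run expr under a temporary RNG state seeded with `seed`
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
    globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed",
      envir = globalenv())) else assign(".Random.seed", old, globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

#' Default age-band cause mix
#'
#' Proportions of deaths by cause group within each 10-year age band,
#' shaped like an aged industrial-country cause-of-death profile: cancer
#' dominates mid life, circulatory diseases and pneumonia rise into old
#' age.
#'
#' @return matrix ageBand x cause (heart, cerebrovascular, pneumonia,
#'   cancer, other), rows summing to 1.
#' @export
defaultCauseMix <- function() {
  m <- rbind(
    c(.04, .02, .04, .08, .82),
    c(.05, .02, .02, .10, .81),
    c(.06, .03, .02, .12, .77),
    c(.08, .05, .02, .20, .65),
    c(.10, .08, .02, .30, .50),
    c(.11, .08, .02, .38, .41),
    c(.12, .08, .03, .42, .35),
    c(.14, .09, .06, .35, .36),
    c(.17, .10, .10, .22, .41),
    c(.20, .10, .12, .12, .46),
    c(.22, .09, .14, .06, .49))
  dimnames(m) <- list(.AGE_BANDS,
    c("heart", "cerebrovascular", "pneumonia", "cancer", "other"))
  m
}

#' Construct a Gompertz-Makeham mortality model
#'
#' @param lambda background (age-independent) hazard, default 3e-4.
#' @param alpha named senescent hazard level per sex; defaults give
#'   life expectancies near 77 (male) and 84 (female) years.
#' @param beta hazard log-slope per year of age, default 0.102.
#' @param infantBump additive hazard at age 0 (default 0).
#' @param districtEffect named hazard multiplier per district; unnamed
#'   districts get 1.
#' @param causeMix age-band cause-mix matrix (default [defaultCauseMix()]).
#' @param causeMultiplier NULL, or array period x cause x district of
#'   multipliers on each cause's hazard share.
#' @param yearEffectSD SD of the lognormal year-level hazard multiplier
#'   (default 0.02), giving the annual variation the uncertainty module
#'   estimates.
#' @return a [MortalityModel-class].
#' @export
mortalityModel <- function(lambda = 3e-4,
    alpha = c(male = 2.2e-5, female = 1.0e-5), beta = 0.102,
    infantBump = 0, districtEffect = numeric(), causeMix = defaultCauseMix(),
    causeMultiplier = NULL, yearEffectSD = 0.02) {
  new("MortalityModel", lambda = lambda, alpha = alpha, beta = beta,
      infantBump = infantBump, districtEffect = districtEffect,
      causeMix = causeMix, causeMultiplier = causeMultiplier,
      yearEffectSD = yearEffectSD)
}

#' Construct a synthetic-scenario configuration
#'
#' Defaults mirror the study setting: 14 districts partitioning 59
#' municipalities, three analysis periods (2006-2010, 2012-2015,
#' 2016-2018; 2011 excluded), roughly two million residents, and a
#' mildly aging beta(2, 1.8) age pyramid.
#'
#' @param nDistricts number of districts (default 14).
#' @param muniPerDistrict municipalities per district; defaults partition
#'   59 codes.
#' @param districtPopulations persons per district-year; default totals
#'   two million.
#' @param propMale proportion male (default 0.49).
#' @param pyramidShape beta-density shape parameters for the age pyramid.
#' @param periods named list of year vectors.
#' @param seed root seed fixing all downstream randomness.
#' @param model a [MortalityModel-class].
#' @return a [ScenarioConfig-class].
#' @export
scenarioConfig <- function(nDistricts = 14L,
    muniPerDistrict = NULL, districtPopulations = NULL, propMale = 0.49,
    pyramidShape = c(2.0, 1.8),
    periods = list(pre = 2006:2010, early = 2012:2015, late = 2016:2018),
    seed = 1L, model = mortalityModel()) {
  ids <- as.character(seq_len(nDistricts))
  if (is.null(muniPerDistrict)) {
    muniPerDistrict <- rep(59L %/% nDistricts, nDistricts)
    extra <- 59L - sum(muniPerDistrict)
    if (extra > 0) muniPerDistrict[seq_len(extra)] <-
        muniPerDistrict[seq_len(extra)] + 1L
  }
  muniPerDistrict <- stats::setNames(as.integer(muniPerDistrict), ids)
  if (is.null(districtPopulations)) {
    if (nDistricts == 14L) {
      districtPopulations <- c(300, 60, 70, 90, 330, 340, 120, 80, 70,
                               110, 100, 130, 100, 100) * 1e3
    } else {
      districtPopulations <- rep(2e6 / nDistricts, nDistricts)
    }
  }
  districtPopulations <- stats::setNames(districtPopulations, ids)
  new("ScenarioConfig", muniPerDistrict = muniPerDistrict,
      districtPopulations = districtPopulations, propMale = propMale,
      pyramidShape = pyramidShape, periods = periods,
      seed = as.integer(seed), model = model)
}

#' District map implied by a scenario
#'
#' Municipality codes M01..M59 are assigned to districts in order of the
#' configured layout.
#'
#' @param cfg a [ScenarioConfig-class].
#' @param evacuatedDistricts district ids flagged as containing
#'   evacuation-order zones (default "2","3","4").
#' @return a [DistrictMap-class].
#' @export
scenarioDistrictMap <- function(cfg, evacuatedDistricts = c("2", "3", "4")) {
  stopifnot(is(cfg, "ScenarioConfig"))
  codes <- sprintf("M%02d", seq_len(sum(cfg@muniPerDistrict)))
  districts <- rep(names(cfg@muniPerDistrict), cfg@muniPerDistrict)
  districtMap(stats::setNames(districts, codes),
              intersect(evacuatedDistricts, districts))
}

#' Generate a registry population table
#'
#' Each district-year receives its configured total, split by sex and
#' spread over ages 0-110 with pyramid weights: a beta-density shape
#' (broad cohort structure) tempered by the mortality model's own
#' survival curve, so the old-age tail thins out the way a real registry
#' does. A small lognormal district-year effect (SD 0.01) provides the
#' annual variation a real registry shows. Deterministic given the
#' scenario seed.
#'
#' @param cfg a [ScenarioConfig-class].
#' @return a [PopulationTable-class].
#' @export
generatePopulation <- function(cfg) {
  stopifnot(is(cfg, "ScenarioConfig"))
  ids <- names(cfg@muniPerDistrict)
  years <- sort(unlist(cfg@periods))
  shape <- stats::dbeta(((.AGES) + 0.5) / 111, cfg@pyramidShape[1L],
                        cfg@pyramidShape[2L])
  a <- array(0, dim = c(length(ids), 2L, length(.AGES), length(years)),
    dimnames = list(district = ids, sex = .SEXES,
                    age = as.character(.AGES), year = as.character(years)))
  .withSeed(cfg@seed, {
    for (d in ids) {
      yearEff <- exp(stats::rnorm(length(years), 0, 0.01))
      for (si in 1:2) {
        sx <- .SEXES[si]
        h <- cfg@model@lambda + cfg@model@alpha[[sx]] *
          exp(cfg@model@beta * .AGES)
        surv <- c(1, exp(-cumsum(h)))[seq_along(.AGES)]
        w <- shape * surv
        w <- w / sum(w)
        sexShare <- if (si == 1L) cfg@propMale else 1 - cfg@propMale
        base <- cfg@districtPopulations[[d]] * sexShare * w
        a[d, si, , ] <- round(outer(base, yearEff))
      }
    }
  })
  new("PopulationTable", counts = a)
}

# enumerate the 3-character roots of a cause group, for code sampling
.groupRoots <- function(group) {
  unlist(lapply(seq_len(nrow(group@ranges)), function(i) {
    r <- group@ranges[i, ]
    sprintf("%s%02d", r$letter, r$lo:r$hi)
  }))
}

.OTHER_ROOTS <- c("A41", "E11", "E14", "G30", "K70", "N18", "R54",
                  "V89", "W79", "X59", "J69", "F03")

# per-cell hazard decomposition: list(total, shares matrix cell x cause)
.cellHazards <- function(model, district, sex, age, period) {
  alpha <- model@alpha[sex]
  h0 <- model@lambda + alpha * exp(model@beta * age) +
    model@infantBump * (age == 0L)
  de <- rep(1, length(district))
  if (length(model@districtEffect)) {
    hit <- district %in% names(model@districtEffect)
    de[hit] <- model@districtEffect[district[hit]]
  }
  h0 <- h0 * de
  mix <- model@causeMix[.bandOfAge(age), , drop = FALSE]
  if (!is.null(model@causeMultiplier)) {
    mult <- model@causeMultiplier
    for (j in colnames(mix)) {
      if (j %in% dimnames(mult)[[2L]]) {
        ok <- !is.na(period) & period %in% dimnames(mult)[[1L]] &
          district %in% dimnames(mult)[[3L]]
        if (any(ok))
          mix[ok, j] <- mix[ok, j] *
            mult[cbind(period[ok], j, district[ok])]
      }
    }
  }
  hCause <- mix * h0
  list(total = rowSums(hCause), shares = hCause)
}

#' Simulate individual death records
#'
#' Per population cell (district, sex, age, year) deaths are Binomial
#' with probability q = 1 - exp(-h), where h is the Gompertz-Makeham
#' hazard scaled by the model's district effect, cause-mix/period
#' multipliers and a lognormal year effect. Each death is assigned a
#' cause bucket in proportion to the cause-specific hazard shares, an
#' ICD-10 code drawn uniformly from the bucket's code roots, a
#' municipality within the district, and a date uniform within the year.
#'
#' @param pop a [PopulationTable-class].
#' @param model a [MortalityModel-class] covering every stratum in pop.
#' @param seed integer seed; the output is deterministic given (pop,
#'   model, seed).
#' @param periods optional named list of year vectors, needed when the
#'   model carries period-specific cause multipliers.
#' @param dmap optional [DistrictMap-class] used to assign municipality
#'   codes; defaults to one municipality per district named after it.
#' @param groups cause groups whose code ranges are sampled from.
#' @return data.frame of death records (sex, age, icd10, municipality,
#'   date, year).
#' @export
simulateDeaths <- function(pop, model, seed, periods = NULL, dmap = NULL,
                           groups = defaultCauseGroups()) {
  stopifnot(is(pop, "PopulationTable"), is(model, "MortalityModel"))
  a <- pop@counts
  dn <- dimnames(a)
  grid <- expand.grid(district = dn[[1L]], sex = dn[[2L]],
    age = as.integer(dn[[3L]]), year = as.integer(dn[[4L]]),
    stringsAsFactors = FALSE)
  grid$count <- as.vector(a)
  grid$period <- NA_character_
  if (!is.null(periods))
    for (p in names(periods))
      grid$period[grid$year %in% periods[[p]]] <- p

  hz <- .cellHazards(model, grid$district, grid$sex, grid$age, grid$period)
  roots <- lapply(groups, .groupRoots)
  roots$other <- .OTHER_ROOTS
  causeNames <- colnames(model@causeMix)

  .withSeed(seed, {
    yearKey <- paste(grid$district, grid$year)
    uk <- unique(yearKey)
    eff <- stats::setNames(exp(stats::rnorm(length(uk), 0,
      model@yearEffectSD)), uk)
    h <- hz$total * unname(eff[yearKey])
    q <- 1 - exp(-h)
    deaths <- stats::rbinom(nrow(grid), grid$count, q)
    nz <- which(deaths > 0L)
    if (!length(nz)) {
      data.frame(sex = factor(character(), levels = .SEXES),
        age = integer(), icd10 = character(), municipality = character(),
        date = as.Date(character()), year = integer())
    } else {
      # cause split per nonzero cell
      shareMat <- hz$shares[nz, , drop = FALSE]
      shareMat <- shareMat / rowSums(shareMat)
      causeCounts <- t(vapply(seq_along(nz), function(i)
        as.integer(stats::rmultinom(1L, deaths[nz[i]], shareMat[i, ])),
        integer(length(causeNames))))
      colnames(causeCounts) <- causeNames
      cellIdx <- rep(nz, times = deaths[nz])
      causeOf <- unlist(lapply(seq_along(nz), function(i)
        rep(causeNames, causeCounts[i, ])), use.names = FALSE)
      icd <- character(length(cellIdx))
      for (cn in causeNames) {
        k <- which(causeOf == cn)
        if (length(k))
          icd[k] <- sample(roots[[cn]], length(k), replace = TRUE)
      }
      district <- grid$district[cellIdx]
      if (is.null(dmap)) {
        muni <- district
      } else {
        muni <- character(length(cellIdx))
        for (d in unique(district)) {
          cand <- names(dmap@map)[dmap@map == d]
          k <- which(district == d)
          muni[k] <- sample(cand, length(k), replace = TRUE)
        }
      }
      yr <- grid$year[cellIdx]
      date <- as.Date(sprintf("%d-01-01", yr)) +
        floor(stats::runif(length(cellIdx), 0, 365))
      data.frame(sex = factor(grid$sex[cellIdx], levels = .SEXES),
        age = grid$age[cellIdx], icd10 = icd, municipality = muni,
        date = date, year = yr, stringsAsFactors = FALSE)
    }
  })
}

#' Analytic life expectancy of the generating model
#'
#' Numeric integral of the survival function implied by the model's
#' piecewise-constant (per year of age) hazard: LE(age) =
#' sum_x S(x) (1 - exp(-h_x)) / h_x over x >= age, with S the survival
#' from \code{age}. Serves as the independent oracle for parameter
#' recovery of the simulate-then-estimate chain.
#'
#' @param model a [MortalityModel-class].
#' @param sex "male" or "female".
#' @param district district id (for the district hazard multiplier);
#'   default "1".
#' @param period period name when cause multipliers apply; default NA.
#' @param age starting exact age (default 0).
#' @param maxAge upper integration bound (default 130; survival beyond is
#'   negligible for human-like parameters).
#' @return expected remaining years at \code{age}.
#' @export
analyticLifeExpectancy <- function(model, sex = "male", district = "1",
                                   period = NA_character_, age = 0L,
                                   maxAge = 130L) {
  ages <- age:maxAge
  hz <- .cellHazards(model, rep(district, length(ages)),
                     rep(sex, length(ages)), ages,
                     rep(period, length(ages)))
  h <- hz$total
  if (any(h <= 0)) stop("non-positive hazard; LE diverges", call. = FALSE)
  S <- c(1, exp(-cumsum(h)))[seq_along(ages)]
  sum(S * (1 - exp(-h)) / h)
}

#' Generate district characteristics for a scenario
#'
#' Plausible 2010-style municipal covariates (population density, income
#' per capita, medical professionals and institutions per 100,000,
#' primary-industry and over-65 shares, financial capability index,
#' natural growth and net migration rates), drawn per municipality and
#' returned with the municipal population needed for district
#' aggregation. Purely synthetic; labelled as such.
#'
#' @param cfg a [ScenarioConfig-class].
#' @param dmap a [DistrictMap-class] (default [scenarioDistrictMap()]).
#' @return data.frame, one row per municipality.
#' @export
generateCharacteristics <- function(cfg, dmap = scenarioDistrictMap(cfg)) {
  stopifnot(is(cfg, "ScenarioConfig"))
  codes <- names(dmap@map)
  n <- length(codes)
  .withSeed(cfg@seed + 101L, {
    shares <- stats::setNames(stats::runif(n, 0.5, 1.5), codes)
    pops <- numeric(n)
    for (d in unique(dmap@map)) {
      k <- which(dmap@map == d)
      pops[k] <- cfg@districtPopulations[[d]] * shares[k] / sum(shares[k])
    }
    clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
    data.frame(municipality = codes, district = unname(dmap@map),
      population = round(pops),
      density = round(exp(stats::rnorm(n, 5, 0.9))),
      income = round(stats::rnorm(n, 2.9e6, 3e5)),
      medical_professionals = round(clip(stats::rnorm(n, 220, 60), 40, 600)),
      medical_institutions = round(clip(stats::rnorm(n, 80, 15), 20, 200)),
      pct_primary_industry = round(clip(stats::rnorm(n, 8, 4), 0, 60), 1),
      pct_over65 = round(clip(stats::rnorm(n, 28, 4), 10, 50), 1),
      financial_capability_index = round(clip(stats::rnorm(n, 0.5, 0.15),
                                              0.1, 1.2), 3),
      natural_growth_rate = round(stats::rnorm(n, -0.5, 0.2), 2),
      net_migration_rate = round(stats::rnorm(n, -0.3, 0.3), 2),
      stringsAsFactors = FALSE)
  })
}

#' Write a complete synthetic scenario to disk
#'
#' Emits deaths.csv, population.csv, district_map.yaml and
#' characteristics.csv in the package's file dialects.
#'
#' @param cfg a [ScenarioConfig-class].
#' @param dir output directory (created if needed).
#' @param evacuatedDistricts passed to [scenarioDistrictMap()].
#' @return invisibly, a named character vector of the written paths.
#' @export
writeScenario <- function(cfg, dir, evacuatedDistricts = c("2", "3", "4")) {
  stopifnot(is(cfg, "ScenarioConfig"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dmap <- scenarioDistrictMap(cfg, evacuatedDistricts)
  pop <- generatePopulation(cfg)
  deaths <- simulateDeaths(pop, cfg@model, seed = cfg@seed + 1L,
                           periods = cfg@periods, dmap = dmap)
  chars <- generateCharacteristics(cfg, dmap)
  paths <- c(deaths = file.path(dir, "deaths.csv"),
             population = file.path(dir, "population.csv"),
             districtMap = file.path(dir, "district_map.yaml"),
             characteristics = file.path(dir, "characteristics.csv"))
  writeDeathRecords(deaths, paths[["deaths"]])
  writePopulation(pop, paths[["population"]])
  writeDistrictMap(dmap, paths[["districtMap"]])
  utils::write.csv(chars, paths[["characteristics"]], row.names = FALSE,
                   quote = FALSE)
  invisible(paths)
}
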