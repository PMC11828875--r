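# End-to-end pipeline: inputs (files or a synthetic scenario) ->
# aggregation -> life tables -> cause-deleted YLL -> Monte Carlo UIs ->
# district effect sizes, with a JSON run manifest.

.configHash <- function(s) {
  # tiny stable polynomial hash of the deparsed config, hex string
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Default pipeline configuration
#'
#' A complete configuration running the bundled synthetic scenario:
#' three periods (2006-2010, 2012-2015, 2016-2018; 2011 excluded), the
#' four major cause groups, central-rate life tables with Gompertz tail
#' over ages 80-94 -> 95-110, and (optionally) the Latin hypercube Monte
#' Carlo at prefecture level.
#'
#' @param seed root seed; every stochastic stage derives its own
#'   substream from it.
#' @param nTrials Monte Carlo trials (0 disables the Monte Carlo stage).
#' @return a nested configuration list accepted by [runPipeline()].
#' @export
defaultRunConfig <- function(seed = 1L, nTrials = 1000L) {
  list(
    schema = "lifeyears/1",
    seed = as.integer(seed),
    scenario = list(use = TRUE),
    inputs = NULL,
    periods = list(pre = 2006:2010, early = 2012:2015, late = 2016:2018),
    excludedYears = 2011L,
    evacuatedDistricts = c("2", "3", "4"),
    lifetable = list(method = "central", a0 = 0.1,
                     fitAges = 80:94),
    mc = list(nTrials = as.integer(nTrials), mode = "uniform"),
    yllAges = c(0L, 40L, 65L))
}

# period-average population by age for one district set, sex and period
.periodPop <- function(popArr, districts, sex, years) {
  sub <- popArr[districts, sex, , as.character(years), drop = FALSE]
  apply(sub, 3L, sum) / length(years)
}

.deathsByAge <- function(cube, districts, sex, period, cause = "all") {
  a <- cube@counts
  apply(a[period, districts, sex, , cause, drop = FALSE], 4L, sum)
}

# all-cause + cause-deleted life expectancies for one stratum
.stratumEstimates <- function(cube, popArr, districts, sex, period,
                              years, groups, cfgLT, yllAges) {
  popBar <- .periodPop(popArr, districts, sex, years)
  dAll <- .deathsByAge(cube, districts, sex, period)
  aSch <- defaultASchedule(a0 = cfgLT$a0)
  qs <- mortalityRates(dAll, popBar, years = length(years),
    method = cfgLT$method, aSchedule = aSch,
    stratum = list(sex = sex, period = period))
  qs <- extendTail(qs, fitAges = cfgLT$fitAges, aSchedule = aSch)
  lt <- buildLifeTable(qs, aSchedule = aSch)
  le <- vapply(yllAges, function(x) lifeExpectancy(lt, x), 0)
  names(le) <- paste0("LE_", yllAges)
  ylls <- list()
  for (g in groups) {
    dC <- .deathsByAge(cube, districts, sex, period, g@name)
    f <- ifelse(dAll > 0, dC / dAll, 0)
    band <- 90:94
    tailF <- if (sum(dAll[band + 1L]) > 0)
      sum(dC[band + 1L]) / sum(dAll[band + 1L]) else 0
    f[96:111] <- tailF
    res <- yll(qs, deleteCause(qs, f), ages = yllAges, aSchedule = aSch,
               cause = g@name)
    ylls[[g@name]] <- res
  }
  list(qs = qs, lt = lt, le = le, ylls = ylls)
}

#' Run the full analysis pipeline
#'
#' Reads (or generates) death records, population counts, the district
#' map and district characteristics; aggregates deaths into the count
#' cube; builds prefecture- and district-level life tables and YLL for
#' the four cause groups per sex and period; runs the Latin hypercube
#' Monte Carlo at prefecture level (when \code{mc$nTrials > 0}); computes
#' changes versus the pre-disaster period and their district effect
#' sizes; and writes plain CSV outputs plus a JSON manifest. The bundle
#' is deterministic given the configuration and seed; on error, partial
#' outputs are removed and the failing stage is named.
#'
#' @param config configuration list (see [defaultRunConfig()]) or the
#'   path of a YAML file holding one.
#' @param outDir output directory.
#' @return invisibly, a list with the in-memory results (cube, prefecture
#'   and district estimates, effects tables, MC results, manifest).
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed)
  periods <- lapply(config$periods, as.integer)
  groups <- defaultCauseGroups()
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  on.exit(if (!is.null(attr(written, "failed"))) unlink(written))

  # --- inputs ---------------------------------------------------------
  if (isTRUE(config$scenario$use)) {
    inp <- .withStage("synthetic_data", {
      sc <- config$scenario
      cfg <- scenarioConfig(
        nDistricts = if (is.null(sc$nDistricts)) 14L else sc$nDistricts,
        districtPopulations = sc$districtPopulations,
        periods = periods, seed = seed)
      dmap <- scenarioDistrictMap(cfg, config$evacuatedDistricts)
      pop <- generatePopulation(cfg)
      deaths <- simulateDeaths(pop, cfg@model, seed = seed + 1L,
                               periods = periods, dmap = dmap)
      chars <- generateCharacteristics(cfg, dmap)
      list(deaths = deaths, pop = pop, dmap = dmap, chars = chars,
           log = c(read = nrow(deaths), excluded = 0L, skipped = 0L))
    })
  } else {
    inp <- .withStage("io_formats", {
      paths <- config$inputs
      for (p in unlist(paths))
        if (!file.exists(p)) stop(sprintf("missing input file: %s", p))
      deaths <- readDeathRecords(paths$deaths,
        excludedYears = as.integer(config$excludedYears))
      list(deaths = deaths, pop = readPopulation(paths$population),
           dmap = readDistrictMap(paths$districtMap),
           chars = utils::read.csv(paths$characteristics),
           log = attr(deaths, "log"))
    })
  }

  # --- aggregation ----------------------------------------------------
  cube <- .withStage("aggregate",
    aggregateDeaths(inp$deaths, inp$dmap, periods, groups))
  popArr <- populationCounts(inp$pop)
  districts <- districtIds(inp$dmap)
  cfgLT <- config$lifetable
  yllAges <- as.integer(config$yllAges)
  sexes <- c("male", "female")

  # --- prefecture and district estimates ------------------------------
  est <- .withStage("lifetable", {
    pref <- list(); dist <- list()
    for (s in sexes) for (p in names(periods)) {
      pref[[paste(s, p)]] <- .stratumEstimates(cube, popArr, districts,
        s, p, periods[[p]], groups, cfgLT, yllAges)
      for (d in districts)
        dist[[paste(d, s, p)]] <- .stratumEstimates(cube, popArr, d,
          s, p, periods[[p]], groups, cfgLT, yllAges)
    }
    list(pref = pref, dist = dist)
  })

  prefRows <- do.call(rbind, lapply(names(est$pref), function(k) {
    sp <- strsplit(k, " ")[[1L]]
    e <- est$pref[[k]]
    data.frame(sex = sp[1L], period = sp[2L],
      quantity = c(names(e$le),
        unlist(lapply(e$ylls, function(y)
          paste0("YLL_", y@cause, "_", names(y@yll))))),
      value = c(unname(e$le),
        unlist(lapply(e$ylls, function(y) unname(y@yll)))))
  }))
  distRows <- do.call(rbind, lapply(names(est$dist), function(k) {
    sp <- strsplit(k, " ")[[1L]]
    e <- est$dist[[k]]
    data.frame(district = sp[1L], sex = sp[2L], period = sp[3L],
      LE_0 = unname(e$le[["LE_0"]]),
      as.data.frame(lapply(e$ylls, function(y) unname(y@yll[1L]))))
  }))
  names(distRows)[5:8] <- paste0("YLL_", names(est$dist[[1L]]$ylls))

  # --- Monte Carlo (prefecture) ---------------------------------------
  mcRes <- NULL
  if (!is.null(config$mc) && config$mc$nTrials > 0) {
    mcRes <- .withStage("uncertainty", {
      out <- list()
      years <- lapply(periods, as.character)
      for (s in sexes) for (p in names(periods)) {
        yrs <- years[[p]]
        dBy <- sapply(yrs, function(y) {
          idx <- inp$deaths$year == as.integer(y) & inp$deaths$sex == s
          tabulate(inp$deaths$age[idx] + 1L, nbins = 111L)
        })
        pBy <- sapply(yrs, function(y)
          apply(popArr[districts, s, , y, drop = FALSE], 3L, sum))
        stats <- cellStatsFromAnnual(dBy, pBy)
        causeStats <- lapply(groups, function(g) {
          bucket <- .assignCauseBucket(inp$deaths$icd10, groups)
          cBy <- sapply(yrs, function(y) {
            idx <- inp$deaths$year == as.integer(y) &
              inp$deaths$sex == s & bucket == g@name
            tabulate(inp$deaths$age[idx] + 1L, nbins = 111L)
          })
          r <- cBy[1:95, , drop = FALSE] / pBy[1:95, , drop = FALSE]
          list(rateMean = rowMeans(r), rateSD = apply(r, 1L, stats::sd))
        })
        names(causeStats) <- vapply(groups, function(g) g@name, "")
        out[[paste(s, p)]] <- monteCarloEstimates(stats, causeStats,
          nTrials = config$mc$nTrials,
          seed = seed + 1000L + 10L * match(p, names(periods)) +
            match(s, sexes), mode = config$mc$mode,
          stratumLabel = paste(s, p, sep = "_"))
      }
      # LE_0 period differences vs pre
      for (s in sexes) for (p in setdiff(names(periods), "pre")) {
        out[[paste(s, p, "minus pre")]] <- list(dLE0 = periodDifference(
          out[[paste(s, "pre")]]$LE_0, out[[paste(s, p)]]$LE_0,
          label = paste0(s, "_dLE_0_", p, "_vs_pre")))
      }
      out
    })
  }

  # --- district deltas and effect sizes -------------------------------
  eff <- .withStage("district_analysis", {
    distChars <- aggregateCharacteristics(inp$chars, inp$dmap)
    outcomes <- c("LE_0", paste0("YLL_", names(est$dist[[1L]]$ylls)))
    charCols <- setdiff(names(distChars),
                        c("district", "population", "evacuated"))
    effRows <- list(); cmpRows <- list()
    for (s in sexes) for (p in setdiff(names(periods), "pre")) {
      for (oc in outcomes) {
        pre <- distRows[distRows$sex == s & distRows$period == "pre", ]
        post <- distRows[distRows$sex == s & distRows$period == p, ]
        pre <- pre[match(distChars$district, pre$district), ]
        post <- post[match(distChars$district, post$district), ]
        delta <- post[[oc]] - pre[[oc]]
        for (cl in charCols) {
          row <- effectSizeContinuous(distChars[[cl]], delta,
                                      variable = cl,
                                      outcome = paste("d", oc))
          row$sex <- s; row$period <- p
          effRows[[length(effRows) + 1L]] <- row
        }
        evac <- distChars$evacuated == 1L
        row <- groupCompare(delta[evac], delta[!evac],
                            outcome = paste("d", oc))
        row$sex <- s; row$period <- p
        effRows[[length(effRows) + 1L]] <-
          row[, c("variable", "outcome", "r", "t", "df", "p",
                  "significant", "sex", "period")]
        cmpRows[[length(cmpRows) + 1L]] <- row
      }
    }
    list(effects = do.call(rbind, lapply(effRows, function(r)
           r[, c("sex", "period", "variable", "outcome", "r", "t", "df",
                 "p", "significant")])),
         compare = do.call(rbind, cmpRows),
         distChars = distChars)
  })

  # --- outputs --------------------------------------------------------
  .withStage("write", {
    f <- function(name) file.path(outDir, name)
    written <- c(f("prefecture_estimates.csv"),
                 f("district_estimates.csv"), f("effects.csv"),
                 f("group_compare.csv"), f("manifest.json"))
    attr(written, "failed") <- TRUE
    utils::write.csv(prefRows, f("prefecture_estimates.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(distRows, f("district_estimates.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(eff$effects, f("effects.csv"), row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(eff$compare, f("group_compare.csv"),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(mcRes)) {
      flat <- unlist(mcRes, recursive = FALSE)
      written <- c(written, f("mc_results.csv"))
      writeMCResults(flat, f("mc_results.csv"))
    }
    manifest <- list(
      schema = config$schema,
      configHash = .configHash(paste(deparse(config), collapse = "")),
      seed = seed,
      recordsRead = unname(inp$log[["read"]]),
      excludedYearRecords = unname(inp$log[["excluded"]]),
      deathsAggregated = sum(cube@counts[, , , , "all"]),
      outOfPeriod = unname(attr(cube, "log")[["outOfPeriod"]]),
      districts = length(districts),
      periods = lapply(periods, range))
    jsonlite::write_json(manifest, f("manifest.json"), auto_unbox = TRUE,
                         digits = NA)
    attr(written, "failed") <- NULL
  })
  on.exit()

  invisible(list(cube = cube, prefecture = prefRows, districts = distRows,
                 effects = eff$effects, compare = eff$compare, mc = mcRes,
                 manifest = file.path(outDir, "manifest.json"),
                 estimates = est))
}
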