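# Latin hypercube Monte Carlo uncertainty intervals for life expectancy,
# YLL, and their period differences, driven by the annual variation of
# populations and crude mortality rates over each period's years.

#' Mean and SD of annual values
#'
#' @param annualValues numeric vector, one value per year (>= 2 years).
#' @return named numeric c(mean, sd); sd uses the n-1 denominator.
#' @export
annualVariation <- function(annualValues) {
  if (length(annualValues) < 2L)
    stop("need at least 2 years to estimate annual variation",
         call. = FALSE)
  c(mean = mean(annualValues), sd = stats::sd(annualValues))
}

#' Per-age input statistics for the Monte Carlo
#'
#' Summarises annual population counts and crude mortality rates
#' (deaths / population, per year) over a period's years into per-age
#' means and sample SDs for ages 0-94, the inputs the Latin hypercube
#' perturbs.
#'
#' @param deathsByYear matrix ages(0..110 rows) x years of death counts.
#' @param popByYear matrix ages x years of population counts (positive
#'   over ages 0-94).
#' @param ages ages summarised (default 0:94).
#' @return list with numeric vectors popMean, popSD, rateMean, rateSD
#'   (named by age) and the scalar nYears.
#' @export
cellStatsFromAnnual <- function(deathsByYear, popByYear, ages = 0:94) {
  stopifnot(ncol(deathsByYear) >= 2L,
            identical(dim(deathsByYear), dim(popByYear)))
  i <- ages + 1L
  if (any(popByYear[i, ] <= 0))
    stop("non-positive population in an age 0-94 cell", call. = FALSE)
  rates <- deathsByYear[i, , drop = FALSE] / popByYear[i, , drop = FALSE]
  pops <- popByYear[i, , drop = FALSE]
  list(popMean = stats::setNames(rowMeans(pops), ages),
       popSD = stats::setNames(apply(pops, 1L, stats::sd), ages),
       rateMean = stats::setNames(rowMeans(rates), ages),
       rateSD = stats::setNames(apply(rates, 1L, stats::sd), ages),
       nYears = ncol(deathsByYear))
}

#' Latin hypercube normal draws
#'
#' For each dimension the n trials occupy each probability stratum
#' (k/n, (k+1)/n] exactly once -- uniformly within the stratum by default,
#' or at the stratum midpoint -- independently permuted across dimensions,
#' then mapped through the normal inverse CDF.
#'
#' @param means,sds numeric vectors of equal length (one entry per
#'   dimension); sds >= 0 (an sd of 0 collapses that dimension onto its
#'   mean).
#' @param nTrials number of trials (rows).
#' @param seed integer seed; draws are deterministic given it.
#' @param mode "uniform" (default) or "midpoint".
#' @return numeric matrix nTrials x length(means).
#' @export
lhsNormalDraws <- function(means, sds, nTrials, seed,
                           mode = c("uniform", "midpoint")) {
  mode <- match.arg(mode)
  stopifnot(length(means) == length(sds), all(sds >= 0))
  k <- length(means)
  P <- .withSeed(seed, {
    if (mode == "uniform") {
      lhs::randomLHS(nTrials, k)
    } else {
      vapply(seq_len(k),
             function(j) (sample.int(nTrials) - 0.5) / nTrials,
             numeric(nTrials))
    }
  })
  P <- matrix(P, nrow = nTrials)
  Z <- stats::qnorm(P)
  sweep(sweep(Z, 2L, sds, "*"), 2L, means, "+")
}

# rebuild a complete q schedule (as a trials x 111 matrix) from perturbed
# crude rates over ages 0..94: occurrence-exposure conversion, then a
# vectorised Gompertz tail fit over fitAges extrapolated to 95..110.
.qMatrixFromRates <- function(rateDraws, aSchedule, fitAges = 80:94) {
  nT <- nrow(rateDraws)
  m <- pmin(pmax(rateDraws, 0), 1)
  aObs <- rep(aSchedule[1:95], each = nT)
  qObs <- m / (1 + (1 - aObs) * m)
  x <- fitAges
  Y <- log(pmax(m[, fitAges + 1L, drop = FALSE], 1e-10))
  xc <- x - mean(x)
  b <- as.vector(Y %*% xc) / sum(xc^2)
  a0 <- rowMeans(Y) - b * mean(x)
  tailAges <- 95:110
  mTail <- exp(outer(b, tailAges) + a0)
  aTail <- rep(aSchedule[tailAges + 1L], each = nT)
  qTail <- pmin(mTail / (1 + (1 - aTail) * mTail), 1)
  Q <- cbind(qObs, qTail)
  Q[, 111L] <- 1
  Q
}

#' Monte Carlo life expectancy and YLL with Latin hypercube sampling
#'
#' Per trial, populations and all-cause crude mortality rates at ages
#' 0-94 are drawn from per-age normal distributions (Latin hypercube
#' stratification, truncated to non-negative populations and rates in
#' [0,1]); the mortality schedule is rebuilt (tail re-estimated per
#' trial) and life expectancy computed. For each requested cause a
#' distinct set of cause-specific rate draws yields per-trial cause
#' fractions, cause-deleted schedules and YLL. Point estimates come from
#' the unperturbed mean inputs.
#'
#' Trials whose population draws are all zero are rejected and redrawn
#' quantities excluded; more than 1% rejections is an error.
#'
#' @param stats all-cause input statistics from [cellStatsFromAnnual()].
#' @param causeStats optional named list (one entry per cause) of
#'   statistics lists with rateMean/rateSD for that cause's rates.
#' @param nTrials number of trials (default 10000).
#' @param seed integer seed.
#' @param ages ages at which LE/YLL are reported (default 0, 40, 65).
#' @param aSchedule fraction-of-year-lived schedule.
#' @param mode Latin hypercube mode, see [lhsNormalDraws()].
#' @param stratumLabel label prefix for result names.
#' @return named list of [MCResult-class]: \code{LE_<age>} and, per cause,
#'   \code{YLL_<cause>_<age>}.
#' @export
monteCarloEstimates <- function(stats, causeStats = NULL, nTrials = 10000L,
    seed = 1L, ages = c(0L, 40L, 65L), aSchedule = defaultASchedule(),
    mode = "uniform", stratumLabel = "") {
  nTrials <- as.integer(nTrials)
  popDraws <- lhsNormalDraws(stats$popMean, stats$popSD, nTrials,
                             seed = seed, mode = mode)
  popDraws <- pmax(popDraws, 0)
  rateDraws <- lhsNormalDraws(stats$rateMean, stats$rateSD, nTrials,
                              seed = seed + 1L, mode = mode)
  reject <- rowSums(popDraws) == 0
  if (mean(reject) > 0.01)
    stop("more than 1% of trials rejected (degenerate population draws)",
         call. = FALSE)
  keep <- which(!reject)
  Q <- .qMatrixFromRates(rateDraws[keep, , drop = FALSE], aSchedule)
  LE <- .leFromQMatrix(Q, ages, aSchedule)

  pointQ <- .qMatrixFromRates(matrix(stats$rateMean, nrow = 1L), aSchedule)
  pointLE <- .leFromQMatrix(pointQ, ages, aSchedule)

  lab <- function(what) if (nzchar(stratumLabel))
    paste(stratumLabel, what, sep = ":") else what
  out <- list()
  for (j in seq_along(ages)) {
    tr <- LE[, j]
    out[[paste0("LE_", ages[j])]] <- new("MCResult",
      label = lab(paste0("LE_", ages[j])), point = unname(pointLE[1L, j]),
      median = stats::median(tr),
      lower = unname(stats::quantile(tr, 0.025)),
      upper = unname(stats::quantile(tr, 0.975)),
      nTrials = nTrials, seed = as.integer(seed), trials = tr,
      significant = NA)
  }
  for (cn in names(causeStats)) {
    cs <- causeStats[[cn]]
    cDraws <- lhsNormalDraws(cs$rateMean, cs$rateSD, nTrials,
      seed = seed + 1L + match(cn, names(causeStats)), mode = mode)
    cDraws <- pmin(pmax(cDraws, 0), 1)[keep, , drop = FALSE]
    allR <- pmax(rateDraws[keep, , drop = FALSE], 1e-12)
    Fmat <- pmin(cDraws / allR, 1)
    # tail fractions: pooled over the last reliable band (90-94)
    fTail <- rowSums(cDraws[, 91:95, drop = FALSE]) /
      pmax(rowSums(allR[, 91:95, drop = FALSE]), 1e-12)
    Ffull <- cbind(Fmat, matrix(pmin(fTail, 1), nrow(Fmat), 16L))
    Qdel <- 1 - (1 - Q)^(1 - Ffull)
    LEdel <- .leFromQMatrix(Qdel, ages, aSchedule)

    fPoint <- pmin(cs$rateMean / pmax(stats$rateMean, 1e-12), 1)
    fpTail <- min(sum(cs$rateMean[91:95]) /
                  max(sum(stats$rateMean[91:95]), 1e-12), 1)
    QdelP <- 1 - (1 - pointQ)^(1 - c(fPoint, rep(fpTail, 16L)))
    pointDel <- .leFromQMatrix(matrix(QdelP, nrow = 1L), ages, aSchedule)

    for (j in seq_along(ages)) {
      tr <- LEdel[, j] - LE[, j]
      out[[paste0("YLL_", cn, "_", ages[j])]] <- new("MCResult",
        label = lab(paste0("YLL_", cn, "_", ages[j])),
        point = unname(pointDel[1L, j] - pointLE[1L, j]),
        median = stats::median(tr),
        lower = unname(stats::quantile(tr, 0.025)),
        upper = unname(stats::quantile(tr, 0.975)),
        nTrials = nTrials, seed = as.integer(seed), trials = tr,
        significant = NA)
    }
  }
  out
}

#' Period difference of two Monte Carlo trial sets
#'
#' Differences are taken trial-wise between two independently drawn trial
#' sets (no pairing is implied: both sets are i.i.d. over trials). The
#' result's \code{significant} slot is TRUE when the 95% UI excludes 0.
#'
#' @param mcA,mcB [MCResult-class] objects (the difference is B - A) or
#'   numeric trial vectors of equal length.
#' @param label result label.
#' @return a [MCResult-class] for (B - A).
#' @export
periodDifference <- function(mcA, mcB, label = "difference") {
  trA <- if (is(mcA, "MCResult")) mcA@trials else mcA
  trB <- if (is(mcB, "MCResult")) mcB@trials else mcB
  if (length(trA) != length(trB))
    stop("trial sets differ in length", call. = FALSE)
  d <- trB - trA
  lo <- unname(stats::quantile(d, 0.025))
  hi <- unname(stats::quantile(d, 0.975))
  pt <- if (is(mcA, "MCResult") && is(mcB, "MCResult"))
    mcB@point - mcA@point else NA_real_
  new("MCResult", label = label, point = pt, median = stats::median(d),
      lower = lo, upper = hi, nTrials = length(d),
      seed = NA_integer_, trials = d,
      significant = (lo > 0 || hi < 0))
}

#' District-group confidence intervals
#'
#' For each group of districts, the mean of the district point estimates,
#' the standard error across districts (sd / sqrt(n)) and the normal 95%
#' CI mean +/- 1.96 SE.
#'
#' @param values named numeric vector of district point estimates.
#' @param groups factor or character vector (same length) assigning each
#'   district to a group; every group needs >= 2 districts.
#' @return data.frame with columns group, n, mean, se, ciLower, ciUpper.
#' @export
groupCI <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- as.factor(groups)
  if (any(table(groups) < 2L))
    stop("every group needs at least 2 districts", call. = FALSE)
  rows <- lapply(levels(groups), function(g) {
    v <- values[groups == g]
    se <- stats::sd(v) / sqrt(length(v))
    data.frame(group = g, n = length(v), mean = mean(v), se = se,
               ciLower = mean(v) - 1.96 * se,
               ciUpper = mean(v) + 1.96 * se)
  })
  do.call(rbind, rows)
}

#' Write Monte Carlo results to CSV
#'
#' @param results named list of [MCResult-class] objects.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
writeMCResults <- function(results, path) {
  rows <- do.call(rbind, lapply(results, function(r)
    data.frame(quantity = r@label, point = r@point, median = r@median,
               ui_low = r@lower, ui_high = r@upper, n_trials = r@nTrials,
               seed = r@seed)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
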