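# Cause-deleted life tables (proportional cause elimination) and years of
# life lost at ages 0, 40 and 65.

#' Per-age cause fractions of all-cause deaths
#'
#' f_x = cause-group deaths / all-cause deaths at age x for one stratum of
#' a [DeathCountCube-class]. Where all-cause deaths are zero, f_x = 0.
#' Because cause-specific counts are too sparse in the open ages, fractions
#' for ages above \code{reliableBand} are replaced by the pooled fraction
#' over that band (default 90-94), matching the tail ages the life-table
#' module estimates rather than observes.
#'
#' @param cube a [DeathCountCube-class].
#' @param period,sex period and sex labels selecting the stratum.
#' @param cause cause-bucket name present in the cube.
#' @param district district id, or NULL (default) to pool all districts.
#' @param reliableBand ages whose pooled fraction is carried into the tail.
#' @return numeric vector of fractions at ages 0..110, with attributes
#'   \code{stratum} and \code{cause}.
#' @export
causeFraction <- function(cube, period, sex, cause, district = NULL,
                          reliableBand = 90:94) {
  stopifnot(is(cube, "DeathCountCube"))
  a <- cube@counts
  pick <- function(bucket) {
    if (is.null(district))
      apply(a[period, , sex, , bucket, drop = FALSE], 4L, sum)
    else
      a[period, district, sex, , bucket]
  }
  cs <- pick(cause)
  all <- pick("all")
  if (any(cs > all))
    stop("cause deaths exceed all-cause deaths (invariant breach)",
         call. = FALSE)
  f <- ifelse(all > 0, cs / all, 0)
  tail <- (max(reliableBand) + 1L):110L
  bandAll <- sum(all[reliableBand + 1L])
  f[tail + 1L] <- if (bandAll > 0) sum(cs[reliableBand + 1L]) / bandAll else 0
  structure(f, names = .AGES,
            stratum = list(period = period, sex = sex, district = district),
            cause = cause)
}

#' Delete a cause from a mortality schedule
#'
#' Proportional cause elimination (Chiang): the cause-deleted probability
#' is q_x^-i = 1 - (1 - q_x)^(1 - f_x), where f_x is the cause's fraction
#' of deaths at age x. This is the standard construction of the survival
#' curve "without" a cause, and guarantees non-negative YLL. A naive
#' subtraction variant q_x^-i = q_x (1 - f_x) is available for
#' sensitivity checks.
#'
#' @param qs a [QSchedule-class].
#' @param f numeric vector of cause fractions at ages 0..omega, each in
#'   [0,1].
#' @param method "chiang" (default) or "subtraction".
#' @return a [QSchedule-class] with the same source flags.
#' @examples
#' # q = 0.2, f = 0.5: 1 - 0.8^0.5 = 0.105573
#' @export
deleteCause <- function(qs, f, method = c("chiang", "subtraction")) {
  method <- match.arg(method)
  stopifnot(is(qs, "QSchedule"), length(f) == length(qs@q))
  if (any(f < 0 | f > 1)) stop("cause fractions outside [0,1]",
                               call. = FALSE)
  q <- qs@q
  qDel <- if (method == "chiang") 1 - (1 - q)^(1 - f) else q * (1 - f)
  new("QSchedule", q = qDel, source = qs@source, stratum = qs@stratum)
}

#' Years of life lost to a cause at given ages
#'
#' Builds the all-cause and cause-deleted life tables with identical
#' conventions and returns YLL(x) = e_x(deleted) - e_x(all-cause): the
#' area between the two survival curves beyond age x, per survivor at x.
#'
#' @param qsAll all-cause [QSchedule-class].
#' @param qsDeleted cause-deleted [QSchedule-class] (same stratum and
#'   length).
#' @param ages ages at which to evaluate YLL (default 0, 40, 65).
#' @param radix life-table radix.
#' @param aSchedule fraction-of-year-lived schedule.
#' @param cause cause label carried on the result.
#' @return a [YLLResult-class].
#' @export
yll <- function(qsAll, qsDeleted, ages = c(0L, 40L, 65L), radix = 1e5,
                aSchedule = defaultASchedule(), cause = "cause") {
  stopifnot(is(qsAll, "QSchedule"), is(qsDeleted, "QSchedule"))
  if (length(qsAll@q) != length(qsDeleted@q))
    stop("schedules must share omega", call. = FALSE)
  if (!identical(qsAll@stratum, qsDeleted@stratum))
    stop("schedules belong to different strata", call. = FALSE)
  ltAll <- buildLifeTable(qsAll, radix = radix, aSchedule = aSchedule)
  ltDel <- buildLifeTable(qsDeleted, radix = radix, aSchedule = aSchedule)
  v <- vapply(ages, function(x)
    lifeExpectancy(ltDel, x) - lifeExpectancy(ltAll, x), 0)
  new("YLLResult", cause = cause, yll = stats::setNames(v, ages),
      tableAll = ltAll, tableDeleted = ltDel)
}

#' Write YLL results to CSV
#'
#' One row per (stratum, cause, age), mirroring a prefecture-level YLL
#' table layout.
#'
#' @param results list of [YLLResult-class] objects.
#' @param path output CSV path.
#' @param strata optional character vector of stratum labels, recycled.
#' @return invisibly, the path.
#' @export
writeYLL <- function(results, path, strata = NULL) {
  rows <- do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    data.frame(
      stratum = if (is.null(strata)) i else strata[[i]],
      cause = r@cause, age = as.integer(names(r@yll)),
      yll_years = unname(r@yll))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
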