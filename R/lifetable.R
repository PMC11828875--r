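# Period life-table construction: occurrence-exposure rates, Gompertz
# tail extrapolation for the open ages, and the l/d/L/T/e columns.

#' Default fraction-of-year-lived schedule
#'
#' a_x is the average fraction of the year of age lived by those dying in
#' it. Infant deaths cluster early in the first year, so a_0 defaults to
#' 0.1; all other ages use 0.5 (deaths spread evenly).
#'
#' @param omega closing age of the table (default 110).
#' @param a0 value at age 0.
#' @return numeric vector of length omega+1.
#' @export
defaultASchedule <- function(omega = 110L, a0 = 0.1) {
  a <- rep(0.5, omega + 1L)
  a[1L] <- a0
  a
}

#' Estimate single-year mortality probabilities from deaths and exposure
#'
#' Computes age-specific death rates m_x = deaths_x / (pop_x * years) --
#' the period-average population times the period length is the
#' person-years of exposure -- and converts them to probabilities. With
#' \code{method = "central"} (default) the standard occurrence-exposure
#' conversion q_x = m_x / (1 + (1 - a_x) m_x) is used; with
#' \code{method = "direct"} q_x = deaths_x / (pop_x * years), clipped to
#' [0,1].
#'
#' Ages 0-94 are filled and flagged "observed" (age 0 is flagged
#' "estimated-age0" because of its special a_0 convention); ages 95+ are
#' left "missing" for [extendTail()]. Ages with zero population and zero
#' deaths get q log-linearly interpolated from the nearest observed
#' neighbours and are flagged "interpolated". Zero population with
#' positive deaths is an error.
#'
#' @param deathsByAge numeric vector of death counts at ages 0..110.
#' @param popByAge numeric vector of period-average population at ages
#'   0..110.
#' @param years period length in years (exposure multiplier, default 1).
#' @param method "central" or "direct".
#' @param aSchedule fraction-of-year-lived schedule (see
#'   [defaultASchedule()]).
#' @param stratum named list of labels carried on the result.
#' @param observedAges ages treated as directly observable (default 0:94).
#' @return a [QSchedule-class] with ages 95+ flagged "missing".
#' @export
mortalityRates <- function(deathsByAge, popByAge, years = 1,
    method = c("central", "direct"), aSchedule = defaultASchedule(),
    stratum = list(), observedAges = 0:94) {
  method <- match.arg(method)
  omega <- 110L
  stopifnot(length(deathsByAge) == omega + 1L,
            length(popByAge) == omega + 1L)
  if (any(popByAge == 0 & deathsByAge > 0))
    stop("zero population with positive deaths at age ",
         which(popByAge == 0 & deathsByAge > 0)[1L] - 1L, call. = FALSE)
  q <- rep(NA_real_, omega + 1L)
  src <- rep("missing", omega + 1L)
  obs <- observedAges + 1L
  expo <- popByAge * years
  if (method == "central") {
    m <- ifelse(expo > 0, deathsByAge / expo, NA_real_)
    qq <- m / (1 + (1 - aSchedule) * m)
  } else {
    qq <- ifelse(expo > 0, deathsByAge / expo, NA_real_)
  }
  q[obs] <- pmin(pmax(qq[obs], 0), 1)
  src[obs] <- "observed"
  src[1L] <- "estimated-age0"
  # empty cells: log-linear interpolation between nearest observed ages
  empty <- obs[is.na(q[obs])]
  if (length(empty)) {
    known <- obs[!is.na(q[obs])]
    if (length(known) < 2L)
      stop("too few observed ages to interpolate empty cells",
           call. = FALSE)
    lq <- log(pmax(q[known], 1e-12))
    q[empty] <- exp(stats::approx(known, lq, xout = empty, rule = 2)$y)
    src[empty] <- "interpolated"
  }
  new("QSchedule", q = q, source = src, stratum = stratum)
}

#' Extrapolate the mortality schedule into the open ages
#'
#' Back-computes death rates m_x from q over \code{fitAges}, fits the
#' Gompertz form log m_x = a + b x by least squares, extrapolates m over
#' \code{targetAges}, converts back to q and closes the table with
#' q_omega = 1. Extended ages are flagged "estimated-tail". This stands in
#' for the official old-age estimation method whose parameters are not
#' published.
#'
#' @param qs a [QSchedule-class] with observed q over \code{fitAges}.
#' @param fitAges ages used for the regression (default 80:94).
#' @param targetAges ages to fill (default 95:110).
#' @param aSchedule fraction-of-year-lived schedule used for the m <-> q
#'   conversions.
#' @return the completed [QSchedule-class].
#' @export
extendTail <- function(qs, fitAges = 80:94, targetAges = 95:110,
                       aSchedule = defaultASchedule()) {
  stopifnot(is(qs, "QSchedule"))
  q <- qs@q
  src <- qs@source
  a <- aSchedule
  usable <- fitAges[!is.na(q[fitAges + 1L]) & q[fitAges + 1L] > 0 &
                    q[fitAges + 1L] < 1]
  if (length(usable) < 3L)
    stop("need at least 3 usable fit ages with q in (0,1)", call. = FALSE)
  qf <- q[usable + 1L]
  m <- qf / (1 - (1 - a[usable + 1L]) * qf)
  fit <- stats::lsfit(usable, log(m))
  co <- fit$coefficients
  mHat <- exp(co[1L] + co[2L] * targetAges)
  qHat <- mHat / (1 + (1 - a[targetAges + 1L]) * mHat)
  q[targetAges + 1L] <- pmin(qHat, 1)
  src[targetAges + 1L] <- "estimated-tail"
  q[length(q)] <- 1
  src[length(src)] <- "estimated-tail"
  new("QSchedule", q = q, source = src, stratum = qs@stratum)
}

#' Build a complete life table from a mortality schedule
#'
#' Survivors l_x decrease by the schedule's probabilities from the radix;
#' d_x = l_x q_x, person-years L_x = l_{x+1} + a_x d_x, T_x is the
#' reverse cumulative sum of L and e_x = T_x / l_x. The table is closed
#' at omega: everyone alive there dies within the interval and lives
#' a_omega of one year on average (L_omega = a_omega l_omega).
#'
#' @param qs a [QSchedule-class] with no missing ages.
#' @param radix l_0, default 100000.
#' @param aSchedule fraction-of-year-lived schedule.
#' @return a [LifeTable-class].
#' @examples
#' qs <- new("QSchedule", q = c(rep(0.5, 110), 1),
#'           source = rep("observed", 111), stratum = list())
#' lifeExpectancy(buildLifeTable(qs, aSchedule = rep(0.5, 111)), 0) # 1.5
#' @export
buildLifeTable <- function(qs, radix = 1e5,
                           aSchedule = defaultASchedule()) {
  stopifnot(is(qs, "QSchedule"))
  q <- qs@q
  if (anyNA(q)) stop("schedule has missing ages; run extendTail() first",
                     call. = FALSE)
  if (any(q < 0 | q > 1)) stop("q outside [0,1]", call. = FALSE)
  n <- length(q)
  stopifnot(length(aSchedule) == n)
  a <- aSchedule
  l <- radix * cumprod(c(1, 1 - q[-n]))
  # closing: all survivors at omega die in the interval
  d <- c(l[-n] * q[-n], l[n])
  lNext <- c(l[-1L], 0)
  L <- lNext + a * d
  T <- rev(cumsum(rev(L)))
  e <- ifelse(l > 0, T / l, NA_real_)
  tb <- data.frame(age = seq_len(n) - 1L, q = q, l = l, d = d, L = L,
                   T = T, e = e)
  new("LifeTable", table = tb, radix = radix, a = a, stratum = qs@stratum)
}

#' Remaining life expectancy at an exact age
#'
#' @param lt a [LifeTable-class].
#' @param age integer age in 0..omega with l_age > 0.
#' @return e_age = T_age / l_age, in years.
#' @export
lifeExpectancy <- function(lt, age = 0L) {
  stopifnot(is(lt, "LifeTable"))
  tb <- lt@table
  i <- match(age, tb$age)
  if (is.na(i)) stop("age outside the table", call. = FALSE)
  if (tb$l[i] <= 0) stop("no survivors at age ", age, call. = FALSE)
  tb$T[i] / tb$l[i]
}

# Vectorised life expectancies at given ages for a matrix of q schedules
# (rows = trials, cols = ages 0..omega). Used by the Monte Carlo engine.
.leFromQMatrix <- function(Q, ages, aSchedule) {
  n <- ncol(Q)
  a <- aSchedule
  logs <- log1p(-pmin(Q[, -n, drop = FALSE], 1 - 1e-15))
  l <- cbind(1, exp(t(apply(logs, 1L, cumsum))))
  d <- cbind(l[, -n, drop = FALSE] * Q[, -n, drop = FALSE], l[, n])
  lNext <- cbind(l[, -1L, drop = FALSE], 0)
  L <- lNext + rep(a, each = nrow(Q)) * d
  T <- t(apply(L[, n:1, drop = FALSE], 1L, cumsum))[, n:1, drop = FALSE]
  out <- sapply(ages, function(x) T[, x + 1L] / l[, x + 1L])
  matrix(out, nrow = nrow(Q), dimnames = list(NULL, as.character(ages)))
}

#' Life expectancy directly from crude mortality rates
#'
#' Convenience wrapper used by the Monte Carlo engine's point estimates:
#' rates at ages 0-94 are converted to probabilities by the
#' occurrence-exposure formula, the tail is Gompertz-extrapolated over
#' the fit ages, and life expectancy read off the resulting table.
#'
#' @param rates crude mortality rates m_x at ages 0..94 (clamped to
#'   [0,1]).
#' @param ages ages at which LE is returned (default 0).
#' @param aSchedule fraction-of-year-lived schedule.
#' @param fitAges tail regression ages (default 80:94).
#' @return named numeric vector of life expectancies.
#' @export
leFromRates <- function(rates, ages = 0L, aSchedule = defaultASchedule(),
                        fitAges = 80:94) {
  stopifnot(length(rates) == 95L)
  Q <- .qMatrixFromRates(matrix(rates, nrow = 1L), aSchedule, fitAges)
  le <- .leFromQMatrix(Q, ages, aSchedule)
  stats::setNames(le[1L, ], ages)
}

#' Write a life table to CSV with a JSON metadata sidecar
#'
#' @param lt a [LifeTable-class].
#' @param path output CSV path; metadata goes to \code{paste0(path,
#'   ".json")}.
#' @return invisibly, the CSV path.
#' @export
writeLifeTable <- function(lt, path) {
  stopifnot(is(lt, "LifeTable"))
  utils::write.csv(lt@table, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(stratum = lt@stratum, radix = lt@radix, a0 = lt@a[1L]),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
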