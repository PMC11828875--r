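# District-level characteristics aggregation, change-from-pre-disaster
# deltas, and effect sizes (Pearson and point-biserial correlations with
# pooled two-sample t tests).

#' Aggregate municipal characteristics to districts
#'
#' All characteristics are population-weighted means across a district's
#' municipalities, except the columns named in \code{simpleMeanCols}
#' (default the financial capability index), which are simple means of
#' the municipal values. The district evacuation indicator comes from the
#' district map.
#'
#' @param muniTable data.frame with columns municipality, population and
#'   the characteristic columns.
#' @param dmap a [DistrictMap-class].
#' @param simpleMeanCols columns averaged without population weights.
#' @return data.frame, one row per district, with an \code{evacuated}
#'   0/1 column.
#' @export
aggregateCharacteristics <- function(muniTable, dmap,
    simpleMeanCols = "financial_capability_index") {
  stopifnot(is(dmap, "DistrictMap"))
  if (!all(c("municipality", "population") %in% names(muniTable)))
    stop("muniTable needs municipality and population columns",
         call. = FALSE)
  unknown <- setdiff(muniTable$municipality, names(dmap@map))
  if (length(unknown))
    stop(sprintf("unknown municipality '%s'", unknown[1L]), call. = FALSE)
  chars <- setdiff(names(muniTable),
                   c("municipality", "district", "population"))
  districts <- names(dmap@evacuated)
  rows <- lapply(districts, function(d) {
    sub <- muniTable[unname(dmap@map[muniTable$municipality]) == d, ,
                     drop = FALSE]
    wt <- sub$population
    if (sum(wt) <= 0)
      stop(sprintf("district %s has zero total population", d),
           call. = FALSE)
    vals <- vapply(chars, function(cl) {
      if (cl %in% simpleMeanCols) mean(sub[[cl]])
      else stats::weighted.mean(sub[[cl]], wt)
    }, 0)
    cbind(data.frame(district = d, population = sum(wt)),
          as.data.frame(as.list(vals)),
          data.frame(evacuated = as.integer(dmap@evacuated[[d]])))
  })
  do.call(rbind, rows)
}

#' Changes relative to the pre-disaster period
#'
#' @param metricByPeriod named numeric with a "pre" element and one or
#'   more post periods.
#' @param pre name of the reference period (default "pre").
#' @return named numeric of differences (post - pre), one per non-pre
#'   period, in input order.
#' @examples
#' deltaVsPre(c(pre = 78.57, early = 79.49, late = 80.12))
#' @export
deltaVsPre <- function(metricByPeriod, pre = "pre") {
  if (!pre %in% names(metricByPeriod))
    stop(sprintf("missing reference period '%s'", pre), call. = FALSE)
  post <- setdiff(names(metricByPeriod), pre)
  if (!length(post)) stop("no post period present", call. = FALSE)
  metricByPeriod[post] - metricByPeriod[[pre]]
}

.effectRow <- function(variable, outcome, r, t, df) {
  p <- 2 * stats::pt(-abs(t), df)
  data.frame(variable = variable, outcome = outcome, r = r, t = t,
             df = df, p = p, significant = abs(r) > 0.5)
}

#' Pearson effect size of a district characteristic on an outcome
#'
#' Pearson correlation r with its t statistic t = r sqrt(df / (1 - r^2)),
#' df = n - 2, and two-sided p value. The significance flag follows the
#' |r| > 0.5 effect-size rule.
#'
#' @param x per-district characteristic values (not constant, n >= 3).
#' @param y per-district outcome values (e.g. change in LE vs the
#'   pre-disaster period).
#' @param variable,outcome labels for the output row.
#' @return one-row data.frame: variable, outcome, r, t, df, p,
#'   significant.
#' @export
effectSizeContinuous <- function(x, y, variable = "x", outcome = "y") {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3L) stop("need at least 3 districts", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant characteristic", call. = FALSE)
  r <- stats::cor(x, y)
  df <- n - 2L
  t <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  .effectRow(variable, outcome, r, t, df)
}

#' Compare evacuation and non-evacuation districts
#'
#' Pooled-variance two-sample Student t test (df = n1 + n2 - 2) with the
#' point-biserial effect size r = t / sqrt(t^2 + df), oriented so r > 0
#' means the evacuation group is larger. Numerically identical to the
#' Pearson correlation of the outcome against a 0/1 evacuation code.
#'
#' @param evac outcome values for evacuation districts (n >= 2).
#' @param nonevac outcome values for non-evacuation districts (n >= 2).
#' @param outcome label for the output row.
#' @return one-row data.frame as in [effectSizeContinuous()], plus group
#'   means and SDs.
#' @export
groupCompare <- function(evac, nonevac, outcome = "y") {
  if (length(evac) < 2L || length(nonevac) < 2L)
    stop("each group needs at least 2 districts", call. = FALSE)
  groupCompareFromSummary(mean(evac), stats::sd(evac), length(evac),
                          mean(nonevac), stats::sd(nonevac),
                          length(nonevac), outcome = outcome)
}

#' Group comparison from printed summary statistics
#'
#' The pooled two-sample t statistic and point-biserial r computed
#' directly from group means, SDs and sizes -- the form needed to
#' reconstruct published effect sizes from a table of group summaries.
#'
#' @param meanEvac,sdEvac,nEvac mean, SD and size of the evacuation
#'   group.
#' @param meanNon,sdNon,nNon mean, SD and size of the non-evacuation
#'   group.
#' @param outcome label for the output row.
#' @return one-row data.frame: variable ("evacuated"), outcome, r, t, df,
#'   p, significant, meanEvac, sdEvac, meanNon, sdNon.
#' @examples
#' groupCompareFromSummary(1.64, 0.458, 3, 0.88, 0.422, 11) # r ~ 0.615
#' @export
groupCompareFromSummary <- function(meanEvac, sdEvac, nEvac, meanNon,
                                    sdNon, nNon, outcome = "y") {
  df <- nEvac + nNon - 2L
  sp2 <- ((nEvac - 1) * sdEvac^2 + (nNon - 1) * sdNon^2) / df
  t <- (meanEvac - meanNon) / sqrt(sp2 * (1 / nEvac + 1 / nNon))
  r <- t / sqrt(t^2 + df)
  out <- .effectRow("evacuated", outcome, r, t, df)
  out$meanEvac <- meanEvac
  out$sdEvac <- sdEvac
  out$meanNon <- meanNon
  out$sdNon <- sdNon
  out
}
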