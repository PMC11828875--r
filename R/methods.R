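# Accessors and show() methods for the core classes.

#' @describeIn CauseGroup-class print a compact description
#' @param object a \code{CauseGroup}
#' @export
setMethod("show", "CauseGroup", function(object) {
  rr <- apply(object@ranges, 1L, function(r)
    sprintf("%s%02d-%s%02d", r[["letter"]], as.integer(r[["lo"]]),
            r[["letter"]], as.integer(r[["hi"]])))
  cat("CauseGroup '", object@name, "': ", paste(rr, collapse = ", "),
      "\n", sep = "")
})

#' @describeIn DistrictMap-class print a summary
#' @param object a \code{DistrictMap}
#' @export
setMethod("show", "DistrictMap", function(object) {
  cat(sprintf(
    "DistrictMap: %d municipalities -> %d districts (%d with evacuation orders)\n",
    length(object@map), length(object@evacuated), sum(object@evacuated)))
})

#' @describeIn PopulationTable-class print a summary
#' @param object a \code{PopulationTable}
#' @export
setMethod("show", "PopulationTable", function(object) {
  d <- dim(object@counts)
  dn <- dimnames(object@counts)
  cat(sprintf(
    "PopulationTable: %d districts x %d sexes x ages %s-%s x years %s-%s (total %s persons)\n",
    d[1L], d[2L], dn[[3L]][1L], dn[[3L]][d[3L]], dn[[4L]][1L],
    dn[[4L]][d[4L]], format(sum(object@counts), big.mark = ",")))
})

#' @describeIn DeathCountCube-class print a summary
#' @param object a \code{DeathCountCube}
#' @export
setMethod("show", "DeathCountCube", function(object) {
  dn <- dimnames(object@counts)
  cat(sprintf(
    "DeathCountCube: periods [%s]; %d districts; causes [%s]; %s all-cause deaths\n",
    paste(dn[[1L]], collapse = ", "), length(dn[[2L]]),
    paste(setdiff(dn[[5L]], "all"), collapse = ", "),
    format(sum(object@counts[, , , , "all"]), big.mark = ",")))
})

#' @describeIn QSchedule-class print a summary
#' @param object a \code{QSchedule}
#' @export
setMethod("show", "QSchedule", function(object) {
  st <- paste(names(object@stratum), unlist(object@stratum),
              sep = "=", collapse = ", ")
  cat(sprintf("QSchedule (%s): ages 0-%d; flags: %s\n",
    if (nzchar(st)) st else "unlabelled", length(object@q) - 1L,
    paste(sprintf("%s x%d", names(table(object@source)),
                  table(object@source)), collapse = ", ")))
})

#' @describeIn LifeTable-class print head of the table and e_0
#' @param object a \code{LifeTable}
#' @export
setMethod("show", "LifeTable", function(object) {
  st <- paste(names(object@stratum), unlist(object@stratum),
              sep = "=", collapse = ", ")
  cat(sprintf("LifeTable (%s): radix %g, e_0 = %.2f years\n",
    if (nzchar(st)) st else "unlabelled", object@radix,
    object@table$e[1L]))
  print(utils::head(object@table, 3L))
})

#' @describeIn MCResult-class print the estimate and interval
#' @param object a \code{MCResult}
#' @export
setMethod("show", "MCResult", function(object) {
  cat(sprintf("MCResult %s: point %.4g, median %.4g (95%% UI %.4g-%.4g), %d trials\n",
    object@label, object@point, object@median, object@lower, object@upper,
    object@nTrials))
})

#' @describeIn YLLResult-class print the YLL values
#' @param object a \code{YLLResult}
#' @export
setMethod("show", "YLLResult", function(object) {
  cat(sprintf("YLLResult '%s': %s\n", object@cause,
    paste(sprintf("YLL(%s) = %.3f y", names(object@yll), object@yll),
          collapse = ", ")))
})

#' Extract the q_x vector of a QSchedule
#' @param x a [QSchedule-class]
#' @return numeric vector of q_x, names are ages.
#' @export
qValues <- function(x) {
  stopifnot(is(x, "QSchedule"))
  stats::setNames(x@q, seq_along(x@q) - 1L)
}

#' Extract the source flags of a QSchedule
#' @param x a [QSchedule-class]
#' @return character vector of per-age source flags, names are ages.
#' @export
qSource <- function(x) {
  stopifnot(is(x, "QSchedule"))
  stats::setNames(x@source, seq_along(x@q) - 1L)
}

#' Life-table columns as a data.frame
#' @param x a [LifeTable-class]
#' @return data.frame with columns age, q, l, d, L, T, e.
#' @export
lifeTableColumns <- function(x) {
  stopifnot(is(x, "LifeTable"))
  x@table
}

#' Population counts array
#' @param x a [PopulationTable-class]
#' @return the 4-d counts array (district x sex x age x year).
#' @export
populationCounts <- function(x) {
  stopifnot(is(x, "PopulationTable"))
  x@counts
}

#' Death counts array
#' @param x a [DeathCountCube-class]
#' @return the 5-d counts array (period x district x sex x age x cause).
#' @export
deathCounts <- function(x) {
  stopifnot(is(x, "DeathCountCube"))
  x@counts
}

#' Periods of a DeathCountCube
#' @param x a [DeathCountCube-class]
#' @return named list of calendar-year vectors.
#' @export
cubePeriods <- function(x) {
  stopifnot(is(x, "DeathCountCube"))
  x@periods
}

#' Evacuation flags of a DistrictMap
#' @param x a [DistrictMap-class]
#' @return named logical vector, one element per district.
#' @export
evacuationFlags <- function(x) {
  stopifnot(is(x, "DistrictMap"))
  x@evacuated
}

#' Districts of a DistrictMap
#' @param x a [DistrictMap-class]
#' @return character vector of district ids.
#' @export
districtIds <- function(x) {
  stopifnot(is(x, "DistrictMap"))
  names(x@evacuated)
}

#' Monte Carlo trial values
#' @param x a [MCResult-class]
#' @return numeric vector of per-trial values.
#' @export
mcTrials <- function(x) {
  stopifnot(is(x, "MCResult"))
  x@trials
}

#' Uncertainty interval of an MCResult
#' @param x a [MCResult-class]
#' @return named numeric: point, median, lower, upper.
#' @export
mcInterval <- function(x) {
  stopifnot(is(x, "MCResult"))
  c(point = x@point, median = x@median, lower = x@lower, upper = x@upper)
}

#' YLL values of a YLLResult
#' @param x a [YLLResult-class]
#' @return named numeric vector of YLL (years) by age.
#' @export
yllValues <- function(x) {
  stopifnot(is(x, "YLLResult"))
  x@yll
}
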