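# Readers/writers for the pipeline's tabular formats and the aggregation
# of individual death records into the period x district x sex x age x
# cause count cube.

.SEXES <- c("male", "female")
.AGES <- 0:110

#' Construct a district map
#'
#' @param map named character vector mapping municipality code -> district
#'   id.
#' @param evacuatedDistricts character vector of district ids that include
#'   evacuation-ordered areas.
#' @return a [DistrictMap-class].
#' @export
districtMap <- function(map, evacuatedDistricts = character()) {
  map <- vapply(map, as.character, "")
  ids <- sort(unique(unname(map)))
  evac <- stats::setNames(ids %in% as.character(evacuatedDistricts), ids)
  new("DistrictMap", map = map, evacuated = evac)
}

#' Read a district map from YAML
#'
#' Expected keys: \code{municipalities} (mapping municipality code ->
#' district id) and \code{evacuated} (list of district ids under
#' evacuation orders).
#'
#' @param path YAML file path.
#' @return a [DistrictMap-class].
#' @export
readDistrictMap <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  y <- yaml::read_yaml(path)
  if (is.null(y$municipalities))
    stop("district map YAML needs a 'municipalities' mapping")
  districtMap(unlist(y$municipalities),
              as.character(unlist(y$evacuated)))
}

#' Write a district map to YAML
#' @param x a [DistrictMap-class]
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeDistrictMap <- function(x, path) {
  stopifnot(is(x, "DistrictMap"))
  yaml::write_yaml(list(
    municipalities = as.list(x@map),
    evacuated = as.list(names(x@evacuated)[x@evacuated])), path)
  invisible(path)
}

#' Read individual death records from CSV
#'
#' The file must have a header with the configured columns (defaults:
#' sex, age, icd10, municipality, date with ISO-8601 dates). Records
#' whose death year falls in \code{excludedYears} are dropped and counted.
#'
#' @param path CSV file path.
#' @param schema named character vector mapping the canonical fields
#'   (sex, age, icd10, municipality, date) to column names in the file.
#' @param excludedYears integer years whose deaths are dropped (default
#'   2011, the disaster year).
#' @param studyYears optional integer vector; when given, record years
#'   outside it are a validity violation in strict mode.
#' @param strict logical; TRUE (default) errors on any invalid row, FALSE
#'   skips invalid rows and counts them.
#' @return data.frame with columns sex (factor male/female), age (integer),
#'   icd10, municipality, date (Date), year (integer). Attribute
#'   \code{"log"} carries counts of rows read / excluded-year rows dropped /
#'   invalid rows skipped.
#' @export
readDeathRecords <- function(path,
    schema = c(sex = "sex", age = "age", icd10 = "icd10",
               municipality = "municipality", date = "date"),
    excludedYears = 2011L, studyYears = NULL, strict = TRUE) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  miss <- setdiff(unname(schema), names(raw))
  if (length(miss))
    stop(sprintf("schema error: missing column(s) %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  n <- nrow(raw)
  if (n == 0L) {
    out <- data.frame(sex = factor(character(), levels = .SEXES),
      age = integer(), icd10 = character(), municipality = character(),
      date = as.Date(character()), year = integer())
    attr(out, "log") <- c(read = 0L, excluded = 0L, skipped = 0L)
    return(out)
  }
  sex <- tolower(raw[[schema[["sex"]]]])
  age <- suppressWarnings(as.integer(raw[[schema[["age"]]]]))
  icd <- toupper(trimws(raw[[schema[["icd10"]]]]))
  muni <- raw[[schema[["municipality"]]]]
  date <- suppressWarnings(as.Date(raw[[schema[["date"]]]]))
  year <- as.integer(format(date, "%Y"))

  bad <- !(sex %in% .SEXES) | is.na(age) | age < 0L | age > 110L |
    !grepl(.icdPattern, icd) | is.na(date)
  if (!is.null(studyYears)) bad <- bad | (!is.na(year) & !(year %in% studyYears))
  if (any(bad)) {
    lines <- which(bad) + 1L # header is line 1
    if (strict)
      stop(sprintf("invalid death record at line %d of %s", lines[1L], path),
           call. = FALSE)
  }
  excl <- !bad & year %in% excludedYears
  keep <- !bad & !excl
  out <- data.frame(sex = factor(sex[keep], levels = .SEXES),
    age = age[keep], icd10 = icd[keep], municipality = muni[keep],
    date = date[keep], year = year[keep], stringsAsFactors = FALSE)
  attr(out, "log") <- c(read = n, excluded = sum(excl), skipped = sum(bad))
  out
}

#' Write death records to CSV
#' @param records data.frame as returned by [readDeathRecords()] or
#'   [simulateDeaths()].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeDeathRecords <- function(records, path) {
  utils::write.csv(
    records[, c("sex", "age", "icd10", "municipality", "date")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a population table from CSV
#'
#' Columns: district, sex, age, year, count. Duplicate (district, sex,
#' age, year) keys and negative counts are errors. Ages not present in
#' the file are zero-filled up to 110.
#'
#' @param path CSV file path.
#' @return a [PopulationTable-class].
#' @export
readPopulation <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("district", "sex", "age", "year", "count")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop(sprintf("population file missing column(s) %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (any(raw$count < 0))
    stop("negative population count", call. = FALSE)
  key <- paste(raw$district, raw$sex, raw$age, raw$year)
  if (anyDuplicated(key))
    stop(sprintf("duplicated population cell: %s", key[duplicated(key)][1L]),
         call. = FALSE)
  districts <- sort(unique(as.character(raw$district)))
  years <- sort(unique(raw$year))
  a <- array(0, dim = c(length(districts), 2L, length(.AGES), length(years)),
    dimnames = list(district = districts, sex = .SEXES,
                    age = as.character(.AGES), year = as.character(years)))
  idx <- cbind(match(as.character(raw$district), districts),
               match(tolower(raw$sex), .SEXES),
               match(raw$age, .AGES),
               match(raw$year, years))
  if (anyNA(idx)) stop("unrecognised sex or age outside 0-110", call. = FALSE)
  a[idx] <- raw$count
  new("PopulationTable", counts = a)
}

#' Write a population table to CSV
#'
#' Inverse of [readPopulation()]: zero cells are omitted, so a write/read
#' round trip reproduces the same cells.
#'
#' @param pop a [PopulationTable-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writePopulation <- function(pop, path) {
  stopifnot(is(pop, "PopulationTable"))
  df <- as.data.frame.table(pop@counts, responseName = "count",
                            stringsAsFactors = FALSE)
  df <- df[df$count > 0, ]
  df$age <- as.integer(df$age)
  df$year <- as.integer(df$year)
  df <- df[order(df$district, df$sex, df$age, df$year), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Aggregate death records into a count cube
#'
#' Each in-period record increments exactly one (period, district, sex,
#' age) cell of the "all" margin and of exactly one cause bucket: the
#' first matching cause group, else "other". Records dated outside every
#' period are dropped and counted in the attribute \code{"log"}.
#'
#' @param records data.frame of death records (see [readDeathRecords()]).
#' @param dmap a [DistrictMap-class]; every record municipality must
#'   appear in it.
#' @param periods named list of disjoint integer year vectors.
#' @param groups list of [CauseGroup-class] objects (default
#'   [defaultCauseGroups()]); validated to be disjoint.
#' @return a [DeathCountCube-class]; attribute \code{"log"} holds the
#'   number of out-of-period records dropped.
#' @export
aggregateDeaths <- function(records, dmap, periods,
                            groups = defaultCauseGroups()) {
  stopifnot(is(dmap, "DistrictMap"))
  validateDisjointGroups(groups)
  yrs <- unlist(periods)
  if (anyDuplicated(yrs)) stop("periods must be disjoint", call. = FALSE)
  unknown <- setdiff(unique(records$municipality), names(dmap@map))
  if (length(unknown))
    stop(sprintf("unknown municipality code '%s'", unknown[1L]),
         call. = FALSE)

  periodOf <- rep(NA_character_, nrow(records))
  for (p in names(periods))
    periodOf[records$year %in% periods[[p]]] <- p
  dropped <- sum(is.na(periodOf))
  keep <- !is.na(periodOf)

  causeNames <- vapply(groups, function(g) g@name, "")
  buckets <- c(causeNames, "other", "all")
  districts <- names(dmap@evacuated)
  a <- array(0L, dim = c(length(periods), length(districts), 2L,
                         length(.AGES), length(buckets)),
    dimnames = list(period = names(periods), district = districts,
                    sex = .SEXES, age = as.character(.AGES),
                    cause = buckets))
  if (any(keep)) {
    rec <- records[keep, ]
    bucket <- .assignCauseBucket(rec$icd10, groups)
    idx <- cbind(match(periodOf[keep], names(periods)),
                 match(unname(dmap@map[rec$municipality]), districts),
                 as.integer(rec$sex),
                 match(rec$age, .AGES))
    for (b in c(unique(bucket))) {
      sub <- idx[bucket == b, , drop = FALSE]
      tb <- table(apply(sub, 1L, paste, collapse = "\r"))
      pos <- do.call(rbind, strsplit(names(tb), "\r", fixed = TRUE))
      storage.mode(pos) <- "integer"
      a[cbind(pos, match(b, buckets))] <- as.integer(tb)
    }
    tbAll <- table(apply(idx, 1L, paste, collapse = "\r"))
    posAll <- do.call(rbind, strsplit(names(tbAll), "\r", fixed = TRUE))
    storage.mode(posAll) <- "integer"
    a[cbind(posAll, match("all", buckets))] <- as.integer(tbAll)
  }
  out <- new("DeathCountCube", counts = a, periods = periods)
  attr(out, "log") <- c(outOfPeriod = dropped)
  out
}
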