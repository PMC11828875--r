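# ICD-10 cause-group construction and matching.

.icdPattern <- "^[A-Z][0-9]{2}(\\.[0-9A-Z]{1,2})?$"

#' Construct an ICD-10 cause group from range strings
#'
#' @param name group label, e.g. "heart".
#' @param ranges character vector of inclusive 3-character ranges written
#'   as \code{"I05-I09"} or single codes \code{"I46"}. Both endpoints of a
#'   range must share the same letter.
#' @return a [CauseGroup-class].
#' @examples
#' causeGroup("cerebrovascular", "I60-I69")
#' @export
causeGroup <- function(name, ranges) {
  parse1 <- function(s) {
    s <- gsub("\\s", "", s)
    parts <- strsplit(s, "-", fixed = TRUE)[[1L]]
    if (length(parts) == 1L) parts <- c(parts, parts)
    if (length(parts) != 2L || !all(grepl("^[A-Z][0-9]{2}$", parts)))
      stop(sprintf("malformed ICD-10 range '%s'", s), call. = FALSE)
    if (substr(parts[1L], 1L, 1L) != substr(parts[2L], 1L, 1L))
      stop(sprintf("range '%s' spans more than one letter", s),
           call. = FALSE)
    data.frame(letter = substr(parts[1L], 1L, 1L),
               lo = as.integer(substr(parts[1L], 2L, 3L)),
               hi = as.integer(substr(parts[2L], 2L, 3L)))
  }
  new("CauseGroup", name = name,
      ranges = do.call(rbind, lapply(ranges, parse1)))
}

#' The four major cause-of-death groups
#'
#' Heart diseases (I05-I09, I20-I25, I30-I52), cerebrovascular disease
#' (I60-I69), pneumonia (J12-J18) and all cancers (C00-C97).
#'
#' @return named list of four [CauseGroup-class] objects, in the order
#'   heart, cerebrovascular, pneumonia, cancer.
#' @export
defaultCauseGroups <- function() {
  list(
    heart = causeGroup("heart", c("I05-I09", "I20-I25", "I30-I52")),
    cerebrovascular = causeGroup("cerebrovascular", "I60-I69"),
    pneumonia = causeGroup("pneumonia", "J12-J18"),
    cancer = causeGroup("cancer", "C00-C97"))
}

#' Test ICD-10 codes for membership in a cause group
#'
#' Only the 3-character root (letter plus two digits) is compared; any
#' subcode after a dot is ignored.
#'
#' @param icd10 character vector of ICD-10 codes such as "I21" or "C34.1".
#' @param group a [CauseGroup-class].
#' @return logical vector, TRUE where the code's root falls in any of the
#'   group's ranges.
#' @examples
#' matchCauseGroup(c("I21", "I10", "C34.1"), defaultCauseGroups()$heart)
#' @export
matchCauseGroup <- function(icd10, group) {
  stopifnot(is(group, "CauseGroup"))
  if (any(!grepl(.icdPattern, icd10)))
    stop(sprintf("malformed ICD-10 code '%s'",
                 icd10[!grepl(.icdPattern, icd10)][1L]), call. = FALSE)
  letter <- substr(icd10, 1L, 1L)
  num <- as.integer(substr(icd10, 2L, 3L))
  out <- logical(length(icd10))
  for (i in seq_len(nrow(group@ranges))) {
    r <- group@ranges[i, ]
    out <- out | (letter == r$letter & num >= r$lo & num <= r$hi)
  }
  out
}

# First matching group name, else "other". Vectorised over codes.
.assignCauseBucket <- function(icd10, groups) {
  out <- rep("other", length(icd10))
  for (g in rev(groups)) # reverse so earlier groups overwrite (first wins)
    out[matchCauseGroup(icd10, g)] <- g@name
  out
}

#' Check that a list of cause groups is pairwise disjoint
#'
#' @param groups list of [CauseGroup-class] objects.
#' @return invisibly TRUE; errors naming the first code claimed by two
#'   groups otherwise.
#' @export
validateDisjointGroups <- function(groups) {
  codes <- as.vector(outer(LETTERS, sprintf("%02d", 0:99), paste0))
  hits <- vapply(groups, function(g) matchCauseGroup(codes, g),
                 logical(length(codes)))
  n <- rowSums(hits)
  if (any(n > 1L))
    stop(sprintf("code %s belongs to more than one cause group",
                 codes[n > 1L][1L]), call. = FALSE)
  invisible(TRUE)
}
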