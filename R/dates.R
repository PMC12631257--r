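#' Parse FAERS-style partial dates
#'
#' FAERS date fields come in three widths: `YYYY`, `YYYYMM` and `YYYYMMDD`.
#' A full 8-digit value parses to a [Date]; partial values carry a usable
#' year but no calendar day, so [faers_date()] returns `NA` for them while
#' [faers_year()] still recovers the year. Anything else (empty strings,
#' non-numeric junk) is `NA` throughout.
#'
#' @param x character or numeric vector of raw date fields.
#' @return [faers_date()]: a `Date` vector; [faers_year()]: an integer vector.
#' @examples
#' faers_date(c("20200321", "202003", "2020", ""))
#' faers_year(c("20200321", "202003", "2020", ""))
#' @export
faers_date <- function(x) {
  x <- trimws(as.character(x))
  x[!grepl("^[0-9]{8}$", x)] <- NA_character_
  as.Date(x, format = "%Y%m%d")
}

#' @rdname faers_date
#' @export
faers_year <- function(x) {
  x <- trimws(as.character(x))
  yr <- rep(NA_integer_, length(x))
  ok <- grepl("^[0-9]{4}([0-9]{2}([0-9]{2})?)?$", x)
  # the year is usable even when the month/day part is junk
  yr[ok] <- as.integer(substr(x[ok], 1, 4))
  yr
}

#' Calendar quarters
#'
#' Quarters are written `"2016Q4"`. [parse_quarter()] converts that notation
#' to a single sortable index (4 * year + quarter); [date_quarter()] assigns
#' a date to its quarter index.
#'
#' @param q character vector like `"2016Q4"`.
#' @param date a `Date` vector.
#' @return integer quarter indices.
#' @export
parse_quarter <- function(q) {
  q <- toupper(trimws(q))
  m <- regmatches(q, regexec("^([0-9]{4})[ -]?Q([1-4])$", q))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("invalid quarter string(s): ", paste(q[bad], collapse = ", "),
         " (expected e.g. \"2016Q4\")", call. = FALSE)
  }
  vapply(m, function(p) 4L * as.integer(p[2]) + as.integer(p[3]), 1L)
}

#' @rdname parse_quarter
#' @export
date_quarter <- function(date) {
  yr <- as.integer(format(date, "%Y"))
  qt <- (as.integer(format(date, "%m")) - 1L) %/% 3L + 1L
  4L * yr + qt
}
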