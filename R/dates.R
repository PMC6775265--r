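#' Partial calendar dates
#'
#' Spontaneous reports routinely carry incomplete dates (year only, or year
#' and month). The package stores every date as an ISO-8601 *prefix* string:
#' `"2014"`, `"2014-03"` or `"2014-03-21"`, so the completeness level travels
#' with the value. Only fully complete (`YMD`) dates are usable for
#' time-to-onset arithmetic.
#'
#' @param x character vector of ISO-8601 prefixes (or `NA`).
#' @return `date_completeness()`: one of `"Y"`, `"YM"`, `"YMD"` or `NA` per
#'   element. `parse_partial_date()`: the input, with malformed values set to
#'   `NA`. `partial_date_to_date()`: a `Date` vector, `NA` wherever the value
#'   is not a valid complete date.
#' @examples
#' date_completeness(c("2014", "2014-03", "2014-03-21", NA))
#' partial_date_to_date("2014-03-21")
#' @name partial-dates
NULL

#' @rdname partial-dates
#' @export
date_completeness <- function(x) {
  out <- rep(NA_character_, length(x))
  out[grepl("^\\d{4}$", x)] <- "Y"
  out[grepl("^\\d{4}-\\d{2}$", x)] <- "YM"
  out[grepl("^\\d{4}-\\d{2}-\\d{2}$", x)] <- "YMD"
  out
}

#' @rdname partial-dates
#' @export
parse_partial_date <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & x == ""] <- NA_character_
  ok <- is.na(x) | !is.na(date_completeness(x))
  # a YMD prefix must also be a real calendar date
  ymd <- !is.na(x) & !is.na(date_completeness(x)) & date_completeness(x) == "YMD"
  ok[ymd] <- !is.na(as.Date(x[ymd], format = "%Y-%m-%d"))
  x[!ok] <- NA_character_
  x
}

#' @rdname partial-dates
#' @export
partial_date_to_date <- function(x) {
  d <- rep(as.Date(NA), length(x))
  full <- !is.na(x) & !is.na(date_completeness(x)) & date_completeness(x) == "YMD"
  d[full] <- as.Date(x[full], format = "%Y-%m-%d")
  d
}

#' Convert compact FAERS-style date codes to ISO prefixes
#'
#' FAERS quarterly files encode dates as `YYYYMMDD`, `YYYYMM` or `YYYY`
#' numerics. Values that do not fit any of these shapes (or name an
#' impossible calendar day) become `NA`.
#'
#' @param x character or numeric vector of compact date codes.
#' @return character vector of ISO-8601 prefixes.
#' @export
faers_date_to_iso <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x) | x == ""] <- NA_character_
  out <- rep(NA_character_, length(x))
  y <- grepl("^\\d{4}$", x)
  ym <- grepl("^\\d{6}$", x)
  ymd <- grepl("^\\d{8}$", x)
  out[y] <- x[y]
  out[ym] <- paste0(substr(x[ym], 1, 4), "-", substr(x[ym], 5, 6))
  out[ymd] <- paste0(
    substr(x[ymd], 1, 4), "-", substr(x[ymd], 5, 6), "-", substr(x[ymd], 7, 8)
  )
  parse_partial_date(out)
}
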