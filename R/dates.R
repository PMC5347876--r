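#' Length of an algorithm "month" in days
#'
#' Follow-up months are periods of 30.4 days anchored at study entry, so that
#' twelve of them make up approximately one calendar year.
#'
#' @export
MONTH_DAYS <- 30.4

#' Month index of a date relative to study entry
#'
#' Maps a calendar date to the zero-based follow-up month it falls in, where a
#' month is a 30.4-day period anchored at the entry date. The entry date itself
#' maps to month 0.
#'
#' @param date Date (or vector of Dates) on or after `entry_date`.
#' @param entry_date Date of entry into follow-up (first attendance marker).
#' @return Integer vector of month indices (`floor(days / 30.4)`).
#' @examples
#' month_index(as.Date("2004-01-05") + 122, as.Date("2004-01-05")) # 4
#' @export
month_index <- function(date, entry_date) {
  date <- as.Date(date)
  entry_date <- as.Date(entry_date)
  days <- as.numeric(date - entry_date)
  if (any(days < 0)) {
    stop("event date precedes entry date: month index undefined", call. = FALSE)
  }
  as.integer(floor(days / MONTH_DAYS))
}

#' Calendar date of a follow-up month's midpoint
#'
#' Used when evaluating time-updated covariates: month `m` spans
#' `(m, m + 1] * 30.4` days after entry, and its midpoint sits at
#' `(m + 0.5) * 30.4` days.
#'
#' @param m Integer month index (>= 0).
#' @param entry_date Date of entry into follow-up.
#' @return Date vector.
#' @export
month_midpoint <- function(m, entry_date) {
  as.Date(entry_date) + round((m + 0.5) * MONTH_DAYS)
}

# Internal: parse ISO dates strictly, returning NA for malformed input without
# warnings (callers collect NA positions into row-level error reports).
parse_iso_date <- function(x) {
  out <- as.Date(rep(NA_character_, length(x)))
  ok <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  # reject impossible dates like 2004-02-31 that strptime rolls over
  roundtrip <- !is.na(out) & format(out, "%Y-%m-%d") != x
  out[which(ok)[is.na(out[ok])]] <- NA
  out[roundtrip] <- NA
  out
}

# Internal: birth dates may arrive at year-month precision ("1970-06"); impute
# the mid-month day so time-updated age strata are unbiased.
parse_birth_date <- function(x) {
  ym <- !is.na(x) & grepl("^\\d{4}-\\d{2}$", x)
  x[ym] <- paste0(x[ym], "-15")
  parse_iso_date(x)
}
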