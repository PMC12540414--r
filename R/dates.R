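#' Parse SRS-style compact dates with precision flags
#'
#' FAERS and JADER carry dates as 8-digit (`YYYYMMDD`), 6-digit (`YYYYMM`)
#' or 4-digit (`YYYY`) strings. Partial dates are anchored at the first day
#' of the month/year and flagged with their precision so that downstream
#' date arithmetic (deduplication windows, time-to-onset) can refuse
#' anything coarser than day precision. Any other form becomes `NA`.
#'
#' @param x Character (or numeric) vector of raw date fields.
#' @return A tibble with columns `date` (`Date`) and `precision`
#'   (`"day"`, `"month"`, `"year"` or `NA`).
#' @examples
#' parse_srs_date(c("20200131", "202001", "2020", "", "31-01-2020"))
#' @export
parse_srs_date <- function(x) {
  x <- stringr::str_trim(as.character(x))
  x[is.na(x)] <- ""
  digits <- stringr::str_detect(x, "^[0-9]+$")
  nch <- nchar(x)

  out <- tibble::tibble(
    date = as.Date(rep(NA_character_, length(x))),
    precision = rep(NA_character_, length(x))
  )

  day8 <- digits & nch == 8L
  if (any(day8)) {
    d <- suppressWarnings(as.Date(x[day8], format = "%Y%m%d"))
    out$date[day8] <- d
    out$precision[day8] <- ifelse(is.na(d), NA_character_, "day")
  }
  mon6 <- digits & nch == 6L
  if (any(mon6)) {
    d <- suppressWarnings(as.Date(paste0(x[mon6], "01"), format = "%Y%m%d"))
    out$date[mon6] <- d
    out$precision[mon6] <- ifelse(is.na(d), NA_character_, "month")
  }
  yr4 <- digits & nch == 4L
  if (any(yr4)) {
    d <- suppressWarnings(as.Date(paste0(x[yr4], "0101"), format = "%Y%m%d"))
    out$date[yr4] <- d
    out$precision[yr4] <- ifelse(is.na(d), NA_character_, "year")
  }
  out
}

#' Format a date back to the compact SRS form implied by its precision
#'
#' Inverse of [parse_srs_date()]: day precision renders as `YYYYMMDD`,
#' month as `YYYYMM`, year as `YYYY`, missing as the empty string.
#'
#' @param date `Date` vector.
#' @param precision Character vector (`"day"`, `"month"`, `"year"`, `NA`).
#' @return Character vector.
#' @export
format_srs_date <- function(date, precision) {
  out <- character(length(date))
  ok <- !is.na(date) & !is.na(precision)
  fmt <- c(day = "%Y%m%d", month = "%Y%m", year = "%Y")
  for (p in names(fmt)) {
    sel <- ok & precision == p
    out[sel] <- format(date[sel], fmt[[p]])
  }
  out
}
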