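#' Compute time to onset from therapy start to event
#'
#' Time to onset (TTO) is the number of days from the start of the
#' earliest primary-suspect therapy entry for the target drug to the
#' event date. Only day-precision dates enter the arithmetic: partial
#' (month/year) or absent dates are excluded, as are negative differences
#' (event documented before the therapy start). Same-day onsets are
#' mapped to 0.5 days so the records stay on the positive support the
#' Weibull model requires.
#'
#' @param reports Case-report tibble, normally after
#'   [match_target_drug()] and [filter_primary_suspect()]. If the
#'   `matched` flag is absent, all primary-suspect drug entries anchor the
#'   start date.
#' @param quiet Suppress the exclusion-tally message.
#' @return A list with `records` (tibble `case_id, days`) and
#'   `exclusions` (tibble `reason, n`).
#' @export
compute_tto <- function(reports, quiet = FALSE) {
  n <- nrow(reports)
  reason <- rep(NA_character_, n)
  days <- rep(NA_real_, n)

  start_info <- lapply(reports$drugs, function(d) {
    sel <- d$role == "primary_suspect"
    if ("matched" %in% names(d)) sel <- sel & d$matched
    d <- d[sel, ]
    ok <- !is.na(d$start_date) & !is.na(d$start_precision) &
      d$start_precision == "day"
    any_start <- any(!is.na(d$start_date))
    if (!any(ok)) {
      list(date = as.Date(NA),
           reason = if (any_start) "start_date_imprecise" else "no_start_date")
    } else {
      list(date = min(d$start_date[ok]), reason = NA_character_)
    }
  })

  for (i in seq_len(n)) {
    ev <- reports$event_date[i]
    ep <- reports$event_precision[i]
    if (is.na(ev)) {
      reason[i] <- "no_event_date"
    } else if (is.na(ep) || ep != "day") {
      reason[i] <- "event_date_imprecise"
    } else if (!is.na(start_info[[i]]$reason)) {
      reason[i] <- start_info[[i]]$reason
    } else {
      dd <- as.numeric(ev - start_info[[i]]$date)
      if (dd < 0) {
        reason[i] <- "negative_tto"
      } else {
        days[i] <- if (dd == 0) 0.5 else dd
      }
    }
  }

  keep <- is.na(reason)
  records <- tibble::tibble(case_id = reports$case_id[keep],
                            days = days[keep])
  tally <- table(factor(reason[!keep],
                        levels = c("no_event_date", "event_date_imprecise",
                                   "no_start_date", "start_date_imprecise",
                                   "negative_tto")))
  exclusions <- tibble::tibble(reason = names(tally), n = as.integer(tally))
  if (!quiet) {
    message(sprintf("compute_tto: %d usable record(s), %d excluded",
                    nrow(records), sum(exclusions$n)))
  }
  list(records = records, exclusions = exclusions)
}

#' Summarize onset-time chronology
#'
#' Order statistics plus binned counts of onset days. Default bin edges
#' (30/60/90/180/365 days) match the 1-month, 6-month and 1-year
#' landmarks conventionally reported for onset chronology.
#'
#' @param records Tibble with a `days` column (from [compute_tto()]).
#' @param bin_edges Increasing positive break points.
#' @return List with `stats` (one-row tibble `n, median, q1, q3, min,
#'   max`) and `bins` (tibble `bin, n, pct`). Empty input returns
#'   zero-row tables flagged with attribute `empty`.
#' @export
tto_summary <- function(records, bin_edges = c(30, 60, 90, 180, 365)) {
  days <- records$days
  if (!length(days)) {
    out <- list(stats = tibble::tibble(n = 0L),
                bins = tibble::tibble(bin = character(), n = integer(),
                                      pct = double()))
    attr(out, "empty") <- TRUE
    return(out)
  }
  q <- quantile(days, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  stats <- tibble::tibble(n = length(days), median = q[2], q1 = q[1],
                          q3 = q[3], min = min(days), max = max(days))
  breaks <- c(0, bin_edges, Inf)
  labels <- c(paste0("<=", bin_edges[1]),
              paste0(head(bin_edges, -1) + 1, "-", bin_edges[-1]),
              paste0(">", bin_edges[length(bin_edges)]))
  cuts <- cut(days, breaks = breaks, labels = labels, include.lowest = TRUE)
  tab <- table(cuts)
  bins <- tibble::tibble(bin = names(tab), n = as.integer(tab),
                         pct = 100 * as.integer(tab) / length(days))
  list(stats = stats, bins = bins)
}

#' Kaplan-Meier estimate of the onset-time distribution
#'
#' Product-limit estimate via [survival::survfit()]. Spontaneous-report
#' onset records carry no censoring (every record is an observed event),
#' so the curve equals one minus the empirical CDF; the estimator is kept
#' for its conventional presentation (counts at risk, step curve).
#'
#' @param records Tibble with a `days` column.
#' @return Tibble of class `km_curve` with columns `time, n_risk,
#'   n_event, surv`.
#' @export
km_estimate <- function(records) {
  if (!nrow(records)) stop("km_estimate: no records", call. = FALSE)
  fit <- survival::survfit(
    survival::Surv(records$days, rep(1, nrow(records))) ~ 1)
  out <- tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                        n_event = fit$n.event, surv = fit$surv)
  class(out) <- c("km_curve", class(out))
  out
}
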