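round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Descriptive demographic summary of a case series
#'
#' Counts and percentages (denominator = total cases, percentages rounded
#' half-up to one decimal) for sex, age group, weight bins, reporter
#' type, outcomes and the top-3 reporting countries, mirroring the
#' descriptive table conventionally reported for SRS case series. A case
#' can contribute to several outcome rows, so outcome percentages need
#' not sum to 100.
#'
#' @param reports Deduplicated, target-filtered case-report tibble.
#' @return Tibble `section, level, n, pct`; empty input yields a zero-row
#'   table.
#' @export
demographic_summary <- function(reports) {
  n_total <- nrow(reports)
  if (n_total == 0L) {
    return(tibble::tibble(section = character(), level = character(),
                          n = integer(), pct = double()))
  }
  row <- function(section, level, n) {
    tibble::tibble(section = section, level = level, n = as.integer(n),
                   pct = round_half_up(100 * n / n_total, 1))
  }
  count_levels <- function(x, levels) {
    tab <- table(factor(x, levels = levels))
    tibble::tibble(level = names(tab), n = as.integer(tab))
  }

  sex <- count_levels(reports$sex, srs_sexes)

  age_levels <- c(setdiff(faers_age_bins, "unknown"),
                  setdiff(jader_age_bins, "unknown"), "unknown")
  age_levels <- age_levels[age_levels %in% unique(reports$age_group) |
                             age_levels == "unknown"]
  age <- count_levels(reports$age_group, age_levels)

  wt <- reports$weight_kg
  wt_bin <- dplyr::case_when(
    is.na(wt) ~ "missing", wt < 50 ~ "<50", wt <= 100 ~ "50-100",
    TRUE ~ ">100")
  weight <- count_levels(wt_bin, c("<50", "50-100", ">100", "missing"))

  reporter <- count_levels(reports$reporter_type, srs_reporters)

  oc <- unlist(reports$outcomes, use.names = FALSE)
  outcome <- count_levels(oc, srs_outcomes)

  ctab <- sort(table(reports$country), decreasing = TRUE)
  # deterministic alphabetical tie-break within equal counts
  ord <- order(-as.integer(ctab), names(ctab))
  top3 <- utils::head(tibble::tibble(level = names(ctab)[ord],
                                     n = as.integer(ctab)[ord]), 3)

  dplyr::bind_rows(
    row("total", "cases", n_total),
    row("sex", sex$level, sex$n),
    row("age", age$level, age$n),
    row("weight_kg", weight$level, weight$n),
    row("reporter", reporter$level, reporter$n),
    row("outcome", outcome$level, outcome$n),
    row("country_top3", top3$level, top3$n)
  )
}

#' Read a user-supplied MedDRA-style mapping table
#'
#' Three delimited columns `pt, hlt, soc`. The licensed dictionary itself
#' is never bundled; any table with unique PTs works.
#'
#' @param path File path.
#' @param delim Field delimiter (default tab).
#' @return Tibble `pt, hlt, soc`.
#' @export
read_meddra_mapping <- function(path, delim = "\t") {
  m <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  require_columns(m, c("pt", "hlt", "soc"), path)
  if (anyDuplicated(m$pt)) {
    stop("mapping table has duplicated pt entries", call. = FALSE)
  }
  m[c("pt", "hlt", "soc")]
}

#' Case-level System Organ Class distribution
#'
#' Counts, per SOC, the cases reporting at least one PT mapping to it
#' (descending). PTs absent from the mapping are tallied under
#' `"unmapped"`.
#'
#' @param reports Case-report tibble.
#' @param meddra_mapping Tibble `pt, hlt, soc` ([read_meddra_mapping()]).
#' @param quiet Suppress the unmapped-PT message.
#' @return Tibble `soc, n` in descending order.
#' @export
soc_distribution <- function(reports, meddra_mapping, quiet = FALSE) {
  soc_of <- stats::setNames(meddra_mapping$soc, meddra_mapping$pt)
  per_case <- lapply(reports$events, function(pts) {
    s <- unname(soc_of[pts])
    s[is.na(s)] <- "unmapped"
    unique(s)
  })
  n_unmapped_pts <- length(setdiff(unlist(reports$events, use.names = FALSE),
                                   meddra_mapping$pt))
  if (!quiet && n_unmapped_pts > 0L) {
    message(sprintf("soc_distribution: %d distinct PT(s) not in the mapping",
                    n_unmapped_pts))
  }
  tab <- sort(table(unlist(per_case, use.names = FALSE)), decreasing = TRUE)
  tibble::tibble(soc = names(tab), n = as.integer(tab))
}

#' Aggregate signal counts under High-Level Terms
#'
#' The data table behind hierarchical signal presentations: for each HLT
#' (and its SOC), the number of consensus-flagged PTs and the range of
#' their RORs.
#'
#' @param signals Output of [signal_table()].
#' @param meddra_mapping Tibble `pt, hlt, soc`.
#' @return Tibble `hlt, soc, n_signals, ror_min, ror_max`, descending by
#'   `n_signals`; unmapped PTs aggregate under `hlt = "unmapped"`.
#' @export
hlt_rollup <- function(signals, meddra_mapping) {
  sig <- signals[signals$is_signal, c("pt", "ror")]
  joined <- dplyr::left_join(sig, meddra_mapping, by = "pt")
  joined$hlt[is.na(joined$hlt)] <- "unmapped"
  joined$soc[is.na(joined$soc)] <- "unmapped"
  joined |>
    dplyr::group_by(.data$hlt, .data$soc) |>
    dplyr::summarise(n_signals = dplyr::n(),
                     ror_min = min(.data$ror), ror_max = max(.data$ror),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_signals), .data$hlt)
}
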