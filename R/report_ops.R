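#' Default fentanyl search patterns
#'
#' Generic, chemical and major brand names used to identify fentanyl
#' reports in the DRUG tables, including the Japanese generic and brand
#' terms used for JADER. Matching is whole-token (see
#' [match_target_drug()]), so congeners such as sufentanil, alfentanil or
#' remifentanil never match.
#'
#' @return Character vector of literal name patterns.
#' @export
fentanyl_patterns <- function() {
  c("fentanyl", "fentanil", "sublimaze", "duragesic", "actiq",
    "fentora", "abstral", "subsys", "lazanda", "ionsys",
    "フェンタニル",    # fentanyl (ja)
    "フェンタネスト")  # fentanest (ja)
}

#' Keep the most recent version of each case
#'
#' Spontaneous-report databases ship every received version of a report;
#' analyses must count each case once. For each `case_id` the report with
#' the latest `version_date` (receipt date) is retained; ties are broken
#' by the lexicographically greatest `row_id` so the result is
#' deterministic. Input order is otherwise preserved, and the number of
#' removed versions is reported.
#'
#' @param reports Case-report tibble with `version_date` present on every
#'   row.
#' @param quiet Suppress the removal-count message.
#' @return The deduplicated tibble, with attribute `removed` = number of
#'   dropped rows.
#' @export
deduplicate_reports <- function(reports, quiet = FALSE) {
  if (nrow(reports) == 0L) {
    attr(reports, "removed") <- 0L
    return(reports)
  }
  stopifnot(!anyNA(reports$version_date))
  ord <- order(reports$case_id,
               as.integer(reports$version_date),
               reports$row_id,
               method = "radix", decreasing = c(FALSE, TRUE, TRUE))
  keep_rows <- ord[!duplicated(reports$case_id[ord])]
  keep <- sort(keep_rows)  # preserve input order among survivors
  out <- reports[keep, ]
  removed <- nrow(reports) - nrow(out)
  if (!quiet && removed > 0L) {
    message(sprintf("deduplicate_reports: removed %d superseded version(s), %d cases retained",
                    removed, nrow(out)))
  }
  attr(out, "removed") <- removed
  out
}

#' Flag reports containing a target drug
#'
#' A drug entry matches when the pattern's letter-token sequence occurs as
#' a consecutive run of tokens in the case-folded drug name, where a token
#' is a maximal run of letters. This is deliberately stricter than plain
#' substring search: `"FENTANYL CITRATE"` and `"DURAGESIC-100"` match the
#' fentanyl patterns, while the congeners `"SUFENTANIL"` and
#' `"ALFENTANIL"` do not, so they cannot contaminate the case series.
#'
#' @param reports Case-report tibble.
#' @param name_patterns Non-empty character vector of literal names;
#'   defaults to [fentanyl_patterns()].
#' @return `reports` with a logical `matched` column added per drug entry
#'   (inside the `drugs` list-column) and a case-level logical `matched`
#'   column.
#' @export
match_target_drug <- function(reports, name_patterns = fentanyl_patterns()) {
  if (length(name_patterns) == 0L) {
    stop("name_patterns must be a non-empty list of drug names", call. = FALSE)
  }
  pattern_tokens <- lapply(name_patterns, name_tokens)
  if (any(lengths(pattern_tokens) == 0L)) {
    stop("every name pattern must contain at least one letter", call. = FALSE)
  }

  all_names <- unique(unlist(lapply(reports$drugs, function(d) d$name_raw),
                             use.names = FALSE))
  matched_lookup <- vapply(all_names, function(nm) {
    toks <- name_tokens(nm)
    any(vapply(pattern_tokens, tokens_contain, logical(1), haystack = toks))
  }, logical(1))

  reports$drugs <- lapply(reports$drugs, function(d) {
    d$matched <- if (nrow(d)) unname(matched_lookup[d$name_raw]) else logical()
    d
  })
  reports$matched <- vapply(reports$drugs,
                            function(d) any(d$matched), logical(1))
  reports
}

name_tokens <- function(x) {
  toks <- regmatches(x, gregexpr("\\p{L}+", x, perl = TRUE))[[1]]
  tolower(toks)
}

tokens_contain <- function(needle, haystack) {
  k <- length(needle)
  n <- length(haystack)
  if (k == 0L || n < k) return(FALSE)
  if (k == 1L) return(needle %in% haystack)
  for (i in seq_len(n - k + 1L)) {
    if (all(haystack[i:(i + k - 1L)] == needle)) return(TRUE)
  }
  FALSE
}

#' Restrict to reports where the target drug is a primary suspect
#'
#' Keeps exactly those reports in which at least one *matched* drug entry
#' carries the primary-suspect role code, focusing the case series on
#' reports with the strongest causal attribution.
#'
#' @param reports Output of [match_target_drug()].
#' @return Filtered case-report tibble.
#' @export
filter_primary_suspect <- function(reports) {
  if (!"matched" %in% names(reports)) {
    stop("run match_target_drug() before filter_primary_suspect()",
         call. = FALSE)
  }
  keep <- vapply(reports$drugs, function(d) {
    any(d$matched & d$role == "primary_suspect")
  }, logical(1))
  reports[keep, ]
}

#' Drop reports with no adverse-event entries
#'
#' Reports that end up with an empty event list after the table join carry
#' no analyzable information and are excluded from all downstream counts.
#'
#' @param reports Case-report tibble.
#' @param quiet Suppress the tally message.
#' @return Filtered tibble with attribute `dropped_eventless`.
#' @export
drop_eventless <- function(reports, quiet = FALSE) {
  keep <- lengths(reports$events) > 0L
  out <- reports[keep, ]
  dropped <- sum(!keep)
  if (!quiet && dropped > 0L) {
    message(sprintf("drop_eventless: excluded %d report(s) with no events",
                    dropped))
  }
  attr(out, "dropped_eventless") <- dropped
  out
}
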