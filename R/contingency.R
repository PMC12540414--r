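#' Build per-event 2x2 contingency tables
#'
#' For every preferred term (PT) occurring in either report set, counts
#' the classic disproportionality 2x2 cells against a rest-of-database
#' comparator: `a` target cases with the PT, `b` target cases without it,
#' `c` comparator cases with it, `d` comparator cases without it.
#' Counting is case-level: a case contributes at most 1 to `a` (or `c`)
#' per PT no matter how many times the PT is repeated among its event
#' rows, so the margins `a + b` (total target cases) and `c + d` (total
#' comparator cases) are identical for every PT of one run.
#'
#' @param target_reports Deduplicated reports forming the target-drug
#'   series.
#' @param comparator_reports Deduplicated rest-of-database reports;
#'   must share no `case_id` with `target_reports`.
#' @return A tibble with columns `pt, a, b, c, d, n`, one row per PT,
#'   sorted by descending `a`.
#' @export
build_contingency <- function(target_reports, comparator_reports) {
  overlap <- intersect(target_reports$case_id, comparator_reports$case_id)
  if (length(overlap)) {
    stop("target and comparator sets overlap on ", length(overlap),
         " case_id(s); they must be disjoint", call. = FALSE)
  }
  n_target <- nrow(target_reports)
  n_comp <- nrow(comparator_reports)

  count_pts <- function(events) {
    pts <- unlist(lapply(events, unique), use.names = FALSE)
    if (!length(pts)) return(tibble::tibble(pt = character(), n = integer()))
    tab <- table(pts)
    tibble::tibble(pt = names(tab), n = as.integer(tab))
  }
  ta <- count_pts(target_reports$events)
  ca <- count_pts(comparator_reports$events)

  out <- dplyr::full_join(
    dplyr::rename(ta, a = "n"), dplyr::rename(ca, c = "n"), by = "pt"
  ) |>
    dplyr::mutate(
      a = dplyr::coalesce(.data$a, 0L),
      c = dplyr::coalesce(.data$c, 0L),
      b = n_target - .data$a,
      d = n_comp - .data$c,
      n = n_target + n_comp
    ) |>
    dplyr::select("pt", "a", "b", "c", "d", "n") |>
    dplyr::arrange(dplyr::desc(.data$a), .data$pt)
  out
}

#' Sex-stratified event counts within the target series
#'
#' Counts female and male target-drug cases with and without a PT;
#' unknown-sex cases are dropped (with a tally) since they cannot enter a
#' female-versus-male comparison.
#'
#' @param target_reports Target-drug case series.
#' @param pt Preferred term to count.
#' @param quiet Suppress the dropped-case message.
#' @return One-row tibble `pt, a_f, b_f, a_m, b_m, n_unknown_sex,
#'   evaluable` — `evaluable` is `FALSE` when no sexed case exists.
#' @export
stratify_by_sex <- function(target_reports, pt, quiet = FALSE) {
  has_pt <- vapply(target_reports$events, function(e) pt %in% e, logical(1))
  sex <- target_reports$sex
  n_unknown <- sum(sex == "unknown")
  if (!quiet && n_unknown > 0L) {
    message(sprintf("stratify_by_sex: dropped %d case(s) of unknown sex",
                    n_unknown))
  }
  a_f <- sum(sex == "female" & has_pt)
  b_f <- sum(sex == "female" & !has_pt)
  a_m <- sum(sex == "male" & has_pt)
  b_m <- sum(sex == "male" & !has_pt)
  tibble::tibble(pt = pt, a_f = a_f, b_f = b_f, a_m = a_m, b_m = b_m,
                 n_unknown_sex = n_unknown,
                 evaluable = (a_f + b_f + a_m + b_m) > 0L)
}

#' Write a contingency table set as an audit TSV
#'
#' @param tables Output of [build_contingency()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_contingency_tsv <- function(tables, path) {
  readr::write_tsv(tables[c("pt", "a", "b", "c", "d")], path)
  invisible(path)
}
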