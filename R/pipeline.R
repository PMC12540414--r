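#' Per-drug observed/expected cell set for hyperparameter fitting
#'
#' The gamma-Poisson shrinker hyperparameters are estimated on the full
#' drug-by-event cell set of a run. Cases are grouped by their first
#' primary-suspect drug name; for each (drug, PT) pair the observed count
#' `a` is the case-level count and the expectation is the independence
#' value `E = n_drug * n_pt / N` from the same margins.
#'
#' @param reports Deduplicated case-report tibble.
#' @return Tibble `drug, pt, a, e` over the complete grid of observed
#'   primary-suspect drugs by observed PTs (zero cells included — they
#'   inform the low-rate mixture component).
#' @export
drug_event_cells <- function(reports) {
  ps_drug <- vapply(reports$drugs, function(d) {
    i <- which(d$role == "primary_suspect")
    if (length(i)) d$name_raw[i[1]] else "(no primary suspect)"
  }, character(1))
  n_cases <- nrow(reports)
  pair <- tibble::tibble(
    drug = rep(ps_drug, lengths(reports$events)),
    pt = unlist(reports$events, use.names = FALSE)
  ) |>
    dplyr::count(.data$drug, .data$pt, name = "a")
  n_drug <- table(ps_drug)
  n_pt <- table(unlist(reports$events, use.names = FALSE))
  grid <- tidyr::expand_grid(drug = names(n_drug), pt = names(n_pt))
  grid <- dplyr::left_join(grid, pair, by = c("drug", "pt"))
  grid$a <- dplyr::coalesce(grid$a, 0L)
  grid$e <- as.integer(n_drug[grid$drug]) * as.integer(n_pt[grid$pt]) / n_cases
  grid
}

#' Run the full signal-detection and onset pipeline
#'
#' Orchestrates parse, deduplication, target matching, primary-suspect
#' restriction, contingency tables against the rest-of-database
#' comparator, the four disproportionality statistics with consensus and
#' Bonferroni control, sex-subgroup odds ratios, time-to-onset
#' summarization with the Weibull hazard fit, and the demographic
#' summary. Every stage logs its input/output counts; given `seed`, the
#' whole run is deterministic.
#'
#' @param faers_paths Named vector with entries `demo, drug, reac` and
#'   optionally `outc, ther` (as returned in `$faers` by
#'   [simulate_reports()]), or `NULL`.
#' @param jader_paths Named vector with entries `demo, drug, reac`, or
#'   `NULL`. Exactly one of `faers_paths`/`jader_paths`/`reports` must be
#'   given.
#' @param reports A pre-parsed case-report tibble (alternative input).
#' @param name_patterns Target-drug patterns ([fentanyl_patterns()]).
#' @param thresholds Consensus thresholds ([signal_thresholds()]).
#' @param priors BCPNN priors ([bcpnn_priors()]).
#' @param bonferroni Apply the Bonferroni multiplicity guard.
#' @param sex_min_a Minimum target case count for a PT to enter the
#'   sex-subgroup analysis.
#' @param bin_edges Chronology bin edges in days.
#' @param gof_reps Bootstrap replicates for the Weibull goodness of fit.
#' @param meddra_mapping Optional `pt, hlt, soc` tibble for the SOC
#'   distribution and HLT rollup.
#' @param out_dir Optional directory to write the TSV artifact set into.
#' @param jader_encoding Encoding passed to [parse_jader()].
#' @param seed Seed applied at the start of the run.
#' @param quiet Suppress stage messages.
#' @return A list with `log` (stage counts), `signals`, `contingency`,
#'   `sex_subgroup`, `tto` (records + exclusions), `tto_summary`,
#'   `weibull`, `demographics`, and (with a mapping) `soc`, `hlt`.
#' @export
run_pipeline <- function(faers_paths = NULL, jader_paths = NULL,
                         reports = NULL,
                         name_patterns = fentanyl_patterns(),
                         thresholds = signal_thresholds(),
                         priors = bcpnn_priors(),
                         bonferroni = TRUE,
                         sex_min_a = 10,
                         bin_edges = c(30, 60, 90, 180, 365),
                         gof_reps = 200,
                         meddra_mapping = NULL,
                         out_dir = NULL,
                         jader_encoding = "CP932",
                         seed = 1L,
                         quiet = FALSE) {
  set.seed(seed)
  inputs <- sum(!is.null(faers_paths), !is.null(jader_paths),
                !is.null(reports))
  if (inputs != 1L) {
    stop("supply exactly one of faers_paths, jader_paths or reports",
         call. = FALSE)
  }
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(log, name, n) {
    say("run_pipeline: %-22s n = %d", name, n)
    dplyr::bind_rows(log, tibble::tibble(stage = name, n = as.integer(n)))
  }

  if (!is.null(faers_paths)) {
    reports <- parse_faers_quarter(faers_paths[["demo"]],
                                   faers_paths[["drug"]],
                                   faers_paths[["reac"]],
                                   faers_paths[["outc"]],
                                   faers_paths[["ther"]], quiet = quiet)
  } else if (!is.null(jader_paths)) {
    reports <- parse_jader(jader_paths[["demo"]], jader_paths[["drug"]],
                           jader_paths[["reac"]],
                           encoding = jader_encoding, quiet = quiet)
  }
  log <- stage(NULL, "parsed", nrow(reports))

  reports <- deduplicate_reports(reports, quiet = quiet)
  log <- stage(log, "deduplicated", nrow(reports))

  reports <- drop_eventless(reports, quiet = quiet)
  log <- stage(log, "with_events", nrow(reports))

  reports <- match_target_drug(reports, name_patterns)
  log <- stage(log, "matched", sum(reports$matched))

  target <- filter_primary_suspect(reports)
  log <- stage(log, "primary_suspect", nrow(target))
  comparator <- reports[!reports$case_id %in% target$case_id, ]
  log <- stage(log, "comparator", nrow(comparator))

  tables <- build_contingency(target, comparator)
  cells <- drug_event_cells(reports)
  gps_hyper <- gps_fit(cells)
  signals <- signal_table(tables, priors = priors, gps_params = gps_hyper,
                          thresholds = thresholds, bonferroni = bonferroni)
  log <- stage(log, "pts_evaluated", nrow(signals))
  log <- stage(log, "consensus_signals", sum(signals$is_signal))

  sex_pts <- signals$pt[signals$a >= sex_min_a]
  sex_subgroup <- dplyr::bind_rows(lapply(sex_pts, function(pt) {
    st <- stratify_by_sex(target, pt, quiet = TRUE)
    if (!st$evaluable || any(c(st$a_f + st$b_f, st$a_m + st$b_m) == 0)) {
      return(NULL)
    }
    dplyr::bind_cols(st[c("pt", "a_f", "b_f", "a_m", "b_m")], sex_ror(st))
  }))

  tto <- compute_tto(target, quiet = quiet)
  log <- stage(log, "tto_records", nrow(tto$records))
  tto_sum <- tto_summary(tto$records, bin_edges)
  wfit <- if (nrow(tto$records) >= 10) {
    weibull_fit(tto$records, gof_reps = gof_reps)
  }

  demographics <- demographic_summary(target)
  soc <- hlt <- NULL
  if (!is.null(meddra_mapping)) {
    soc <- soc_distribution(target, meddra_mapping, quiet = quiet)
    hlt <- hlt_rollup(signals, meddra_mapping)
  }

  out <- list(log = log, signals = signals, contingency = tables,
              gps_params = gps_hyper, sex_subgroup = sex_subgroup,
              tto = tto, tto_summary = tto_sum, weibull = wfit,
              demographics = demographics, soc = soc, hlt = hlt)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_signal_tsv(signals, file.path(out_dir, "signals.tsv"))
    write_contingency_tsv(tables, file.path(out_dir, "contingency.tsv"))
    readr::write_tsv(tto$records, file.path(out_dir, "tto_records.tsv"))
    if (!is.null(wfit)) write_weibull_tsv(wfit, file.path(out_dir, "weibull.tsv"))
    readr::write_tsv(demographics, file.path(out_dir, "demographics.tsv"))
    if (!is.null(sex_subgroup) && nrow(sex_subgroup)) {
      readr::write_tsv(sex_subgroup, file.path(out_dir, "sex_subgroup.tsv"))
    }
    if (!is.null(soc)) readr::write_tsv(soc, file.path(out_dir, "soc.tsv"))
    readr::write_tsv(log, file.path(out_dir, "run_log.tsv"))
  }
  out
}
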