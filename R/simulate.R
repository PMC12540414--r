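#' Configuration for the synthetic-report generator
#'
#' Defines the study conditions emulated by [simulate_reports()]: a
#' spontaneous-report database in which a configurable share of cases
#' carries the target drug as primary suspect, each preferred term occurs
#' independently with probability `base_prob * RR * sexRR` (relative
#' risks apply to target cases; sex rate ratios multiply the female rate
#' among target cases), onset times follow a Weibull law, and realistic
#' missingness and duplicate report versions are injected last.
#'
#' Defaults emulate the published fentanyl case series: a 100-term event
#' vocabulary with geometrically tapering baseline rates (about 2.4
#' events per case), five terms with injected relative risk 10, one term
#' with a 2-fold female excess, the FAERS-fitted onset law
#' Weibull(shape 0.43, scale 111.77 days), missingness rates mirroring
#' the published demographic table (12% sex, 48% age, 72% weight
#' unknown), and 10% duplicated report versions.
#'
#' @param n_cases Number of distinct cases.
#' @param n_background_drugs Number of comparator primary-suspect drugs.
#' @param event_vocabulary Tibble `pt, base_prob` of per-case baseline
#'   occurrence probabilities.
#' @param target_share Probability a case is a target-drug case.
#' @param rr_map Named numeric vector: PT -> relative risk among target
#'   cases.
#' @param sex_split Probability a case is female.
#' @param sex_rr_map Named numeric vector: PT -> female:male rate ratio
#'   among target cases (applied as a multiplier on the female rate).
#' @param tto_shape,tto_scale Weibull onset law (shape; scale in days).
#' @param missing_rates Named list of missingness probabilities for
#'   `sex`, `weight`, `start_date`, `event_date`, and the probability
#'   `date_precision` that a present date is degraded to month precision.
#' @param duplicate_rate Fraction of cases emitted twice with distinct
#'   version dates.
#' @param seed Integer seed; the same seed yields byte-identical files.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 20000,
                       n_background_drugs = 20,
                       event_vocabulary = default_event_vocabulary(),
                       target_share = 0.05,
                       rr_map = c(PT_015 = 10, PT_025 = 10, PT_035 = 10,
                                  PT_045 = 10, PT_055 = 10),
                       sex_split = 0.5,
                       sex_rr_map = c(PT_008 = 2),
                       tto_shape = 0.43, tto_scale = 111.77,
                       missing_rates = list(sex = 0.12, weight = 0.72,
                                            start_date = 0.25,
                                            event_date = 0.25,
                                            date_precision = 0.05),
                       duplicate_rate = 0.1,
                       seed = 1L) {
  stopifnot(n_cases >= 1, n_background_drugs >= 1,
            all(c("pt", "base_prob") %in% names(event_vocabulary)),
            all(event_vocabulary$base_prob >= 0 & event_vocabulary$base_prob <= 1),
            target_share >= 0, target_share <= 1,
            all(rr_map > 0), sex_split >= 0, sex_split <= 1,
            all(sex_rr_map > 0), tto_shape > 0, tto_scale > 0,
            duplicate_rate >= 0, duplicate_rate < 1)
  stopifnot(all(names(rr_map) %in% event_vocabulary$pt),
            all(names(sex_rr_map) %in% event_vocabulary$pt))
  rates <- unlist(missing_rates)
  stopifnot(all(rates >= 0 & rates <= 1))
  structure(list(
    n_cases = as.integer(n_cases),
    n_background_drugs = as.integer(n_background_drugs),
    event_vocabulary = event_vocabulary,
    target_share = target_share, rr_map = rr_map,
    sex_split = sex_split, sex_rr_map = sex_rr_map,
    tto_shape = tto_shape, tto_scale = tto_scale,
    missing_rates = missing_rates, duplicate_rate = duplicate_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default 100-term event vocabulary with tapering baseline rates
#'
#' @return Tibble `pt, base_prob` with `base_prob = 0.12 * 0.95^(i-1)`.
#' @export
default_event_vocabulary <- function() {
  tibble::tibble(pt = sprintf("PT_%03d", 1:100),
                 base_prob = 0.12 * 0.95^(0:99))
}

#' Generate FAERS-style and JADER-style report files with known truth
#'
#' Draws a full synthetic case series under `config`, records the ground
#' truth, and emits the identical case series in both source dialects
#' (under `dir/faers/` and `dir/jader/`) plus a delimited truth file.
#' The generation is fully reproducible: the same seed yields
#' byte-identical files.
#'
#' @param config A [sim_config()] object.
#' @param dir Output directory.
#' @return A list with `faers` and `jader` (named file-path vectors),
#'   `truth` (a `sim_truth` list: `cases`, `pt_counts`, `duplicates`,
#'   `config`) and `truth_path`.
#' @export
simulate_reports <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_cases
  vocab <- config$event_vocabulary
  k <- nrow(vocab)

  case_id <- as.character(10000000 + seq_len(n))
  target <- runif(n) < config$target_share
  female <- runif(n) < config$sex_split
  sex_true <- ifelse(female, "female", "male")

  # per-case event probabilities: base * RR (target) * sexRR (target female)
  rr <- rep(1, k); rr[match(names(config$rr_map), vocab$pt)] <- config$rr_map
  srr <- rep(1, k)
  srr[match(names(config$sex_rr_map), vocab$pt)] <- config$sex_rr_map
  p <- matrix(vocab$base_prob, n, k, byrow = TRUE)
  p[target, ] <- p[target, , drop = FALSE] *
    matrix(rr, sum(target), k, byrow = TRUE)
  tf <- target & female
  p[tf, ] <- p[tf, , drop = FALSE] * matrix(srr, sum(tf), k, byrow = TRUE)
  if (any(p > 1)) {
    warning("event probability exceeded 1 after multipliers; clamped")
    p <- pmin(p, 1)
  }
  events_mat <- matrix(runif(n * k), n, k) < p
  # validated reports carry at least one event: force a weighted draw
  none <- which(rowSums(events_mat) == 0L)
  for (i in none) {
    events_mat[i, sample.int(k, 1L, prob = p[i, ])] <- TRUE
  }
  events <- lapply(seq_len(n), function(i) vocab$pt[events_mat[i, ]])

  # onset law and dates (fixed 2004-2025 study window)
  onset_days <- rweibull(n, shape = config$tto_shape, scale = config$tto_scale)
  start_date <- as.Date("2004-01-01") + sample.int(7120L, n, replace = TRUE) - 1L
  event_date_true <- start_date + round(onset_days)
  version_date <- event_date_true + sample(10:100, n, replace = TRUE)

  # drug entries: target cases carry a primary-suspect fentanyl-pattern
  # name; comparator cases a background primary suspect; 40% of cases add
  # one concomitant background drug
  fent_names <- c("FENTANYL", "FENTANYL CITRATE", "DURAGESIC", "ACTIQ")
  bg_names <- paste0("BGDRUG", sprintf("%02d", seq_len(config$n_background_drugs)))
  ps_name <- ifelse(target,
                    fent_names[sample.int(length(fent_names), n, replace = TRUE)],
                    bg_names[sample.int(length(bg_names), n, replace = TRUE)])
  has_conc <- runif(n) < 0.4
  conc_name <- bg_names[sample.int(length(bg_names), n, replace = TRUE)]

  mr <- config$missing_rates
  start_missing <- runif(n) < mr$start_date
  start_coarse <- runif(n) < mr$date_precision
  ps_start <- start_date
  ps_start[start_missing] <- NA
  ps_prec <- ifelse(start_missing, NA_character_,
                    ifelse(start_coarse, "month", "day"))
  # month-precision dates are anchored at the first of the month
  coarse <- !start_missing & start_coarse
  ps_start[coarse] <- as.Date(format(ps_start[coarse], "%Y-%m-01"))

  ev_missing <- runif(n) < mr$event_date
  ev_coarse <- runif(n) < mr$date_precision
  event_date <- event_date_true
  event_date[ev_missing] <- NA
  ev_prec <- ifelse(ev_missing, NA_character_,
                    ifelse(ev_coarse, "month", "day"))
  ecoarse <- !ev_missing & ev_coarse
  event_date[ecoarse] <- as.Date(format(event_date[ecoarse], "%Y-%m-01"))

  idx <- c(seq_len(n), which(has_conc))
  flat <- tibble::tibble(
    case = idx,
    name_raw = c(ps_name, conc_name[has_conc]),
    role = c(rep("primary_suspect", n), rep("concomitant", sum(has_conc))),
    start_date = c(ps_start, rep(as.Date(NA), sum(has_conc))),
    start_precision = c(ps_prec, rep(NA_character_, sum(has_conc)))
  )
  flat <- flat[order(flat$case), ]
  dsplit <- split(flat[-1], factor(flat$case, levels = seq_len(n)))
  drugs <- lapply(dsplit, tibble::as_tibble)

  # demographics with masking
  sex_emit <- ifelse(runif(n) < mr$sex, "unknown", sex_true)
  age_group <- sample(faers_age_bins, n, replace = TRUE,
                      prob = c(0.007, 0.007, 0.008, 0.377, 0.103, 0.017, 0.48))
  weight_kg <- ifelse(runif(n) < mr$weight, NA_real_,
                      round(exp(rnorm(n, log(70), 0.25)), 1))
  reporter <- sample(c("consumer", "physician", "pharmacist",
                       "other_health_professional", "unknown"),
                     n, replace = TRUE,
                     prob = c(0.453, 0.236, 0.129, 0.041, 0.141))
  country <- sample(c("United States", "Japan", "France", "Germany",
                      "United Kingdom"),
                    n, replace = TRUE,
                    prob = c(0.746, 0.054, 0.030, 0.090, 0.080))
  om <- cbind(death = runif(n) < 0.24, hospitalization = runif(n) < 0.135,
              life_threatening = runif(n) < 0.015,
              disability = runif(n) < 0.006, other = runif(n) < 0.603)
  outcomes <- lapply(seq_len(n), function(i) colnames(om)[om[i, ]])

  # duplicate versions: exactly floor(rate * n) cases emitted twice
  n_dup <- as.integer(floor(config$duplicate_rate * n))
  dup_rows <- sort(sample.int(n, n_dup))
  suffix <- rep("1", n)
  suffix[dup_rows] <- "2"  # the retained (latest) version

  reports <- tibble::tibble(
    case_id = case_id,
    row_id = paste0(case_id, suffix),
    version_date = version_date,
    source = "FAERS",
    sex = sex_emit,
    age_group = age_group,
    weight_kg = weight_kg,
    country = country,
    reporter_type = reporter,
    outcomes = outcomes,
    drugs = drugs,
    events = events,
    event_date = event_date,
    event_precision = ev_prec
  )
  if (n_dup > 0) {
    dup <- reports[dup_rows, ]
    dup$row_id <- paste0(dup$case_id, "1")
    dup$version_date <- dup$version_date - sample(30:200, n_dup, replace = TRUE)
    reports <- dplyr::bind_rows(reports, dup)
  }

  # ground truth (pre-masking, one row per distinct case)
  truth_cases <- tibble::tibble(
    case_id = case_id,
    arm = ifelse(target, "target", "comparator"),
    sex_true = sex_true,
    onset_days = onset_days,
    duplicated = seq_len(n) %in% dup_rows,
    pts = vapply(events, paste, character(1), collapse = ";")
  )
  grp <- interaction(truth_cases$arm, sex_true, drop = FALSE)
  pt_counts <- dplyr::bind_rows(lapply(split(seq_len(n), grp), function(rows) {
    if (!length(rows)) return(NULL)
    tibble::tibble(pt = vocab$pt,
                   arm = truth_cases$arm[rows[1]],
                   sex = sex_true[rows[1]],
                   n = colSums(events_mat[rows, , drop = FALSE]))
  }))

  truth <- structure(list(cases = truth_cases, pt_counts = pt_counts,
                          duplicates = case_id[dup_rows], config = config),
                     class = "sim_truth")

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  faers_paths <- write_faers(reports, file.path(dir, "faers"))
  jader_model <- reports
  jader_model$source <- "JADER"
  jader_paths <- write_jader(jader_model, file.path(dir, "jader"))
  truth_path <- file.path(dir, "truth.csv")
  readr::write_csv(truth_cases, truth_path)

  list(faers = faers_paths, jader = jader_paths, truth = truth,
       truth_path = truth_path)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Synthetic SRS ground truth\n")
  cat(sprintf("  %d cases (%d target, %d comparator), %d duplicated\n",
              nrow(x$cases), sum(x$cases$arm == "target"),
              sum(x$cases$arm == "comparator"), length(x$duplicates)))
  invisible(x)
}
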