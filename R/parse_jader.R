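#' Parse JADER-style CSV tables into case reports
#'
#' Reads the comma-delimited demo/drug/reac tables keyed by the case
#' identification number and returns the same nested case-report model as
#' [parse_faers_quarter()], with `source = "JADER"`. Field values (sex,
#' reporter, drug role, outcome) are Japanese codes and are normalized
#' onto the package's canonical vocabulary; drug and event names are
#' treated as opaque strings and never translated.
#'
#' Expected columns: demo `case_id, sex, age, weight, reporter,
#' report_date, event_date, outcome`; drug `case_id, drug_seq, role,
#' drug_name, start_date`; reac `case_id, pt` (extra columns pass
#' through unharmed; only `case_id` and the listed mandatory ones are
#' required).
#'
#' @param demo_path,drug_path,reac_path Paths to the three CSV tables.
#' @param encoding Text encoding of the files. Defaults to the Japanese
#'   legacy encoding the distribution files use; override with `"UTF-8"`
#'   for re-encoded copies.
#' @param quiet Suppress the row-count message.
#' @return A case-report tibble (see [parse_faers_quarter()] for columns).
#'   `row_id` is `case_id` plus the demo row number, so repeated versions
#'   of one case remain distinguishable until [deduplicate_reports()].
#' @export
parse_jader <- function(demo_path, drug_path, reac_path,
                        encoding = "CP932", quiet = FALSE) {
  loc <- readr::locale(encoding = encoding)
  read_csv_enc <- function(path) {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    locale = loc, progress = FALSE, show_col_types = FALSE)
  }
  demo <- read_csv_enc(demo_path)
  require_columns(demo, c("case_id", "report_date"), demo_path)
  drug <- read_csv_enc(drug_path)
  require_columns(drug, c("case_id", "role", "drug_name"), drug_path)
  reac <- read_csv_enc(reac_path)
  require_columns(reac, c("case_id", "pt"), reac_path)

  if (nrow(demo) == 0L) {
    warning("demo file '", demo_path, "' has no records; returning 0 reports")
    return(empty_report_tbl())
  }

  vd <- parse_srs_date(demo$report_date)
  ed <- parse_srs_date(demo[["event_date"]] %||% rep("", nrow(demo)))
  row_id <- sprintf("%s#%04d", demo$case_id, seq_len(nrow(demo)))

  outcome_raw <- stringr::str_trim(demo[["outcome"]] %||% rep("", nrow(demo)))
  outcomes <- lapply(outcome_raw, function(x) {
    if (is.na(x) || x == "") character() else
      if (x == jader_death_code) "death" else "other"
  })

  reports <- tibble::tibble(
    case_id = as.character(demo$case_id),
    row_id = row_id,
    version_date = vd$date,
    source = "JADER",
    sex = code_to_enum(demo[["sex"]], jader_sex_codes),
    age_group = bin_age_jader(jader_decade(demo[["age"]])),
    weight_kg = jader_weight(demo[["weight"]]),
    country = "Japan",
    reporter_type = code_to_enum(demo[["reporter"]], jader_reporter_codes),
    event_date = ed$date,
    event_precision = ed$precision,
    outcomes = outcomes
  )

  # per-case entry tables are keyed by case_id (JADER has no primaryid);
  # every demo row of a case receives the full entry set
  sd <- parse_srs_date(drug[["start_date"]] %||% rep("", nrow(drug)))
  drug_tbl <- tibble::tibble(
    case_id = as.character(drug$case_id),
    name_raw = as.character(drug$drug_name),
    role = code_to_enum(drug$role, jader_role_codes),
    start_date = sd$date,
    start_precision = sd$precision
  )
  reac_tbl <- tibble::tibble(case_id = as.character(reac$case_id),
                             pt = as.character(reac$pt))

  dsplit <- split(drug_tbl[-1], factor(drug_tbl$case_id,
                                       levels = unique(reports$case_id)))
  esplit <- split(reac_tbl$pt, factor(reac_tbl$case_id,
                                      levels = unique(reports$case_id)))
  reports$drugs <- lapply(reports$case_id, function(id) {
    x <- dsplit[[id]]
    if (is.null(x)) empty_drug_entry() else tibble::as_tibble(x)
  })
  reports$events <- lapply(reports$case_id, function(id) {
    unique(as.character(esplit[[id]] %||% character()))
  })

  reports <- reports[c("case_id", "row_id", "version_date", "source", "sex",
                       "age_group", "weight_kg", "country", "reporter_type",
                       "outcomes", "drugs", "events", "event_date",
                       "event_precision")]
  if (!quiet) {
    message(sprintf(
      "parse_jader: %d demo rows, %d drug rows, %d reac rows -> %d reports",
      nrow(demo), nrow(drug), nrow(reac), nrow(reports)))
  }
  reports
}

jader_decade <- function(x) {
  x <- stringr::str_trim(as.character(x %||% character()))
  out <- rep(NA_real_, length(x))
  out[!is.na(x) & x == "10歳未満"] <- 0  # under 10
  dec <- stringr::str_match(x, "^([0-9]+)歳代$")[, 2]  # e.g. 30歳代
  out[!is.na(dec)] <- as.numeric(dec[!is.na(dec)])
  out
}

jader_weight <- function(x) {
  w <- suppressWarnings(as.numeric(stringr::str_remove_all(
    as.character(x %||% character()), "kg|キロ")))
  ifelse(!is.na(w) & w > 0, w, NA_real_)
}
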