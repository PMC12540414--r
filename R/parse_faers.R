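#' Parse one quarter of FAERS-style ASCII files into case reports
#'
#' Reads the `$`-delimited quarterly tables (DEMO, DRUG, REAC, and
#' optionally OUTC and THER), joins them on `primaryid`, and returns one
#' row per DEMO record in the common nested case-report model shared with
#' [parse_jader()]. Therapy start dates are attached to their drug entries
#' via `dsg_drug_seq`. Dates are parsed with [parse_srs_date()], so partial
#' dates survive with a precision flag instead of being silently coerced.
#'
#' The returned tibble is *not yet deduplicated*: FAERS ships every
#' received version of a case, and [deduplicate_reports()] is the next
#' pipeline step.
#'
#' @param demo_path,drug_path,reac_path Paths to the DEMO, DRUG and REAC
#'   files (mandatory).
#' @param outc_path,ther_path Optional paths to the OUTC and THER files.
#' @param quiet Suppress the row-count message.
#' @return A case-report tibble with one row per DEMO row; columns
#'   `case_id`, `row_id` (primaryid), `version_date`, `source`, `sex`,
#'   `age_group`, `weight_kg`, `country`, `reporter_type`, `outcomes`
#'   (list of character), `drugs` (list of tibbles with `name_raw`, `role`,
#'   `start_date`, `start_precision`), `events` (list of character PTs),
#'   `event_date`, `event_precision`.
#' @export
parse_faers_quarter <- function(demo_path, drug_path, reac_path,
                                outc_path = NULL, ther_path = NULL,
                                quiet = FALSE) {
  demo <- read_dollar(demo_path)
  require_columns(demo, c("primaryid", "caseid", "fda_dt"), demo_path)
  drug <- read_dollar(drug_path)
  require_columns(drug, c("primaryid", "drug_seq", "role_cod", "drugname"),
                  drug_path)
  reac <- read_dollar(reac_path)
  require_columns(reac, c("primaryid", "pt"), reac_path)

  outc <- if (!is.null(outc_path)) {
    x <- read_dollar(outc_path)
    require_columns(x, c("primaryid", "outc_cod"), outc_path)
    x
  }
  ther <- if (!is.null(ther_path)) {
    x <- read_dollar(ther_path)
    require_columns(x, c("primaryid", "dsg_drug_seq", "start_dt"), ther_path)
    x
  }

  if (nrow(demo) == 0L) {
    warning("DEMO file '", demo_path, "' has no records; returning 0 reports")
    return(empty_report_tbl())
  }

  vd <- parse_srs_date(demo$fda_dt)
  ed <- parse_srs_date(demo[["event_dt"]] %||% rep("", nrow(demo)))

  age_years <- faers_age_years(demo[["age"]], demo[["age_cod"]])
  weight <- faers_weight_kg(demo[["wt"]], demo[["wt_cod"]])

  reports <- tibble::tibble(
    case_id = as.character(demo$caseid),
    row_id = as.character(demo$primaryid),
    version_date = vd$date,
    source = "FAERS",
    sex = faers_sex(demo[["sex"]]),
    age_group = bin_age_faers(age_years),
    weight_kg = weight,
    country = blank_to_unknown(demo[["reporter_country"]]),
    reporter_type = code_to_enum(demo[["occp_cod"]], faers_reporter_codes),
    event_date = ed$date,
    event_precision = ed$precision
  )

  # drug entries with therapy starts joined by (primaryid, drug_seq)
  drug_tbl <- tibble::tibble(
    row_id = as.character(drug$primaryid),
    drug_seq = as.character(drug$drug_seq),
    name_raw = as.character(drug$drugname),
    role = code_to_enum(drug$role_cod, faers_role_codes)
  )
  if (!is.null(ther)) {
    sd <- parse_srs_date(ther$start_dt)
    ther_tbl <- tibble::tibble(
      row_id = as.character(ther$primaryid),
      drug_seq = as.character(ther$dsg_drug_seq),
      start_date = sd$date,
      start_precision = sd$precision
    ) |>
      dplyr::distinct(.data$row_id, .data$drug_seq, .keep_all = TRUE)
    drug_tbl <- dplyr::left_join(drug_tbl, ther_tbl,
                                 by = c("row_id", "drug_seq"))
  } else {
    drug_tbl$start_date <- as.Date(NA)
    drug_tbl$start_precision <- NA_character_
  }
  drug_tbl$drug_seq <- NULL

  reac_tbl <- tibble::tibble(
    row_id = as.character(reac$primaryid),
    pt = as.character(reac$pt)
  )
  outc_tbl <- if (!is.null(outc)) {
    tibble::tibble(
      row_id = as.character(outc$primaryid),
      outcome = code_to_enum(outc$outc_cod, faers_outcome_codes)
    )
  } else {
    tibble::tibble(row_id = character(), outcome = character())
  }

  reports <- attach_entries(reports, drug_tbl, reac_tbl, outc_tbl)

  if (!quiet) {
    message(sprintf(
      "parse_faers_quarter: %d DEMO rows, %d DRUG rows, %d REAC rows -> %d reports",
      nrow(demo), nrow(drug), nrow(reac), nrow(reports)))
  }
  reports
}

# ---- internals --------------------------------------------------------

read_dollar <- function(path) {
  readr::read_delim(path, delim = "$", trim_ws = TRUE,
                    col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE, show_col_types = FALSE)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("file '", path, "' is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

faers_sex <- function(x) {
  x <- toupper(stringr::str_trim(x %||% character()))
  dplyr::case_when(x == "M" ~ "male", x == "F" ~ "female", TRUE ~ "unknown")
}

faers_age_years <- function(age, age_cod) {
  a <- suppressWarnings(as.numeric(age %||% NA))
  cod <- toupper(stringr::str_trim(age_cod %||% rep("YR", length(a))))
  cod[cod == "" | is.na(cod)] <- "YR"
  mult <- dplyr::case_when(
    cod == "YR" ~ 1, cod == "DEC" ~ 10, cod == "MON" ~ 1 / 12,
    cod == "WK" ~ 1 / 52.18, cod == "DY" ~ 1 / 365.25,
    TRUE ~ NA_real_
  )
  a * mult
}

faers_weight_kg <- function(wt, wt_cod) {
  w <- suppressWarnings(as.numeric(wt %||% NA))
  cod <- toupper(stringr::str_trim(wt_cod %||% rep("KG", length(w))))
  cod[cod == "" | is.na(cod)] <- "KG"
  w <- ifelse(cod == "LBS", w * 0.453592, ifelse(cod == "KG", w, NA_real_))
  ifelse(!is.na(w) & w > 0, w, NA_real_)
}

blank_to_unknown <- function(x) {
  x <- stringr::str_trim(as.character(x %||% character()))
  ifelse(is.na(x) | x == "", "unknown", x)
}

code_to_enum <- function(x, map) {
  x <- stringr::str_trim(as.character(x %||% character()))
  out <- unname(map[x])
  ifelse(is.na(out), "unknown", out)
}

empty_drug_entry <- function() {
  tibble::tibble(name_raw = character(), role = character(),
                 start_date = as.Date(character()),
                 start_precision = character())
}

empty_report_tbl <- function() {
  tibble::tibble(
    case_id = character(), row_id = character(),
    version_date = as.Date(character()), source = character(),
    sex = character(), age_group = character(), weight_kg = double(),
    country = character(), reporter_type = character(),
    event_date = as.Date(character()), event_precision = character(),
    outcomes = list(), drugs = list(), events = list()
  )
}

# split per-entry tables into list-columns aligned with `reports$row_id`
attach_entries <- function(reports, drug_tbl, reac_tbl, outc_tbl) {
  ids <- reports$row_id

  dsplit <- split(
    drug_tbl[setdiff(names(drug_tbl), "row_id")],
    factor(drug_tbl$row_id, levels = ids)
  )
  esplit <- split(reac_tbl$pt, factor(reac_tbl$row_id, levels = ids))
  osplit <- split(outc_tbl$outcome, factor(outc_tbl$row_id, levels = ids))

  reports$drugs <- lapply(dsplit, tibble::as_tibble)
  reports$events <- lapply(esplit, function(x) unique(as.character(x)))
  reports$outcomes <- lapply(osplit, function(x) {
    x <- unique(as.character(x))
    x[x %in% srs_outcomes]
  })
  reports[c("case_id", "row_id", "version_date", "source", "sex",
            "age_group", "weight_kg", "country", "reporter_type",
            "outcomes", "drugs", "events", "event_date", "event_precision")]
}
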