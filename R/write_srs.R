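# Writers emitting the two source dialects from the nested case-report
# model. They serve the synthetic-report generator and the round-trip
# guarantee: parse(write(x)) reproduces x field-by-field for day-precision
# records. Age groups are rendered as a representative raw value of their
# bin (the model stores bins, not raw ages).

faers_age_rep <- c("<2" = "1", "2-11" = "6", "12-17" = "14",
                   "18-64" = "40", "65-85" = "70", ">85" = "90",
                   "unknown" = "")
jader_age_rep <- c("<10" = "10歳未満", "10-19" = "10歳代",
                   "20-69" = "40歳代", ">=70" = "70歳代",
                   # FAERS-binned models coarsen onto the JADER decades
                   "<2" = "10歳未満", "2-11" = "10歳未満", "12-17" = "10歳代",
                   "18-64" = "40歳代", "65-85" = "70歳代", ">85" = "80歳代",
                   "unknown" = "")

rev_map <- function(map) stats::setNames(names(map), unname(map))

#' Write case reports as FAERS-style quarterly ASCII files
#'
#' Emits `$`-delimited `demo.txt`, `drug.txt`, `reac.txt`, `outc.txt` and
#' `ther.txt` into `dir`, in the dialect read by [parse_faers_quarter()].
#'
#' @param reports Case-report tibble.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the five file paths.
#' @export
write_faers <- function(reports, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  role_rev <- rev_map(faers_role_codes)
  rep_rev <- c(physician = "MD", pharmacist = "PH", consumer = "CN",
               other_health_professional = "OT", unknown = "")
  outc_rev <- rev_map(faers_outcome_codes)

  demo <- tibble::tibble(
    primaryid = reports$row_id,
    caseid = reports$case_id,
    fda_dt = format(reports$version_date, "%Y%m%d"),
    event_dt = format_srs_date(reports$event_date, reports$event_precision),
    sex = dplyr::case_when(reports$sex == "male" ~ "M",
                           reports$sex == "female" ~ "F", TRUE ~ ""),
    age = unname(faers_age_rep[reports$age_group]),
    age_cod = ifelse(reports$age_group == "unknown", "", "YR"),
    wt = ifelse(is.na(reports$weight_kg), "",
                format(reports$weight_kg, trim = TRUE)),
    wt_cod = ifelse(is.na(reports$weight_kg), "", "KG"),
    occp_cod = unname(rep_rev[reports$reporter_type]),
    reporter_country = ifelse(reports$country == "unknown", "",
                              reports$country)
  )

  n_drugs <- vapply(reports$drugs, nrow, integer(1))
  dflat <- dplyr::bind_rows(reports$drugs)
  drug_rows <- tibble::tibble(
    primaryid = rep(reports$row_id, n_drugs),
    drug_seq = as.character(unlist(lapply(n_drugs, seq_len), use.names = FALSE)),
    role_cod = unname(role_rev[dflat$role]) %|na|% "",
    drugname = dflat$name_raw,
    start_dt = format_srs_date(dflat$start_date, dflat$start_precision)
  )
  reac_rows <- tibble::tibble(
    primaryid = rep(reports$row_id, lengths(reports$events)),
    pt = unlist(reports$events, use.names = FALSE) %||% character()
  )
  outc_rows <- tibble::tibble(
    primaryid = rep(reports$row_id, lengths(reports$outcomes)),
    outc_cod = unname(outc_rev[unlist(reports$outcomes, use.names = FALSE) %||%
                                 character()])
  )
  drug_rows <- ensure_cols(drug_rows, c("primaryid", "drug_seq", "role_cod",
                                        "drugname", "start_dt"))
  reac_rows <- ensure_cols(reac_rows, c("primaryid", "pt"))
  outc_rows <- ensure_cols(outc_rows, c("primaryid", "outc_cod"))
  ther_rows <- drug_rows[drug_rows$start_dt != "", ]

  paths <- c(demo = file.path(dir, "demo.txt"),
             drug = file.path(dir, "drug.txt"),
             reac = file.path(dir, "reac.txt"),
             outc = file.path(dir, "outc.txt"),
             ther = file.path(dir, "ther.txt"))
  write_delim_dollar(demo, paths["demo"])
  write_delim_dollar(drug_rows[c("primaryid", "drug_seq", "role_cod", "drugname")],
                     paths["drug"])
  write_delim_dollar(reac_rows, paths["reac"])
  write_delim_dollar(outc_rows, paths["outc"])
  write_delim_dollar(
    tibble::tibble(primaryid = ther_rows$primaryid,
                   dsg_drug_seq = ther_rows$drug_seq,
                   start_dt = ther_rows$start_dt),
    paths["ther"])
  invisible(paths)
}

#' Write case reports as JADER-style CSV tables
#'
#' Emits `demo.csv`, `drug.csv` and `reac.csv` into `dir` in the dialect
#' read by [parse_jader()], with Japanese field codes for sex, reporter,
#' role and outcome. JADER's role vocabulary has no separate
#' secondary-suspect code, so both suspect roles render as the suspect
#' code.
#'
#' @param reports Case-report tibble.
#' @param dir Output directory (created if needed).
#' @param encoding Output text encoding (default the Japanese legacy
#'   encoding assumed by [parse_jader()]).
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_jader <- function(reports, dir, encoding = "CP932") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sex_rev <- rev_map(jader_sex_codes)
  rep_rev <- rev_map(jader_reporter_codes)
  role_rev <- c(primary_suspect = "被疑薬",
                secondary_suspect = "被疑薬",
                concomitant = "併用薬",
                interacting = "相互作用",
                unknown = "")

  demo <- tibble::tibble(
    case_id = reports$case_id,
    sex = unname(sex_rev[reports$sex]) %|na|% "",
    age = unname(jader_age_rep[reports$age_group]),
    weight = ifelse(is.na(reports$weight_kg), "",
                    format(reports$weight_kg, trim = TRUE)),
    reporter = unname(rep_rev[reports$reporter_type]) %|na|% "",
    report_date = format(reports$version_date, "%Y%m%d"),
    event_date = format_srs_date(reports$event_date, reports$event_precision),
    outcome = vapply(reports$outcomes, function(o) {
      if (!length(o)) "" else if ("death" %in% o) jader_death_code
      else "軽快"  # recovered/improving
    }, character(1))
  )

  # entry tables are keyed by case_id; emit entries once per case
  first <- reports[!duplicated(reports$case_id), ]
  n_drugs <- vapply(first$drugs, nrow, integer(1))
  dflat <- dplyr::bind_rows(first$drugs)
  drug_rows <- tibble::tibble(
    case_id = rep(first$case_id, n_drugs),
    drug_seq = as.character(unlist(lapply(n_drugs, seq_len), use.names = FALSE)),
    role = unname(role_rev[dflat$role]) %|na|% "",
    drug_name = dflat$name_raw,
    start_date = format_srs_date(dflat$start_date, dflat$start_precision)
  )
  reac_rows <- tibble::tibble(
    case_id = rep(first$case_id, lengths(first$events)),
    pt = unlist(first$events, use.names = FALSE) %||% character()
  )

  drug_rows <- ensure_cols(drug_rows, c("case_id", "drug_seq", "role",
                                        "drug_name", "start_date"))
  reac_rows <- ensure_cols(reac_rows, c("case_id", "pt"))

  paths <- c(demo = file.path(dir, "demo.csv"),
             drug = file.path(dir, "drug.csv"),
             reac = file.path(dir, "reac.csv"))
  write_csv_enc(demo, paths["demo"], encoding)
  write_csv_enc(drug_rows, paths["drug"], encoding)
  write_csv_enc(reac_rows, paths["reac"], encoding)
  invisible(paths)
}

ensure_cols <- function(df, cols) {
  if (is.null(df) || nrow(df) == 0L) {
    df <- tibble::as_tibble(stats::setNames(
      rep(list(character()), length(cols)), cols))
  }
  df[cols]
}

`%|na|%` <- function(x, fill) {
  x[is.na(x)] <- fill
  x
}

write_delim_dollar <- function(df, path) {
  df[] <- lapply(df, function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    x
  })
  lines <- c(paste(names(df), collapse = "$"),
             do.call(paste, c(unname(as.list(df)), sep = "$")))
  writeLines(lines, path)
}

write_csv_enc <- function(df, path, encoding) {
  df[] <- lapply(df, function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    x
  })
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(unname(as.list(df)), sep = ",")))
  if (toupper(encoding) != "UTF-8") {
    lines <- iconv(lines, from = "UTF-8", to = encoding)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
}
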