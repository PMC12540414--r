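# In-code fixture builders shared across the suite.

drug_entry <- function(name = "FENTANYL", role = "primary_suspect",
                       start_date = as.Date(NA),
                       start_precision = NA_character_) {
  tibble::tibble(name_raw = name, role = role,
                 start_date = as.Date(start_date),
                 start_precision = start_precision)
}

make_report <- function(case_id, row_id = paste0(case_id, "1"),
                        version_date = as.Date("2020-06-01"),
                        source = "FAERS", sex = "female",
                        age_group = "18-64", weight_kg = 70,
                        country = "United States",
                        reporter_type = "physician",
                        outcomes = list("other"),
                        drugs = list(drug_entry()),
                        events = list("PT_X"),
                        event_date = as.Date(NA),
                        event_precision = NA_character_) {
  tibble::tibble(
    case_id = case_id, row_id = row_id,
    version_date = as.Date(version_date), source = source, sex = sex,
    age_group = age_group, weight_kg = weight_kg, country = country,
    reporter_type = reporter_type, outcomes = outcomes, drugs = drugs,
    events = events, event_date = as.Date(event_date),
    event_precision = event_precision
  )
}

# A hand-built FAERS quarter: 5 DEMO rows (4 distinct cases; case 103 has
# two versions), 8 DRUG rows, 9 REAC rows, 3 OUTC rows, 3 THER rows.
write_faers_fixture <- function(dir = tempfile("faersfix")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(file, lines) writeLines(lines, file.path(dir, file))
  w("demo.txt", c(
    "primaryid$caseid$fda_dt$event_dt$sex$age$age_cod$wt$wt_cod$occp_cod$reporter_country",
    "1011$101$20200115$20200110$F$45$YR$70$KG$MD$United States",
    "1021$102$20200210$2020$M$8$YR$$$CN$France",
    "1031$103$20200301$20200225$F$70$YR$154$LBS$PH$United States",
    "1032$103$20200401$20200225$F$70$YR$70$KG$PH$United States",
    "1041$104$20200310$202002$$6$MON$$$$Japan"
  ))
  w("drug.txt", c(
    "primaryid$caseid$drug_seq$role_cod$drugname",
    "1011$101$1$PS$FENTANYL CITRATE",
    "1011$101$2$C$IBUPROFEN",
    "1021$102$1$PS$SUFENTANIL",
    "1031$103$1$PS$DURAGESIC-100",
    "1032$103$1$PS$DURAGESIC-100",
    "1032$103$2$SS$MORPHINE",
    "1041$104$1$C$FENTANYL",
    "1041$104$2$PS$OXYCODONE"
  ))
  w("reac.txt", c(
    "primaryid$caseid$pt",
    "1011$101$Nausea",
    "1011$101$Somnolence",
    "1021$102$Respiratory depression",
    "1031$103$Drug abuse",
    "1031$103$Nausea",
    "1032$103$Drug abuse",
    "1032$103$Somnolence",
    "1041$104$Vomiting",
    "1041$104$Nausea"
  ))
  w("outc.txt", c(
    "primaryid$caseid$outc_cod",
    "1011$101$HO",
    "1031$103$DE",
    "1032$103$DE"
  ))
  w("ther.txt", c(
    "primaryid$caseid$dsg_drug_seq$start_dt",
    "1011$101$1$20200101",
    "1031$103$1$20200201",
    "1032$103$1$20200201"
  ))
  c(demo = file.path(dir, "demo.txt"), drug = file.path(dir, "drug.txt"),
    reac = file.path(dir, "reac.txt"), outc = file.path(dir, "outc.txt"),
    ther = file.path(dir, "ther.txt"))
}

# Small JADER fixture: 3 distinct cases, one lacking sex, Japanese drug
# names, and case J2 reported twice (shared identification number).
write_jader_fixture <- function(dir = tempfile("jaderfix")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  enc <- function(lines) iconv(lines, "UTF-8", "CP932")
  w <- function(file, lines) {
    con <- file(file.path(dir, file), open = "wb")
    on.exit(close(con))
    writeLines(enc(lines), con, useBytes = TRUE)
  }
  w("demo.csv", c(
    "case_id,sex,age,weight,reporter,report_date,event_date,outcome",
    "J1,男性,40歳代,60,医師,20200401,20200325,死亡",
    "J2,女性,70歳代,,医師,20200310,20200301,軽快",
    "J2,女性,70歳代,,医師,20200510,20200301,軽快",
    "J3,,10歳未満,,,20200620,202006,"
  ))
  w("drug.csv", c(
    "case_id,drug_seq,role,drug_name,start_date",
    "J1,1,被疑薬,フェンタニル,20200320",
    "J2,1,被疑薬,フェンタネスト,20200201",
    "J2,2,併用薬,モルヒネ,",
    "J3,1,被疑薬,オキシコドン,"
  ))
  w("reac.csv", c(
    "case_id,pt",
    "J1,呼吸抑制",
    "J2,悪心",
    "J2,傾眠",
    "J3,嘔吐"
  ))
  c(demo = file.path(dir, "demo.csv"), drug = file.path(dir, "drug.csv"),
    reac = file.path(dir, "reac.csv"))
}

# brute-force 2x2 recount used as the independent oracle for
# build_contingency
recount_tables <- function(target, comparator, pt) {
  has <- function(reports) {
    vapply(reports$events, function(e) pt %in% e, logical(1))
  }
  ht <- has(target); hc <- has(comparator)
  c(a = sum(ht), b = sum(!ht), c = sum(hc), d = sum(!hc))
}
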