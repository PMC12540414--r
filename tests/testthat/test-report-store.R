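test_that("FAERS quarter parsing joins the tables with correct counts", {
  paths <- write_faers_fixture()
  suppressMessages(
    reports <- parse_faers_quarter(paths["demo"], paths["drug"],
                                   paths["reac"], paths["outc"],
                                   paths["ther"])
  )
  expect_equal(nrow(reports), 5L)  # one per DEMO row
  expect_equal(sum(vapply(reports$drugs, nrow, integer(1))), 8L)
  # REAC has 9 rows but case 104 repeats a PT only across cases, so all
  # survive as event entries
  expect_equal(sum(lengths(reports$events)), 9L)

  # partial dates keep a precision flag
  r102 <- reports[reports$row_id == "1021", ]
  expect_equal(r102$event_precision, "year")
  expect_equal(r102$event_date, as.Date("2020-01-01"))
  r104 <- reports[reports$row_id == "1041", ]
  expect_equal(r104$event_precision, "month")

  # weights normalize to kg (154 LBS ~ 69.9 kg), therapy dates joined
  r103 <- reports[reports$row_id == "1031", ]
  expect_equal(r103$weight_kg, 154 * 0.453592)
  expect_equal(r103$drugs[[1]]$start_date[1], as.Date("2020-02-01"))
  expect_equal(r103$drugs[[1]]$start_precision[1], "day")

  # age in months lands in the infant bin
  expect_equal(r104$age_group, "<2")
  expect_equal(r104$reporter_type, "unknown")
  expect_setequal(reports$outcomes[[1]], "hospitalization")
})

test_that("FAERS parsing reports format errors and degenerate inputs", {
  paths <- write_faers_fixture()
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("primaryid$caseid", "1$1"), bad)
  expect_error(parse_faers_quarter(paths["demo"], bad, paths["reac"]),
               "role_cod")

  empty_demo <- withr::local_tempfile(fileext = ".txt")
  writeLines("primaryid$caseid$fda_dt", empty_demo)
  expect_warning(
    out <- parse_faers_quarter(empty_demo, paths["drug"], paths["reac"],
                               quiet = TRUE),
    "no records")
  expect_equal(nrow(out), 0L)

  # empty REAC -> reports with empty event lists, droppable downstream
  empty_reac <- withr::local_tempfile(fileext = ".txt")
  writeLines("primaryid$caseid$pt", empty_reac)
  suppressMessages(
    out2 <- parse_faers_quarter(paths["demo"], paths["drug"], empty_reac))
  expect_true(all(lengths(out2$events) == 0L))
  expect_equal(nrow(suppressMessages(drop_eventless(out2))), 0L)
})

test_that("JADER parsing normalizes Japanese codes and keeps names opaque", {
  paths <- write_jader_fixture()
  suppressMessages(
    reports <- parse_jader(paths["demo"], paths["drug"], paths["reac"]))
  expect_equal(nrow(reports), 4L)
  expect_true(all(reports$source == "JADER"))

  j1 <- reports[reports$case_id == "J1", ]
  expect_equal(j1$sex, "male")
  expect_equal(j1$age_group, "20-69")
  expect_equal(j1$reporter_type, "physician")
  expect_equal(j1$outcomes[[1]], "death")
  expect_equal(j1$drugs[[1]]$name_raw[1], "フェンタニル")

  # case lacking sex -> unknown; under-10 age bin
  j3 <- reports[reports$case_id == "J3", ]
  expect_equal(j3$sex, "unknown")
  expect_equal(j3$age_group, "<10")

  # two demo rows share identification number J2; dedup collapses to one,
  # keeping the later report date
  dedup <- deduplicate_reports(reports, quiet = TRUE)
  expect_equal(nrow(dedup), 3L)
  expect_equal(dedup$version_date[dedup$case_id == "J2"],
               as.Date("2020-05-10"))
})

test_that("deduplication keeps the latest version with deterministic ties", {
  r <- dplyr::bind_rows(
    make_report("100", row_id = "1001", version_date = "2020-01-01"),
    make_report("100", row_id = "1002", version_date = "2021-01-01"),
    make_report("200", row_id = "2001"),
    # tie on version_date: greatest row_id wins
    make_report("300", row_id = "3001", version_date = "2020-05-05"),
    make_report("300", row_id = "3002", version_date = "2020-05-05")
  )
  out <- deduplicate_reports(r, quiet = TRUE)
  expect_equal(nrow(out), 3L)
  expect_equal(out$row_id[out$case_id == "100"], "1002")
  expect_equal(out$row_id[out$case_id == "300"], "3002")
  expect_equal(attr(out, "removed"), 2L)

  # single report unchanged; idempotence
  single <- make_report("X")
  expect_equal(deduplicate_reports(single, quiet = TRUE)$row_id,
               single$row_id)
  again <- deduplicate_reports(out, quiet = TRUE)
  expect_equal(dplyr::select(again, -dplyr::any_of("matched")),
               dplyr::select(out, -dplyr::any_of("matched")),
               ignore_attr = TRUE)
})

test_that("drug matching is whole-token and congener-safe", {
  names10 <- c("FENTANYL", "FENTANYL CITRATE", "Duragesic-100", "ACTIQ",
               "sufentanil", "ALFENTANIL", "REMIFENTANIL HCL",
               "fentanyl transdermal system", "MORPHINE", "SUFENTANIL CITRATE")
  # oracle: token-boundary regex on case-folded names
  oracle <- vapply(names10, function(nm) {
    any(grepl("(^|[^[:alpha:]])(fentanyl|duragesic|actiq)([^[:alpha:]]|$)",
              tolower(nm)))
  }, logical(1))
  r <- dplyr::bind_rows(lapply(seq_along(names10), function(i) {
    make_report(as.character(i), drugs = list(drug_entry(names10[i])))
  }))
  out <- match_target_drug(r, c("fentanyl", "duragesic", "actiq"))
  expect_equal(out$matched, unname(oracle))
  expect_false(out$matched[5])   # sufentanil never matches
  expect_true(out$matched[3])    # DURAGESIC-100 matches
  expect_error(match_target_drug(r, character()), "non-empty")
})

test_that("primary-suspect filtering keeps only matched PS reports", {
  r <- dplyr::bind_rows(
    make_report("A", drugs = list(drug_entry("FENTANYL", "concomitant"))),
    make_report("B", drugs = list(drug_entry("FENTANYL", "primary_suspect"))),
    make_report("C", drugs = list(drug_entry("MORPHINE", "primary_suspect"))),
    make_report("D", drugs = list(dplyr::bind_rows(
      drug_entry("MORPHINE", "primary_suspect"),
      drug_entry("DURAGESIC", "primary_suspect"))))
  )
  out <- filter_primary_suspect(match_target_drug(r))
  expect_setequal(out$case_id, c("B", "D"))
  expect_error(filter_primary_suspect(r), "match_target_drug")
})

test_that("pipeline counts form a monotone chain on generated fixtures", {
  cfg <- sim_config(n_cases = 400, seed = 5)
  sim <- simulate_reports(cfg, withr::local_tempdir())
  suppressMessages({
    parsed <- parse_faers_quarter(sim$faers["demo"], sim$faers["drug"],
                                  sim$faers["reac"], sim$faers["outc"],
                                  sim$faers["ther"], quiet = TRUE)
    dedup <- deduplicate_reports(parsed, quiet = TRUE)
    matched <- match_target_drug(dedup)
    ps <- filter_primary_suspect(matched)
  })
  expect_true(nrow(parsed) >= nrow(dedup))
  expect_true(nrow(dedup) >= sum(matched$matched))
  expect_true(sum(matched$matched) >= nrow(ps))
})

test_that("writing back to the source dialect round-trips the case model", {
  cfg <- sim_config(n_cases = 150, seed = 77)
  sim <- simulate_reports(cfg, withr::local_tempdir())

  parse_f <- function(p) {
    parse_faers_quarter(p["demo"], p["drug"], p["reac"], p["outc"],
                        p["ther"], quiet = TRUE)
  }
  m1 <- suppressWarnings(parse_f(sim$faers))
  p2 <- write_faers(m1, withr::local_tempdir())
  m2 <- suppressWarnings(parse_f(p2))
  expect_equal(m2, m1)

  j1 <- parse_jader(sim$jader["demo"], sim$jader["drug"], sim$jader["reac"],
                    quiet = TRUE)
  jp <- write_jader(j1, withr::local_tempdir())
  j2 <- parse_jader(jp["demo"], jp["drug"], jp["reac"], quiet = TRUE)
  expect_equal(j2, j1)
})
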