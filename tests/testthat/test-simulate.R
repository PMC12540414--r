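test_that("the same seed yields byte-identical output files", {
  cfg <- sim_config(n_cases = 300, seed = 17)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_reports(cfg, d1)
  s2 <- simulate_reports(cfg, d2)
  files <- c(s1$faers, s1$jader, s1$truth_path)
  files2 <- c(s2$faers, s2$jader, s2$truth_path)
  for (i in seq_along(files)) {
    expect_identical(readBin(files[i], "raw", file.size(files[i])),
                     readBin(files2[i], "raw", file.size(files2[i])),
                     label = basename(files[i]))
  }
})

test_that("duplicate injection emits exactly the configured count", {
  cfg <- sim_config(n_cases = 1000, duplicate_rate = 0.1, seed = 3)
  sim <- simulate_reports(cfg, withr::local_tempdir())
  expect_length(sim$truth$duplicates, 100L)

  parsed <- suppressWarnings(parse_faers_quarter(
    sim$faers["demo"], sim$faers["drug"], sim$faers["reac"], quiet = TRUE))
  expect_equal(nrow(parsed), 1100L)
  dedup <- deduplicate_reports(parsed, quiet = TRUE)
  expect_equal(nrow(dedup), 1000L)
  expect_equal(attr(dedup, "removed"), 100L)
  # the retained version of each duplicated case is the later one
  dup <- dedup[dedup$case_id %in% sim$truth$duplicates, ]
  expect_true(all(endsWith(dup$row_id, "2")))
})

test_that("a null generator produces no systematic disproportionality", {
  cfg <- sim_config(n_cases = 4000, target_share = 0.2,
                    rr_map = setNames(numeric(0), character(0)),
                    sex_rr_map = setNames(numeric(0), character(0)),
                    seed = 23)
  sim <- simulate_reports(cfg, withr::local_tempdir())
  reports <- deduplicate_reports(suppressWarnings(parse_faers_quarter(
    sim$faers["demo"], sim$faers["drug"], sim$faers["reac"], quiet = TRUE)),
    quiet = TRUE)
  reports <- match_target_drug(reports)
  target <- filter_primary_suspect(reports)
  comparator <- reports[!reports$case_id %in% target$case_id, ]
  tab <- build_contingency(target, comparator)

  # under the null, per-PT target counts are binomial draws from the
  # pooled margin; few PTs should look discrepant
  share <- nrow(target) / (nrow(target) + nrow(comparator))
  pv <- vapply(seq_len(nrow(tab)), function(i) {
    stats::binom.test(tab$a[i], tab$a[i] + tab$c[i], share)$p.value
  }, numeric(1))
  expect_lt(mean(pv < 0.05), 0.10)
})

test_that("realized onset times, sex split and missingness match the configuration", {
  cfg <- sim_config(n_cases = 5000, seed = 13)
  sim <- simulate_reports(cfg, withr::local_tempdir())
  truth <- sim$truth

  # onset law: exact KS test against the configured Weibull
  ks <- stats::ks.test(truth$cases$onset_days,
                       function(q) pweibull(q, cfg$tto_shape, cfg$tto_scale))
  expect_gt(ks$p.value, 0.01)

  n <- nrow(truth$cases)
  se <- function(p) sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(truth$cases$sex_true == "female") - cfg$sex_split),
            3 * se(cfg$sex_split))

  reports <- deduplicate_reports(suppressWarnings(parse_faers_quarter(
    sim$faers["demo"], sim$faers["drug"], sim$faers["reac"], quiet = TRUE)),
    quiet = TRUE)
  expect_lt(abs(mean(reports$sex == "unknown") - cfg$missing_rates$sex),
            3 * se(cfg$missing_rates$sex))
  expect_lt(abs(mean(is.na(reports$weight_kg)) - cfg$missing_rates$weight),
            3 * se(cfg$missing_rates$weight))
})

test_that("truth counts agree between dialects and with the emitted files", {
  cfg <- sim_config(n_cases = 400, seed = 41)
  sim <- simulate_reports(cfg, withr::local_tempdir())
  faers <- deduplicate_reports(suppressWarnings(parse_faers_quarter(
    sim$faers["demo"], sim$faers["drug"], sim$faers["reac"], quiet = TRUE)),
    quiet = TRUE)
  jader <- deduplicate_reports(parse_jader(
    sim$jader["demo"], sim$jader["drug"], sim$jader["reac"], quiet = TRUE),
    quiet = TRUE)
  expect_equal(nrow(faers), nrow(sim$truth$cases))
  expect_equal(nrow(jader), nrow(sim$truth$cases))
  # identical event truth regardless of dialect
  fa <- setNames(faers$events, faers$case_id)
  ja <- setNames(jader$events, jader$case_id)
  expect_equal(fa[order(names(fa))], ja[order(names(ja))])

  # per-PT truth counts match a recount of the emitted events
  counts <- sim$truth$pt_counts
  tot <- tapply(counts$n, counts$pt, sum)
  emitted <- table(unlist(faers$events, use.names = FALSE))
  for (pt in names(emitted)) {
    expect_equal(unname(tot[pt]), unname(as.integer(emitted[pt])))
  }
})
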