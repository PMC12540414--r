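test_that("ROR matches the log-scale hand calculation", {
  # symmetric table
  sym <- ror(5, 5, 5, 5)
  expect_equal(sym$ror, 1)
  expect_true(sym$ror_lo < 1 && sym$ror_hi > 1)

  # frozen hand calculation: ror = (10*9900)/(90*100) = 11,
  # CI = exp(ln 11 +/- 1.96 * sqrt(1/10 + 1/90 + 1/100 + 1/9900))
  r <- ror(10, 90, 100, 9900)
  expect_equal(r$ror, 11)
  se <- sqrt(1 / 10 + 1 / 90 + 1 / 100 + 1 / 9900)
  expect_equal(r$ror_lo, exp(log(11) - qnorm(0.975) * se))
  expect_equal(signif(r$ror_lo, 3), 5.56)
  expect_equal(signif(r$ror_hi, 3), 21.8)

  # zero cell -> non-evaluable
  expect_true(is.na(ror(0, 100, 100, 9900)$ror))
})

test_that("PRR and Yates chi-square match hand calculations", {
  expect_equal(prr(1, 9, 10, 90)$prr, 1)

  p <- prr(10, 90, 100, 9900)
  expect_equal(p$prr, 10)
  n <- 10100
  chi2_hand <- n * (abs(10 * 9900 - 90 * 100) - n / 2)^2 /
    (100 * 10000 * 110 * 9990)
  expect_equal(p$chi2, chi2_hand)
  expect_equal(signif(p$chi2, 3), 66.3)
  expect_equal(p$p_value, pchisq(chi2_hand, 1, lower.tail = FALSE))

  expect_equal(prr(0, 100, 10, 90)$prr, 0)
  expect_true(is.na(prr(10, 90, 0, 100)$prr))
  expect_error(prr(0, 0, 10, 90), "a\\+b")
})

test_that("information component matches frozen values and the independence limit", {
  # exact independence: 1000/100000 * 10000/100000 joint = 100/100000
  ind <- bcpnn_ic(100, 900, 9900, 89100)
  expect_lt(abs(ind$ic), 0.05)

  # frozen closed-form values for the standard example table
  x <- bcpnn_ic(10, 90, 100, 9900)
  expect_equal(round(x$ic, 2), 2.38)
  expect_equal(round(x$ic025, 2), 1.43)
  expect_equal(x$ic025, x$ic - 2 * x$ic_sd)

  # the formula is defined for any table with positive pseudo-counts
  deg <- bcpnn_ic(1, 0, 0, 0)
  expect_true(is.finite(deg$ic))
})

test_that("information component moments agree with Monte-Carlo posterior sampling", {
  # Beta posteriors on the joint and marginal reporting probabilities;
  # run in the moderate-count regime where the closed-form
  # moment approximation is accurate
  a <- 100; b <- 900; c <- 1000; d <- 99000
  n <- a + b + c + d
  pri <- bcpnn_priors()
  g <- pri$gamma11 * (n + pri$alpha) * (n + pri$beta) /
    ((a + b + pri$alpha1) * (a + c + pri$beta1))
  set.seed(123)
  ndraw <- 1e5
  p11 <- rbeta(ndraw, a + pri$gamma11, n - a + g - pri$gamma11)
  p1 <- rbeta(ndraw, a + b + pri$alpha1, n - a - b + pri$alpha - pri$alpha1)
  p2 <- rbeta(ndraw, a + c + pri$beta1, n - a - c + pri$beta - pri$beta1)
  ic_draws <- log2(p11 / (p1 * p2))

  x <- bcpnn_ic(a, b, c, d)
  expect_lt(abs(x$ic - mean(ic_draws)), 0.05)
  expect_lt(abs(x$ic_sd - sd(ic_draws)), 0.05)
})

test_that("Bonferroni adjustment matches the element-wise oracle", {
  expect_equal(bonferroni_adjust(0.001, m = 10), 0.01)
  expect_equal(bonferroni_adjust(0.5, m = 10), 1)
  set.seed(9)
  p <- runif(50)
  expect_equal(bonferroni_adjust(p), pmin(1, length(p) * p))
})

test_that("consensus requires every criterion and vetoes on any failure", {
  base <- tibble::tibble(a = 10, ror_lo = 2, prr = 5, chi2 = 30,
                         ic025 = 1, eb05 = 3, p_adjusted = 0.001)
  expect_true(consensus(base))
  expect_false(consensus(dplyr::mutate(base, ic025 = -0.1)))
  expect_false(consensus(dplyr::mutate(base, a = 2)))
  expect_false(consensus(dplyr::mutate(base, eb05 = 1.9)))
  expect_false(consensus(dplyr::mutate(base, p_adjusted = 0.06)))
  # non-evaluable statistic fails rather than passing
  expect_false(consensus(dplyr::mutate(base, ror_lo = NA_real_)))
})

test_that("sex-subgroup ROR matches the hand calculation and symmetry", {
  st <- tibble::tibble(a_f = 30, b_f = 70, a_m = 10, b_m = 90)
  out <- sex_ror(st)
  expect_equal(out$ror_fm, (30 * 90) / (70 * 10))
  expect_equal(round(out$ror_fm, 2), 3.86)
  expect_lt(out$ror_fm_lo, out$ror_fm)
  expect_gt(out$ror_fm_hi, out$ror_fm)

  eq <- sex_ror(tibble::tibble(a_f = 20, b_f = 80, a_m = 20, b_m = 80))
  expect_equal(eq$ror_fm, 1)
  expect_gt(eq$p_value, 0.9)

  zc <- sex_ror(tibble::tibble(a_f = 5, b_f = 95, a_m = 0, b_m = 100))
  expect_equal(zc$method, "fisher_zero_cell")
})

test_that("simulated male-excess PT yields ror_fm below 1 with small p", {
  cfg <- sim_config(n_cases = 5000, target_share = 1,
                    sex_rr_map = c(PT_010 = 0.4), seed = 99)
  sim <- simulate_reports(cfg, withr::local_tempdir())
  r <- suppressMessages(deduplicate_reports(parse_faers_quarter(
    sim$faers["demo"], sim$faers["drug"], sim$faers["reac"], quiet = TRUE),
    quiet = TRUE))
  tgt <- filter_primary_suspect(match_target_drug(r))
  out <- sex_ror(stratify_by_sex(tgt, "PT_010", quiet = TRUE))
  expect_lt(out$ror_fm, 1)
  expect_lt(out$p_value, 0.05)
})

test_that("ROR and PRR agree in the rare-event regime; IC tracks log2 PRR", {
  set.seed(21)
  for (i in 1:20) {
    a <- sample(5:20, 1); b <- 1000 - a
    c <- sample(50:200, 1); d <- 100000 - c
    r <- ror(a, b, c, d)$ror
    p <- prr(a, b, c, d)$prr
    expect_lt(abs(r / p - 1), 0.1)
  }
  # in the large-count limit the pseudo-count shrinkage vanishes and the
  # IC approaches log2 of the observed/expected ratio
  for (i in 1:20) {
    a <- sample(200:800, 1); b <- 10000 - a
    c <- sample(5000:20000, 1); d <- 1e6 - c
    ic <- bcpnn_ic(a, b, c, d)$ic
    oe <- a / ((a + b) * (a + c) / (a + b + c + d))
    expect_lt(abs(ic - log2(oe)), 0.05)
  }
})

test_that("consensus is conservative under the global null", {
  set.seed(77)
  n_t <- 2000; n_c <- 98000
  p <- runif(1000, 0.001, 0.02)
  a <- rbinom(1000, n_t, p)
  c <- rbinom(1000, n_c, p)
  tab <- tibble::tibble(pt = sprintf("N%04d", 1:1000), a = a, b = n_t - a,
                        c = c, d = n_c - c, n = n_t + n_c)
  cells <- tibble::tibble(a = tab$a,
                          e = (tab$a + tab$b) * (tab$a + tab$c) / tab$n)
  sig <- signal_table(tab, gps_params = gps_fit(cells))

  frac <- function(x) mean(!is.na(x) & x)
  f_ror <- frac(sig$a >= 3 & sig$ror_lo > 1)
  f_prr <- frac(sig$prr >= 2 & sig$chi2 >= 4)
  f_ic <- frac(sig$ic025 > 0)
  f_eb <- frac(sig$eb05 >= 2)
  f_cons <- mean(sig$is_signal)
  expect_lte(f_cons, min(f_ror, f_prr, f_ic, f_eb))
  expect_lte(f_cons, 0.01)
})
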