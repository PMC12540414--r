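tto_report <- function(case_id, start, start_prec, event, event_prec) {
  make_report(case_id,
              drugs = list(drug_entry("FENTANYL", "primary_suspect",
                                      start_date = start,
                                      start_precision = start_prec)),
              event_date = event, event_precision = event_prec)
}

test_that("time to onset applies the date-quality exclusion rules", {
  r <- dplyr::bind_rows(
    tto_report("ok30", "2020-01-01", "day", "2020-01-31", "day"),
    tto_report("neg", "2020-01-01", "day", "2019-12-31", "day"),
    tto_report("coarse_start", "2020-01-01", "month", "2020-03-01", "day"),
    tto_report("no_event", "2020-01-01", "day", NA, NA),
    tto_report("same_day", "2020-02-01", "day", "2020-02-01", "day")
  )
  out <- compute_tto(r, quiet = TRUE)
  expect_equal(out$records$days[out$records$case_id == "ok30"], 30)
  expect_equal(out$records$days[out$records$case_id == "same_day"], 0.5)
  expect_false("neg" %in% out$records$case_id)
  ex <- setNames(out$exclusions$n, out$exclusions$reason)
  expect_equal(unname(ex["negative_tto"]), 1L)
  expect_equal(unname(ex["start_date_imprecise"]), 1L)
  expect_equal(unname(ex["no_event_date"]), 1L)

  # the earliest primary-suspect start anchors the interval
  multi <- make_report("multi", drugs = list(dplyr::bind_rows(
    drug_entry("FENTANYL", "primary_suspect", "2020-02-01", "day"),
    drug_entry("DURAGESIC", "primary_suspect", "2020-01-01", "day"))),
    event_date = as.Date("2020-01-11"), event_precision = "day")
  out2 <- compute_tto(multi, quiet = TRUE)
  expect_equal(out2$records$days, 10)
})

test_that("chronology summary bins and order statistics are correct", {
  s <- tto_summary(tibble::tibble(days = c(10, 45, 400)))
  bins <- setNames(s$bins$n, s$bins$bin)
  expect_equal(unname(bins[c("<=30", "31-60", ">365")]), c(1L, 1L, 1L))
  expect_equal(sum(s$bins$n), 3L)

  s2 <- tto_summary(tibble::tibble(days = 1:5))
  expect_equal(s2$stats$median, 3)
  expect_equal(c(s2$stats$q1, s2$stats$q3), c(2, 4))

  # large-sample bin proportions match the analytic Weibull CDF
  set.seed(314)
  d <- rweibull(5000, 0.43, 111.77)
  d[d == 0] <- 0.5
  s3 <- tto_summary(tibble::tibble(days = d))
  p30 <- s3$bins$pct[s3$bins$bin == "<=30"] / 100
  expect_lt(abs(p30 - pweibull(30, 0.43, 111.77)), 0.02)

  empty <- tto_summary(tibble::tibble(days = numeric()))
  expect_true(isTRUE(attr(empty, "empty")))
})

test_that("Kaplan-Meier estimate equals one minus the ECDF without censoring", {
  km <- km_estimate(tibble::tibble(days = c(1, 2, 3)))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))

  km_tied <- km_estimate(tibble::tibble(days = c(2, 2, 4)))
  expect_equal(km_tied$surv[km_tied$time == 2], 1 / 3)

  set.seed(8)
  d <- rweibull(400, 0.6, 50)
  km2 <- km_estimate(tibble::tibble(days = d))
  ec <- ecdf(d)
  expect_equal(km2$surv, 1 - ec(km2$time), tolerance = 1e-12)
  expect_true(all(diff(km2$surv) <= 0))
  expect_equal(km2$surv[length(km2$surv)], 0)

  expect_error(km_estimate(tibble::tibble(days = numeric())), "no records")
})

test_that("Weibull MLE matches the profile identity and a grid-search oracle", {
  # shape fixed at 1 reduces the profile identity to the sample mean
  f1 <- weibull_fit(c(2, 4, 6), gof_reps = 0, fix_shape = 1)
  expect_equal(f1$scale, 4)

  # independent grid-search oracle (beta step 1e-3, profile lambda)
  t <- c(0.5, 1, 2, 4, 8)
  bs <- seq(0.05, 20, by = 1e-3)
  ll <- vapply(bs, function(b) {
    l <- (mean(t^b))^(1 / b)
    length(t) * log(b) - length(t) * b * log(l) + (b - 1) * sum(log(t)) -
      sum((t / l)^b)
  }, numeric(1))
  i <- which.max(ll)
  f2 <- suppressWarnings(weibull_fit(t, gof_reps = 0))
  expect_equal(f2$shape, bs[i], tolerance = 1e-3)
  expect_equal(f2$scale, (mean(t^bs[i]))^(1 / bs[i]), tolerance = 1e-3)
})

test_that("Weibull MLE is scale-equivariant", {
  set.seed(42)
  t <- rweibull(300, 0.7, 40)
  f <- weibull_fit(t, gof_reps = 0)
  fk <- weibull_fit(10 * t, gof_reps = 0)
  expect_equal(fk$shape, f$shape, tolerance = 1e-5)
  expect_equal(fk$scale, 10 * f$scale, tolerance = 1e-4)
})

test_that("hazard classification follows the confidence-interval rule", {
  set.seed(7)
  d <- rweibull(2000, 0.43, 111.77)
  d[d <= 0] <- 0.5
  f <- weibull_fit(d, gof_reps = 0)
  expect_lt(f$shape_ci[2], 1)
  expect_equal(classify_hazard(f), "decreasing")

  inc <- weibull_fit(rweibull(2000, 1.5, 20), gof_reps = 0)
  expect_equal(classify_hazard(inc), "increasing")

  const <- weibull_fit(rweibull(2000, 1, 20), gof_reps = 0)
  expect_equal(classify_hazard(const), "constant")
})

test_that("bootstrap goodness-of-fit p-values are calibrated under the null", {
  set.seed(1234)
  pvals <- replicate(60, {
    d <- rweibull(80, 0.8, 30)
    f <- weibull_fit(d, gof_reps = 99)
    f$ks_p
  })
  # roughly uniform: mean near 1/2 and no pile-up below 0.1
  expect_lt(abs(mean(pvals) - 0.5), 0.12)
  expect_lt(mean(pvals < 0.1), 0.25)
  # bootstrap p-values are discrete (lattice 1/(B+1)); ties are expected
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)

  # a grossly non-Weibull sample is rejected
  set.seed(99)
  bimodal <- c(runif(150, 0.5, 1), runif(150, 400, 401))
  fbad <- weibull_fit(bimodal, gof_reps = 99)
  expect_lt(fbad$ks_p, 0.05)
})

test_that("tidy and glance expose the fit as conventional tables", {
  set.seed(5)
  f <- weibull_fit(rweibull(200, 0.5, 100), gof_reps = 19)
  td <- tidy(f)
  expect_equal(td$parameter, c("shape", "scale"))
  expect_true(all(td$ci_lower <= td$estimate & td$estimate <= td$ci_upper))
  gl <- glance(f)
  expect_equal(gl$n_used, 200L)
  expect_true(gl$hazard_class %in% c("decreasing", "constant", "increasing"))
})
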