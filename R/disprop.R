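#' Reporting odds ratio with 95% confidence interval
#'
#' `ror = (a d)/(b c)` with the Woolf log-scale interval
#' `exp(ln ror +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. Any zero cell makes
#' the statistic non-evaluable (`NA`); no continuity correction is applied
#' by default, matching the convention that zero-cell pairs simply fail
#' the signal criteria.
#'
#' @param a,b,c,d Integer vectors of 2x2 cell counts (recycled).
#' @param conf_level Confidence level of the interval.
#' @return Tibble with columns `ror, ror_lo, ror_hi`.
#' @export
ror <- function(a, b, c, d, conf_level = 0.95) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  ok <- a > 0 & b > 0 & c > 0 & d > 0
  z <- qnorm(1 - (1 - conf_level) / 2)
  est <- ifelse(ok, (a * d) / (b * c), NA_real_)
  se <- ifelse(ok, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  tibble::tibble(
    ror = est,
    ror_lo = exp(log(est) - z * se),
    ror_hi = exp(log(est) + z * se)
  )
}

#' Proportional reporting ratio with Yates-corrected chi-square
#'
#' `prr = [a/(a+b)] / [c/(c+d)]`; the test statistic is the
#' continuity-corrected chi-square
#' `N (|ad - bc| - N/2)^2 / ((a+b)(c+d)(a+c)(b+d))` with its 1-df
#' upper-tail p-value. A zero comparator count (`c = 0`) makes the ratio
#' non-evaluable; `a = 0` yields `prr = 0`.
#'
#' @param a,b,c,d Integer vectors of 2x2 cell counts.
#' @return Tibble with columns `prr, chi2, p_value`.
#' @export
prr <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  if (any(a + b == 0) || any(c + d == 0)) {
    stop("prr requires a+b > 0 and c+d > 0", call. = FALSE)
  }
  n <- a + b + c + d
  est <- ifelse(c > 0, (a / (a + b)) / (c / (c + d)), NA_real_)
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  dev <- pmax(abs(a * d - b * c) - n / 2, 0)
  chi2 <- ifelse(denom > 0, n * dev^2 / denom, NA_real_)
  tibble::tibble(
    prr = est,
    chi2 = chi2,
    p_value = pchisq(chi2, df = 1, lower.tail = FALSE)
  )
}

#' Default BCPNN pseudo-count priors
#'
#' The customary pseudo-counts of the closed-form information-component
#' posterior: 1 on each margin numerator (`alpha1`, `beta1`), 2 on the
#' margin denominators (`alpha`, `beta`) and 1 on the joint cell
#' (`gamma11`); the joint denominator pseudo-count `gamma` is derived per
#' table so the prior IC is centred at zero.
#'
#' @param alpha1,beta1,alpha,beta,gamma11 Strictly positive pseudo-counts.
#' @return A named list of class `bcpnn_priors`.
#' @export
bcpnn_priors <- function(alpha1 = 1, beta1 = 1, alpha = 2, beta = 2,
                         gamma11 = 1) {
  vals <- c(alpha1 = alpha1, beta1 = beta1, alpha = alpha, beta = beta,
            gamma11 = gamma11)
  if (any(vals <= 0)) stop("all BCPNN pseudo-counts must be > 0", call. = FALSE)
  structure(as.list(vals), class = "bcpnn_priors")
}

#' BCPNN information component (closed-form posterior moments)
#'
#' The information component is the log2 ratio of the joint reporting
#' probability of a drug-event pair to the product of its margins. With
#' beta-distributed posteriors on the joint and marginal proportions the
#' posterior mean and variance have closed forms:
#' `ic = log2[(a + g11)(N + alpha)(N + beta) /
#'            ((N + g)(a + b + alpha1)(a + c + beta1))]`
#' with `g = g11 (N + alpha)(N + beta) / ((a + b + alpha1)(a + c + beta1))`,
#' and `ic025 = ic - 2 ic_sd` is the conventional lower credibility bound.
#'
#' @param a,b,c,d Integer vectors of 2x2 cell counts.
#' @param priors A [bcpnn_priors()] list.
#' @return Tibble with columns `ic, ic_sd, ic025`.
#' @export
bcpnn_ic <- function(a, b, c, d, priors = bcpnn_priors()) {
  stopifnot(inherits(priors, "bcpnn_priors"))
  n <- a + b + c + d
  a1 <- priors$alpha1; b1 <- priors$beta1
  al <- priors$alpha;  be <- priors$beta
  g11 <- priors$gamma11
  g <- g11 * (n + al) * (n + be) / ((a + b + a1) * (a + c + b1))

  ic <- log2((a + g11) * (n + al) * (n + be) /
               ((n + g) * (a + b + a1) * (a + c + b1)))
  v <- (1 / log(2))^2 * (
    (n - a + g - g11) / ((a + g11) * (1 + n + g)) +
    (n - a - b + al - a1) / ((a + b + a1) * (1 + n + al)) +
    (n - a - c + be - b1) / ((a + c + b1) * (1 + n + be))
  )
  ic_sd <- sqrt(v)
  tibble::tibble(ic = ic, ic_sd = ic_sd, ic025 = ic - 2 * ic_sd)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m p)` with `m` the number of terms evaluated in the
#' run (a thin wrapper over [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param m Number of tests; defaults to `length(p_values)`.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  stopifnot(all(is.na(p_values) | (p_values >= 0 & p_values <= 1)))
  stats::p.adjust(p_values, method = "bonferroni", n = m)
}

#' Default consensus signal thresholds
#'
#' The literature-standard cut-offs for the four algorithms: at least 3
#' cases and ROR CI lower bound above 1; PRR at least 2 with chi-square at
#' least 4; IC025 above 0; EB05 at least 2; plus Bonferroni-adjusted
#' p-value below `alpha` as a multiplicity guard.
#'
#' @param min_a,ror_lo,prr,chi2,ic025,eb05,alpha Threshold values.
#' @return Named list of class `signal_thresholds`.
#' @export
signal_thresholds <- function(min_a = 3, ror_lo = 1, prr = 2, chi2 = 4,
                              ic025 = 0, eb05 = 2, alpha = 0.05) {
  structure(list(min_a = min_a, ror_lo = ror_lo, prr = prr, chi2 = chi2,
                 ic025 = ic025, eb05 = eb05, alpha = alpha),
            class = "signal_thresholds")
}

#' Four-way consensus signal rule
#'
#' A drug-event pair is declared a signal only when *all four* algorithms
#' pass their thresholds — `a >= 3` and ROR CI lower bound `> 1`;
#' `prr >= 2` and `chi2 >= 4`; `ic025 > 0`; `eb05 >= 2` — and the
#' Bonferroni-adjusted p-value is below `alpha`. A statistic that is
#' non-evaluable (zero cell) fails its criterion rather than being
#' imputed, so the rule is strictly conservative.
#'
#' @param stats_tbl Tibble containing columns `a, ror_lo, prr, chi2,
#'   ic025, eb05, p_adjusted`.
#' @param thresholds A [signal_thresholds()] list.
#' @return Logical vector `is_signal`.
#' @export
consensus <- function(stats_tbl, thresholds = signal_thresholds()) {
  th <- thresholds
  pass <- function(x) !is.na(x) & x
  pass(stats_tbl$a >= th$min_a) &
    pass(stats_tbl$ror_lo > th$ror_lo) &
    pass(stats_tbl$prr >= th$prr) &
    pass(stats_tbl$chi2 >= th$chi2) &
    pass(stats_tbl$ic025 > th$ic025) &
    pass(stats_tbl$eb05 >= th$eb05) &
    pass(stats_tbl$p_adjusted < th$alpha)
}

#' Female-versus-male subgroup reporting odds ratio
#'
#' Within the target-drug series, compares the odds of a PT among female
#' cases to the odds among male cases:
#' `ror_fm = (a_f b_m) / (b_f a_m)`, so values below 1 indicate a male
#' excess. The p-value uses the Yates-corrected chi-square, replaced by
#' Fisher's exact test whenever an expected cell is below 5; with a zero
#' cell only the Fisher output (conditional-MLE odds ratio, flagged) is
#' returned.
#'
#' @param sex_table One-row tibble from [stratify_by_sex()] (or any list
#'   with `a_f, b_f, a_m, b_m`).
#' @param conf_level Confidence level.
#' @return One-row tibble `ror_fm, ror_fm_lo, ror_fm_hi, p_value, method`.
#' @export
sex_ror <- function(sex_table, conf_level = 0.95) {
  a_f <- sex_table$a_f; b_f <- sex_table$b_f
  a_m <- sex_table$a_m; b_m <- sex_table$b_m
  m <- matrix(c(a_f, b_f, a_m, b_m), nrow = 2, byrow = TRUE)
  z <- qnorm(1 - (1 - conf_level) / 2)

  if (any(m == 0)) {
    ft <- fisher.test(m, conf.level = conf_level)
    return(tibble::tibble(
      ror_fm = unname(ft$estimate), ror_fm_lo = ft$conf.int[1],
      ror_fm_hi = ft$conf.int[2], p_value = ft$p.value,
      method = "fisher_zero_cell"
    ))
  }
  est <- (a_f * b_m) / (b_f * a_m)
  se <- sqrt(1 / a_f + 1 / b_f + 1 / a_m + 1 / b_m)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5)) {
    p <- fisher.test(m)$p.value
    method <- "fisher"
  } else {
    p <- suppressWarnings(chisq.test(m, correct = TRUE))$p.value
    method <- "yates_chisq"
  }
  tibble::tibble(
    ror_fm = est,
    ror_fm_lo = exp(log(est) - z * se),
    ror_fm_hi = exp(log(est) + z * se),
    p_value = p,
    method = method
  )
}

#' Full signal table for a set of contingency tables
#'
#' Computes all four disproportionality statistics per PT, applies the
#' Bonferroni correction over the PTs evaluated in the run, and flags the
#' consensus signals. The gamma-Poisson shrinker needs hyperparameters
#' estimated on a large cell set: pass a [gps_fit()] result via
#' `gps_params` (the pipeline fits it on the full drug-by-event cell set);
#' if omitted, the fit is attempted on the supplied tables themselves.
#'
#' @param tables Output of [build_contingency()].
#' @param priors BCPNN priors ([bcpnn_priors()]).
#' @param gps_params A `gps_params` object from [gps_fit()], or `NULL`.
#' @param thresholds Consensus thresholds ([signal_thresholds()]).
#' @param bonferroni Apply Bonferroni across PTs (`TRUE`) or use raw
#'   p-values.
#' @return Tibble with columns `pt, a, ror, ror_lo, ror_hi, prr, chi2,
#'   p_value, p_adjusted, ic, ic_sd, ic025, ebgm, eb05, is_signal`.
#' @export
signal_table <- function(tables, priors = bcpnn_priors(),
                         gps_params = NULL,
                         thresholds = signal_thresholds(),
                         bonferroni = TRUE) {
  if (is.null(gps_params)) {
    gps_params <- gps_fit(
      tibble::tibble(a = tables$a,
                     e = (tables$a + tables$b) * (tables$a + tables$c) / tables$n))
  }
  e <- (tables$a + tables$b) * (tables$a + tables$c) / tables$n
  out <- dplyr::bind_cols(
    tables["pt"], tables["a"],
    ror(tables$a, tables$b, tables$c, tables$d),
    prr(tables$a, tables$b, tables$c, tables$d),
    bcpnn_ic(tables$a, tables$b, tables$c, tables$d, priors),
    gps_score(tables$a, e, gps_params)
  )
  out$p_adjusted <- if (bonferroni) bonferroni_adjust(out$p_value) else
    out$p_value
  out$is_signal <- consensus(out, thresholds)
  out[c("pt", "a", "ror", "ror_lo", "ror_hi", "prr", "chi2", "p_value",
        "p_adjusted", "ic", "ic_sd", "ic025", "ebgm", "eb05", "is_signal")]
}

#' Write a signal table TSV (fixed column order, 4 significant digits)
#'
#' @param signals Output of [signal_table()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_signal_tsv <- function(signals, path) {
  out <- signals[c("pt", "a", "ror", "ror_lo", "ror_hi", "prr", "chi2",
                   "p_value", "p_adjusted", "ic", "ic025", "ebgm", "eb05",
                   "is_signal")]
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], signif, digits = 4)
  readr::write_tsv(out, path)
  invisible(path)
}
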