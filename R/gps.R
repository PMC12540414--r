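#' Construct gamma-Poisson shrinker hyperparameters
#'
#' The empirical-Bayes gamma-Poisson shrinker models the relative report
#' rate `lambda` of each drug-event cell as drawn from a two-component
#' gamma mixture prior `w Gamma(alpha1, beta1) + (1-w) Gamma(alpha2,
#' beta2)` (shape/rate parameterization); observed counts are Poisson with
#' mean `lambda E` where `E` is the independence expectation.
#'
#' @param alpha1,beta1 Shape and rate of the first mixture component.
#' @param alpha2,beta2 Shape and rate of the second component.
#' @param w Mixture weight of the first component, in (0, 1).
#' @param loglik,convergence,n_cells Optional fit metadata (filled by
#'   [gps_fit()]).
#' @return A list of class `gps_params`.
#' @export
gps_params <- function(alpha1, beta1, alpha2, beta2, w,
                       loglik = NA_real_, convergence = NA_integer_,
                       n_cells = NA_integer_) {
  stopifnot(alpha1 > 0, beta1 > 0, alpha2 > 0, beta2 > 0, w > 0, w < 1)
  structure(list(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2,
                 beta2 = beta2, w = w, loglik = loglik,
                 convergence = convergence, n_cells = n_cells),
            class = "gps_params")
}

#' @export
print.gps_params <- function(x, ...) {
  cat("Gamma-Poisson shrinker hyperparameters\n")
  cat(sprintf("  component 1: Gamma(shape = %.4g, rate = %.4g), weight %.3f\n",
              x$alpha1, x$beta1, x$w))
  cat(sprintf("  component 2: Gamma(shape = %.4g, rate = %.4g), weight %.3f\n",
              x$alpha2, x$beta2, 1 - x$w))
  if (!is.na(x$loglik)) {
    cat(sprintf("  log-likelihood %.3f over %d cells (convergence %d)\n",
                x$loglik, x$n_cells, x$convergence))
  }
  invisible(x)
}

# marginal log-likelihood of observed counts under the mixture prior:
# each component marginal is negative binomial with size alpha_j and
# prob beta_j / (beta_j + E)
gps_loglik <- function(theta, a, e) {
  f1 <- suppressWarnings(
    dnbinom(a, size = theta[1], prob = theta[2] / (theta[2] + e)))
  f2 <- suppressWarnings(
    dnbinom(a, size = theta[3], prob = theta[4] / (theta[4] + e)))
  mix <- theta[5] * f1 + (1 - theta[5]) * f2
  if (any(!is.finite(mix))) return(-Inf)
  sum(log(pmax(mix, 1e-300)))
}

#' Fit the shrinker hyperparameters by marginal maximum likelihood
#'
#' Maximizes the summed log marginal likelihood of the observed cell
#' counts over the five hyperparameters, using multi-start quasi-Newton
#' optimization on an unconstrained transform (log shapes/rates, logit
#' weight). The canonical starting point is
#' `(0.2, 0.1, 2, 4, 1/3)`; additional fixed starts guard against local
#' optima.
#'
#' @param cells Tibble (or data frame) with columns `a` (observed count)
#'   and `e` (independence-expected count, `> 0`). At least `min_cells`
#'   rows are required for a stable five-parameter fit.
#' @param starts Optional list of numeric length-5 starting values
#'   `(alpha1, beta1, alpha2, beta2, w)`.
#' @param min_cells Minimum number of cells.
#' @return A `gps_params` object carrying the final log-likelihood and
#'   convergence code.
#' @export
gps_fit <- function(cells, starts = NULL, min_cells = 100L) {
  a <- cells$a
  e <- cells$e
  stopifnot(length(a) == length(e))
  if (length(a) < min_cells) {
    stop("gps_fit needs at least ", min_cells, " drug-event cells (got ",
         length(a), ")", call. = FALSE)
  }
  if (any(e <= 0)) stop("all expected counts must be > 0", call. = FALSE)
  if (all(a == 0)) {
    stop("degenerate cell set: every observed count is zero", call. = FALSE)
  }

  if (is.null(starts)) {
    starts <- list(
      c(0.2, 0.1, 2, 4, 1 / 3),
      c(1, 1, 1, 1, 0.5),
      c(0.5, 0.25, 5, 10, 0.2),
      c(2, 4, 0.2, 0.1, 2 / 3)
    )
  }
  to_eta <- function(th) c(log(th[1:4]), log(th[5] / (1 - th[5])))
  to_theta <- function(eta) c(exp(eta[1:4]), 1 / (1 + exp(-eta[5])))
  nll <- function(eta) {
    v <- -gps_loglik(to_theta(eta), a, e)
    if (!is.finite(v)) 1e12 else v
  }

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(to_eta(s), nll, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-10)),
      error = function(err) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop("gps_fit: optimization failed from every start", call. = FALSE)
  }
  th <- to_theta(best$par)
  out <- gps_params(th[1], th[2], th[3], th[4], th[5],
                    loglik = -best$value, convergence = best$convergence,
                    n_cells = length(a))
  if (best$convergence != 0) {
    cond <- simpleError(paste0("gps_fit did not converge (code ",
                               best$convergence, ")"))
    cond$best_so_far <- out
    stop(cond)
  }
  out
}

#' Posterior shrinkage score for one or more cells
#'
#' Given hyperparameters, the posterior on the relative report rate of a
#' cell with observed count `a` and expectation `E` is again a
#' two-component gamma mixture with components
#' `Gamma(alpha_j + a, beta_j + E)` and weights proportional to the
#' component marginal likelihoods. `EBGM = 2^{E[log2 lambda | a]}` via the
#' digamma closed form, and `EB05` is the 5th percentile of the posterior
#' mixture, found by bracketed root search on its CDF.
#'
#' @param a Observed counts (vector).
#' @param e Expected counts (vector, `> 0`).
#' @param params A `gps_params` object.
#' @param quantile_probs Lower quantile reported as `eb05`.
#' @param tol Root-finding tolerance on the CDF inversion.
#' @return Tibble with columns `ebgm, eb05`.
#' @export
gps_score <- function(a, e, params, quantile_probs = 0.05, tol = 1e-8) {
  stopifnot(inherits(params, "gps_params"))
  if (any(e <= 0)) stop("expected counts must be > 0", call. = FALSE)
  if (any(a < 0)) stop("observed counts must be >= 0", call. = FALSE)

  f1 <- dnbinom(a, size = params$alpha1, prob = params$beta1 / (params$beta1 + e))
  f2 <- dnbinom(a, size = params$alpha2, prob = params$beta2 / (params$beta2 + e))
  q1 <- params$w * f1
  q2 <- (1 - params$w) * f2
  qn <- q1 / (q1 + q2)

  s1 <- params$alpha1 + a; r1 <- params$beta1 + e
  s2 <- params$alpha2 + a; r2 <- params$beta2 + e
  mean_log <- qn * (digamma(s1) - log(r1)) + (1 - qn) * (digamma(s2) - log(r2))
  ebgm <- exp(mean_log)

  eb05 <- vapply(seq_along(a), function(i) {
    cdf <- function(x) {
      qn[i] * pgamma(x, shape = s1[i], rate = r1[i]) +
        (1 - qn[i]) * pgamma(x, shape = s2[i], rate = r2[i]) - quantile_probs
    }
    hi <- max(qgamma(quantile_probs, shape = s1[i], rate = r1[i]),
              qgamma(quantile_probs, shape = s2[i], rate = r2[i]))
    lo <- min(qgamma(quantile_probs, shape = s1[i], rate = r1[i]),
              qgamma(quantile_probs, shape = s2[i], rate = r2[i]))
    if (cdf(lo) >= 0) return(lo)
    if (cdf(hi) <= 0) return(hi)
    uniroot(cdf, lower = lo, upper = hi, tol = tol)$root
  }, numeric(1))

  tibble::tibble(ebgm = ebgm, eb05 = eb05)
}
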