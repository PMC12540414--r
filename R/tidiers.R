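#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Weibull time-to-onset fit
#'
#' @param x A `weibull_fit` object.
#' @param ... Unused.
#' @return One row per parameter (`shape`, `scale`) with estimate, CI
#'   bounds and the bootstrap goodness-of-fit p-values, mirroring the
#'   conventional onset-model report table.
#' @method tidy weibull_fit
#' @export
tidy.weibull_fit <- function(x, ...) {
  tibble::tibble(
    parameter = c("shape", "scale"),
    estimate = c(x$shape, x$scale),
    ci_lower = c(x$shape_ci[1], x$scale_ci[1]),
    ci_upper = c(x$shape_ci[2], x$scale_ci[2]),
    ks_p = x$ks_p,
    ad_p = x$ad_p
  )
}

#' Glance at a Weibull time-to-onset fit
#'
#' @param x A `weibull_fit` object.
#' @param ... Unused.
#' @return One-row tibble with the estimates, hazard classification,
#'   sample size and log-likelihood.
#' @method glance weibull_fit
#' @export
glance.weibull_fit <- function(x, ...) {
  tibble::tibble(shape = x$shape, scale = x$scale,
                 hazard_class = x$hazard_class, n_used = x$n_used,
                 loglik = x$loglik, ks_p = x$ks_p, ad_p = x$ad_p)
}

#' Tidy fitted gamma-Poisson shrinker hyperparameters
#'
#' @param x A `gps_params` object.
#' @param ... Unused.
#' @return One row per mixture component with shape, rate, mean and
#'   weight.
#' @method tidy gps_params
#' @export
tidy.gps_params <- function(x, ...) {
  tibble::tibble(
    component = c(1L, 2L),
    shape = c(x$alpha1, x$alpha2),
    rate = c(x$beta1, x$beta2),
    mean = c(x$alpha1 / x$beta1, x$alpha2 / x$beta2),
    weight = c(x$w, 1 - x$w)
  )
}

#' Glance at fitted gamma-Poisson shrinker hyperparameters
#'
#' @param x A `gps_params` object.
#' @param ... Unused.
#' @return One-row tibble with log-likelihood, convergence code and cell
#'   count.
#' @method glance gps_params
#' @export
glance.gps_params <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, convergence = x$convergence,
                 n_cells = x$n_cells)
}
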