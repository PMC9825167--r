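#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a shortening-rate estimate
#'
#' @param x A `rate_estimate` (from [rate_diffquot()] or
#'   [rate_regression()]).
#' @param ... Unused.
#' @return One-row tibble with `clone_id`, `condition`, `method`,
#'   `estimate` (bp/PD, shortening positive), `std.error`, `n_points`.
#' @export
tidy.rate_estimate <- function(x, ...) {
  tibble::tibble(
    clone_id = x$clone_id, condition = x$condition, method = x$method,
    estimate = x$rate, std.error = x$std_error, n_points = x$n_points
  )
}

#' Glance at a shortening-rate estimate
#'
#' @param x A `rate_estimate`.
#' @param ... Unused.
#' @return One-row tibble with `method`, `rate_bp_per_pd`, `r.squared`
#'   (`NA` for the difference-quotient method) and `n_points`.
#' @export
glance.rate_estimate <- function(x, ...) {
  r2 <- if (!is.null(x$fit)) {
    suppressWarnings(summary(x$fit))$r.squared
  } else NA_real_
  tibble::tibble(method = x$method, rate_bp_per_pd = x$rate,
                 r.squared = r2, n_points = x$n_points)
}

#' Tidy a SAS-rate comparison
#'
#' @param x A `sas_comparison` (from [compare_sas()]).
#' @param ... Unused.
#' @return Tibble with one row per group: `condition`, `n`,
#'   `mean_pd_to_min`, `sd_pd_to_min`.
#' @export
tidy.sas_comparison <- function(x, ...) {
  tibble::tibble(
    condition = c(x$condition_a, x$condition_b),
    n = c(length(x$values_a), length(x$values_b)),
    mean_pd_to_min = c(x$mean_a, x$mean_b),
    sd_pd_to_min = c(stats::sd(x$values_a), stats::sd(x$values_b))
  )
}

#' Glance at a SAS-rate comparison
#'
#' @param x A `sas_comparison`.
#' @param ... Unused.
#' @return One-row tibble with `mean_difference`, `statistic`, `p.value`,
#'   `method` (`NA` columns when the t-test could not be run).
#' @export
glance.sas_comparison <- function(x, ...) {
  tibble::tibble(
    mean_difference = x$mean_difference,
    statistic = if (is.null(x$htest)) NA_real_ else
      unname(x$htest$statistic),
    p.value = if (is.null(x$htest)) NA_real_ else x$htest$p.value,
    method = if (is.null(x$htest)) NA_character_ else x$htest$method
  )
}
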