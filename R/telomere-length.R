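#' Detect bands on a densitometry lane profile
#'
#' Finds local intensity maxima whose topographic prominence exceeds
#' `min_prominence` times the profile's maximum intensity, and returns their
#' positions on the migration coordinate. The prominence of a peak is its
#' height above the higher of the two deepest valleys separating it from
#' taller terrain (or the profile edge).
#'
#' @param profile A `lane_profile` tibble with `coordinate` (strictly
#'   increasing) and `intensity` (non-negative) columns.
#' @param min_prominence Prominence threshold as a fraction of the maximum
#'   intensity (default 0.05).
#' @return Numeric vector of band positions (coordinates), in increasing
#'   order. Errors if no peak exceeds the threshold.
#' @export
detect_bands <- function(profile, min_prominence = 0.05) {
  stopifnot(all(c("coordinate", "intensity") %in% names(profile)))
  x <- profile$coordinate
  y <- profile$intensity
  n <- length(y)
  if (n == 0) stop("empty profile", call. = FALSE)
  if (any(diff(x) <= 0)) {
    stop("coordinates must be strictly increasing", call. = FALSE)
  }
  if (any(y < 0)) stop("intensities must be non-negative", call. = FALSE)
  # local maxima; for plateaus keep the first sample of the flat top
  is_peak <- vapply(seq_len(n), function(i) {
    left_lower <- i == 1 || y[i - 1] < y[i]
    right_not_higher <- i == n || y[i + 1] <= y[i]
    left_lower && right_not_higher
  }, logical(1))
  peaks <- which(is_peak)
  prominence <- vapply(peaks, function(i) {
    side_min <- function(idx) {
      if (length(idx) == 0) return(min(y))
      higher <- idx[y[idx] > y[i]]
      if (length(higher) == 0) return(min(y[idx]))
      nearest <- if (all(idx < i)) max(higher) else min(higher)
      between <- idx[if (all(idx < i)) idx > nearest else idx < nearest]
      if (length(between) == 0) y[i] else min(y[between])
    }
    left <- side_min(seq_len(i - 1))
    right <- side_min(if (i < n) (i + 1):n else integer(0))
    y[i] - max(left, right)
  }, numeric(1))
  keep <- prominence > 0 & prominence >= min_prominence * max(y)
  if (!any(keep)) stop("no peak above threshold", call. = FALSE)
  x[peaks[keep]]
}

#' Relative telomere lengths from band positions
#'
#' Normalizes band positions (distance from x = 0 on the rotated blot image,
#' a monotone proxy for telomere length) by the position of the longest
#' telomere, which is set to 1; ties share the maximal value and the first
#' occurrence is taken as the reference band.
#'
#' @param positions Band positions, all > 0.
#' @return Fractions in `(0, 1]`, same order as the input.
#' @examples
#' relative_length(c(2, 4, 8)) # 0.25 0.50 1.00
#' @export
relative_length <- function(positions) {
  if (length(positions) == 0) stop("no positions given", call. = FALSE)
  if (any(positions <= 0)) {
    stop("positions must be positive", call. = FALSE)
  }
  positions / max(positions)
}

#' Percent telomere length relative to a reference first value
#'
#' Expresses lengths as percent of the first measurement of the reference
#' (empty-vector) strain, the '% telomere length' convention.
#'
#' @param lengths Lengths (bp or relative units).
#' @param reference_first First length of the reference strain, > 0.
#' @return Percent series.
#' @export
percent_of_first <- function(lengths, reference_first) {
  if (!is.finite(reference_first) || reference_first <= 0) {
    stop("`reference_first` must be positive", call. = FALSE)
  }
  100 * lengths / reference_first
}

new_rate_estimate <- function(clone_id, condition, method, rate, n_points,
                              std_error = NA_real_, fit = NULL) {
  structure(
    list(clone_id = clone_id, condition = condition, method = method,
         rate = rate, n_points = n_points, std_error = std_error, fit = fit),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("Telomere shortening rate (%s): %.4g bp/PD (n = %d points)\n",
              x$method, x$rate, x$n_points))
  invisible(x)
}

#' Shortening rate by consecutive difference quotients
#'
#' For every consecutive pair of measurements the length drop is divided by
#' the PD difference, and the mean of these bp/PD ratios is returned.
#' Positive rates mean shortening.
#'
#' @param lengths Telomere lengths, bp (>= 2 values).
#' @param pds Corresponding cumulative population doublings, strictly
#'   increasing.
#' @param clone_id,condition Labels carried into the estimate.
#' @return A `rate_estimate` object (`method = "diffquot"`).
#' @examples
#' rate_diffquot(c(350, 340, 330), c(0, 10, 20))$rate # 1
#' @export
rate_diffquot <- function(lengths, pds, clone_id = NA_character_,
                          condition = NA_character_) {
  if (length(lengths) != length(pds) || length(lengths) < 2) {
    stop("need >= 2 paired (length, pd) points", call. = FALSE)
  }
  if (any(diff(pds) == 0)) stop("duplicate PD values", call. = FALSE)
  if (any(diff(pds) < 0)) stop("PDs must be strictly increasing",
                               call. = FALSE)
  ratios <- -diff(lengths) / diff(pds)
  new_rate_estimate(clone_id, condition, "diffquot", mean(ratios),
                    length(lengths),
                    std_error = stats::sd(ratios) / sqrt(length(ratios)))
}

#' Shortening rate by linear regression
#'
#' Ordinary least-squares slope of length on PD ("slope of the shortening
#' trendline"), sign-flipped so that shortening is a positive rate.
#'
#' @inheritParams rate_diffquot
#' @return A `rate_estimate` object (`method = "regression"`) carrying the
#'   `lm` fit.
#' @export
rate_regression <- function(lengths, pds, clone_id = NA_character_,
                            condition = NA_character_) {
  if (length(lengths) != length(pds) || length(lengths) < 3) {
    stop("need >= 3 paired (length, pd) points", call. = FALSE)
  }
  if (length(unique(pds)) < 2) {
    stop("degenerate design: all PDs equal", call. = FALSE)
  }
  fit <- stats::lm(lengths ~ pds)
  slope <- unname(stats::coef(fit)[2])
  # suppressed: summary.lm warns on (legitimate) perfect fits
  se <- unname(suppressWarnings(summary(fit))$coefficients[2, 2])
  new_rate_estimate(clone_id, condition, "regression", -slope,
                    length(lengths), std_error = se, fit = fit)
}

#' Fold change between two shortening-rate estimates
#'
#' Treatment rate divided by control rate (e.g. RNH1 over the same-day EV
#' sample). Both estimates must come from the same method.
#'
#' @param treatment,control `rate_estimate` objects.
#' @return Fold change (numeric scalar).
#' @export
rate_fold_change <- function(treatment, control) {
  stopifnot(inherits(treatment, "rate_estimate"),
            inherits(control, "rate_estimate"))
  if (treatment$method != control$method) {
    stop("method mismatch: ", treatment$method, " vs ", control$method,
         call. = FALSE)
  }
  if (control$rate == 0) stop("zero control rate", call. = FALSE)
  treatment$rate / control$rate
}

#' Shortening rates for a table of length-vs-PD series
#'
#' Data-frame-first wrapper applying [rate_diffquot()] or
#' [rate_regression()] per clone and condition.
#'
#' @param data Tibble with columns `clone_id`, `condition`, `pd`,
#'   `length_bp`.
#' @param method `"regression"` (default) or `"diffquot"`.
#' @return Tibble with one row per clone: `clone_id`, `condition`, `method`,
#'   `rate_bp_per_pd`, `std_error`, `n_points`.
#' @export
shortening_rates <- function(data, method = c("regression", "diffquot")) {
  method <- match.arg(method)
  need <- c("clone_id", "condition", "pd", "length_bp")
  if (!all(need %in% names(data))) {
    stop("data needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  fun <- if (method == "regression") rate_regression else rate_diffquot
  data |>
    dplyr::group_by(.data$clone_id, .data$condition) |>
    dplyr::group_split() |>
    purrr::map(function(df) {
      df <- dplyr::arrange(df, .data$pd)
      est <- fun(df$length_bp, df$pd, clone_id = df$clone_id[1],
                 condition = df$condition[1])
      tibble::tibble(
        clone_id = est$clone_id, condition = est$condition,
        method = est$method, rate_bp_per_pd = est$rate,
        std_error = est$std_error, n_points = est$n_points
      )
    }) |>
    purrr::list_rbind()
}
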