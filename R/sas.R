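#' Two-point smoothing of a potential profile
#'
#' Replaces the series by the averages of consecutive value pairs, the
#' smoothing applied to percent-replicative-potential profiles before minima
#' detection to damp stochastic OD fluctuations. Output is one element
#' shorter than the input. Applied once (single pass) by default throughout
#' the package; see `passes` to repeat.
#'
#' @param values Numeric series, length >= 2.
#' @param passes Number of smoothing passes (default 1).
#' @return Numeric series of length `length(values) - passes`.
#' @examples
#' smooth_pairwise(c(0, 2, 4)) # 1 3
#' @export
smooth_pairwise <- function(values, passes = 1) {
  stopifnot(passes >= 1)
  for (p in seq_len(passes)) {
    if (length(values) < 2) {
      stop("need at least 2 values to smooth", call. = FALSE)
    }
    n <- length(values)
    values <- (values[-n] + values[-1]) / 2
  }
  values
}

#' Admissible local minima of a series
#'
#' Position `i` is a local minimum iff the full window of `k` values on each
#' side exists and none of them is strictly smaller than `values[i]`
#' ("no other values in a neighborhood of four were inferior", with the
#' neighborhood read as k per side). Ties never disqualify a candidate, but
#' tied positions are deduplicated: within a flat run (or tied candidates
#' within one window) only the earliest position is kept.
#'
#' @param values Numeric series, length > 2k.
#' @param k Window half-width (values per side); default 4.
#' @return Integer positions of admissible minima (possibly empty).
#' @examples
#' find_local_minima(c(9, 8, 7, 6, 5, 6, 7, 8, 9, 10, 11), k = 4) # 5
#' @export
find_local_minima <- function(values, k = 4) {
  n <- length(values)
  k <- as.integer(k)
  stopifnot(k >= 1)
  if (n <= 2 * k) {
    stop("series too short for any full window (need length > 2k)",
         call. = FALSE)
  }
  cand <- integer(0)
  for (i in (k + 1):(n - k)) {
    window <- values[(i - k):(i + k)]
    if (!any(window < values[i])) cand <- c(cand, i)
  }
  keep <- logical(length(cand))
  for (j in seq_along(cand)) {
    i <- cand[j]
    earlier_tie <- cand[cand < i & cand >= i - k]
    keep[j] <- !any(values[earlier_tie] == values[i])
  }
  cand[keep]
}

#' Select the minimum used for the SAS-rate count
#'
#' Minima falling in the first few days are excluded because growth is
#' frequently erratic right after the transfer from solid to liquid medium;
#' among the remaining minima the earliest is returned. A `forced` position
#' overrides the rule entirely, supporting the manual cross-condition
#' profile-similarity criterion, which is never automated.
#'
#' @param minima Integer positions in the smoothed series (from
#'   [find_local_minima()]).
#' @param series The `potential_series` the minima refer to; smoothed
#'   position `i` inherits the day of record `i`.
#' @param exclude_days Minima on days `<= exclude_days` are dropped
#'   (default 3).
#' @param forced Optional position returned verbatim.
#' @return The selected position (integer).
#' @export
select_minimum <- function(minima, series, exclude_days = 3, forced = NULL) {
  if (!is.null(forced)) return(as.integer(forced))
  if (length(minima) == 0) stop("no admissible minimum", call. = FALSE)
  days <- series$day[minima]
  ok <- minima[days > exclude_days]
  if (length(ok) == 0) {
    stop("no admissible minimum after excluding the first ", exclude_days,
         " days", call. = FALSE)
  }
  ok[1]
}

#' Population doublings from start to the selected minimum
#'
#' The SAS rate statistic: cumulative PD at the selected minimum minus
#' cumulative PD at the start of the propagation.
#'
#' @param series A `potential_series` with `pd_cumulative`.
#' @param selected Position of the selected minimum (index into `series`
#'   rows; smoothed position `i` maps to record `i`).
#' @return PD count (numeric, >= 0 for non-degenerate series).
#' @export
sas_pd_count <- function(series, selected) {
  selected <- as.integer(selected)
  stopifnot(selected >= 1, selected <= nrow(series))
  series$pd_cumulative[selected] - series$pd_cumulative[1]
}

#' SAS rate per clone
#'
#' Full survivor-associated-senescence rate measurement on one or more
#' clones: the percent-potential profile is smoothed pairwise, admissible
#' local minima are found with a +/-`k` window, minima in the first
#' `exclude_days` days are discarded, and the PDs from the start to the
#' earliest remaining minimum are counted.
#'
#' @param potential A `potential_series` tibble (one or more clones;
#'   grouped internally by `clone_id` and `condition`).
#' @param k Minima window half-width (default 4).
#' @param exclude_days Early-day exclusion (default 3).
#' @param forced Optional named integer vector of forced minima positions,
#'   names being `clone_id` values.
#' @param passes Smoothing passes (default 1).
#' @return A `sas_result` tibble with one row per clone: `clone_id`,
#'   `condition`, `n_minima`, `minima_indices` (list column),
#'   `selected_index`, `day_min`, `pd_to_min`, `potential_at_min`.
#' @export
sas_rate <- function(potential, k = 4, exclude_days = 3, forced = NULL,
                     passes = 1) {
  need <- c("clone_id", "condition", "day", "pd_cumulative", "potential_pct")
  if (!all(need %in% names(potential))) {
    stop("potential series needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  one <- function(df) {
    df <- dplyr::arrange(df, .data$day)
    sm <- smooth_pairwise(df$potential_pct, passes = passes)
    minima <- find_local_minima(sm, k = k)
    f <- if (!is.null(forced)) unname(forced[df$clone_id[1]]) else NULL
    if (!is.null(f) && is.na(f)) f <- NULL
    sel <- select_minimum(minima, df, exclude_days = exclude_days, forced = f)
    tibble::tibble(
      clone_id = df$clone_id[1],
      condition = df$condition[1],
      n_minima = length(minima),
      minima_indices = list(minima),
      selected_index = sel,
      day_min = df$day[sel],
      pd_to_min = sas_pd_count(df, sel),
      potential_at_min = sm[sel]
    )
  }
  out <- potential |>
    dplyr::group_by(.data$clone_id, .data$condition) |>
    dplyr::group_split() |>
    purrr::map(one) |>
    purrr::list_rbind()
  class(out) <- c("sas_result", class(out))
  out
}

#' Compare SAS rates between two groups of clones
#'
#' Thin wrapper around the unpaired two-tailed t-test on the per-clone
#' PD-to-minimum values of two conditions (Student by default, Welch on
#' request).
#'
#' @param group_a,group_b `sas_result` tibbles (from [sas_rate()]).
#' @param welch Use Welch's correction (default `FALSE`, plain Student).
#' @return A `sas_comparison` object: list with per-group values and means,
#'   the mean difference (`a - b`), and the `htest` object (`NULL` when a
#'   group has fewer than 2 clones). Has [tidy()]/[glance()] methods.
#' @export
compare_sas <- function(group_a, group_b, welch = FALSE) {
  if (nrow(group_a) == 0 || nrow(group_b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  a <- group_a$pd_to_min
  b <- group_b$pd_to_min
  htest <- if (length(a) >= 2 && length(b) >= 2) {
    stats::t.test(a, b, var.equal = !welch)
  } else NULL
  structure(
    list(
      condition_a = group_a$condition[1],
      condition_b = group_b$condition[1],
      values_a = a, values_b = b,
      mean_a = mean(a), mean_b = mean(b),
      mean_difference = mean(a) - mean(b),
      htest = htest
    ),
    class = "sas_comparison"
  )
}

#' @export
print.sas_comparison <- function(x, ...) {
  cat("SAS rate comparison (PDs to selected minimum)\n")
  cat(sprintf("  %s: mean %.2f PD (n = %d)\n", x$condition_a, x$mean_a,
              length(x$values_a)))
  cat(sprintf("  %s: mean %.2f PD (n = %d)\n", x$condition_b, x$mean_b,
              length(x$values_b)))
  cat(sprintf("  mean difference: %.2f PD\n", x$mean_difference))
  if (!is.null(x$htest)) {
    cat(sprintf("  %s: t = %.3f, p = %.4g\n", x$htest$method,
                x$htest$statistic, x$htest$p.value))
  }
  invisible(x)
}
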