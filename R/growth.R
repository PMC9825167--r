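#' Population doublings between two optical densities
#'
#' PDs realized by a culture growing from `od_start` to `od_end`, defined as
#' `log2(od_end / od_start)`. Negative values are allowed (a culture that
#' shrank); non-positive ODs are an error.
#'
#' @param od_end,od_start OD600 readings, both > 0. Vectorized.
#' @return Population doublings (numeric).
#' @examples
#' population_doublings(0.08, 0.01) # 3
#' @export
population_doublings <- function(od_end, od_start) {
  if (any(!is.finite(od_end)) || any(!is.finite(od_start)) ||
      any(od_end <= 0) || any(od_start <= 0)) {
    stop("OD values must be positive and finite", call. = FALSE)
  }
  log2(od_end / od_start)
}

#' Percent replicative potential of a clone
#'
#' Converts daily OD600 records into the percent replicative-potential series:
#' every `od_end` of `series` is divided by the *day-0* `od_end` of the
#' reference clone (the empty-vector transformant, or the RNH201-complemented
#' clone for the tel- comparison) and scaled to percent. The reference's own
#' day-0 record therefore maps to exactly 100. Days must be consecutive: the
#' protocol is strictly daily and series with gaps are rejected, not
#' interpolated.
#'
#' @param series A growth series: tibble with columns `clone_id`, `condition`,
#'   `day`, `od_start`, `od_end` (and optionally `pd_cumulative`, recomputed
#'   from the ODs when absent).
#' @param reference Reference growth series (defaults to `series` itself).
#' @param day_matched If `TRUE`, divide by the reference `od_end` of the
#'   *same* day instead of its day-0 value (non-default variant).
#' @return A `potential_series` tibble with columns `clone_id`, `condition`,
#'   `day`, `pd_cumulative`, `potential_pct` (plus any sidecar columns of
#'   `series`, e.g. simulated `length_bp`).
#' @examples
#' g <- tibble::tibble(clone_id = "a", condition = "EV", day = 0:3,
#'                     od_start = 0.01, od_end = c(0.32, 0.30, 0.16, 0.28))
#' replicative_potential(g)
#' @export
replicative_potential <- function(series, reference = series,
                                  day_matched = FALSE) {
  need <- c("clone_id", "condition", "day", "od_start", "od_end")
  for (df in list(series, reference)) {
    if (!all(need %in% names(df))) {
      stop("growth series needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
  }
  check_daily <- function(df, what) {
    d <- sort(unique(df$day))
    if (any(diff(d) != 1)) {
      stop(what, " has missing days; the protocol is strictly daily",
           call. = FALSE)
    }
  }
  check_daily(series, "`series`")
  check_daily(reference, "`reference`")
  day0 <- min(reference$day)
  ref0 <- reference$od_end[reference$day == day0][1]
  if (!is.finite(ref0) || ref0 <= 0) {
    stop("missing or non-positive day-0 reference OD", call. = FALSE)
  }
  out <- series
  if (day_matched) {
    idx <- match(out$day, reference$day)
    if (anyNA(idx)) stop("day misalignment with reference", call. = FALSE)
    out$potential_pct <- 100 * out$od_end / reference$od_end[idx]
  } else {
    out$potential_pct <- 100 * out$od_end / ref0
  }
  if (!"pd_cumulative" %in% names(out)) {
    out$pd_cumulative <- cumsum(population_doublings(out$od_end, out$od_start))
  }
  out <- dplyr::relocate(out, "clone_id", "condition", "day", "pd_cumulative",
                         "potential_pct")
  class(out) <- c("potential_series", setdiff(class(out), "growth_series"))
  out
}
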