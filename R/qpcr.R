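#' Expression as percent of a reference transcript
#'
#' Converts a (target, reference) Ct pair into percent of the reference
#' transcript via `100 * efficiency^-(ct_target - ct_reference)`; with the
#' default perfect doubling efficiency this is `100 * 2^-dCt`, the
#' '% actin mRNA' scale used for TERRA.
#'
#' @param ct_target,ct_reference Threshold cycles (finite). Vectorized.
#' @param efficiency Amplification efficiency per cycle (default 2, perfect
#'   doubling).
#' @return Percent of reference (numeric).
#' @examples
#' percent_reference(23, 23) # 100
#' percent_reference(24, 23) # 50
#' @export
percent_reference <- function(ct_target, ct_reference, efficiency = 2) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference))) {
    stop("missing Ct value", call. = FALSE)
  }
  stopifnot(efficiency > 1)
  100 * efficiency^(-(ct_target - ct_reference))
}

#' Quantify a Ct table on the percent-of-reference scale
#'
#' Data-frame-first convenience: adds a `pct_reference` column to a long Ct
#' table (one row per sample x locus with paired target/reference Cts).
#'
#' @param data Tibble with columns `ct_target` and `ct_reference`.
#' @param efficiency Amplification efficiency (default 2).
#' @return `data` with `pct_reference` appended.
#' @export
terra_quant <- function(data, efficiency = 2) {
  if (!all(c("ct_target", "ct_reference") %in% names(data))) {
    stop("data needs `ct_target` and `ct_reference` columns", call. = FALSE)
  }
  dplyr::mutate(data, pct_reference = percent_reference(
    .data$ct_target, .data$ct_reference, efficiency = efficiency
  ))
}

#' Fold change relative to a reference group
#'
#' Divides each record's percent-of-reference value by the arithmetic mean of
#' the reference group at the same locus (the 'fold change to EV'
#' convention). Averaging happens after the exponential transform, on the
#' percent scale.
#'
#' @param data Tibble with columns `group`, `locus` and `pct_reference` (see
#'   [terra_quant()]).
#' @param reference_group Label of the reference group (e.g. `"EV"`).
#' @return `data` with a `fold_change` column appended.
#' @export
fold_change_to_group <- function(data, reference_group) {
  need <- c("group", "locus", "pct_reference")
  if (!all(need %in% names(data))) {
    stop("data needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  ref <- data |>
    dplyr::filter(.data$group == reference_group) |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(.ref_mean = mean(.data$pct_reference), .groups = "drop")
  missing_loci <- setdiff(unique(data$locus), ref$locus)
  if (length(missing_loci) > 0) {
    stop("empty reference group `", reference_group, "` at locus: ",
         paste(missing_loci, collapse = ", "), call. = FALSE)
  }
  data |>
    dplyr::left_join(ref, by = "locus") |>
    dplyr::mutate(fold_change = .data$pct_reference / .data$.ref_mean) |>
    dplyr::select(-".ref_mean")
}

#' Percent decline of expression across replication
#'
#' Relative drop from the early-S-phase peak to the G2 value,
#' `100 * (early_s - g2) / early_s` — the statistic behind the ~29%
#' (wild-type) and ~33.5% (survivor) TERRA declines as replication completes.
#'
#' @param early_s Early-S-phase expression (> 0). Vectorized.
#' @param g2 G2-phase expression, same units.
#' @return Percent decline (negative if expression rose).
#' @export
cell_cycle_drop <- function(early_s, g2) {
  if (any(!is.finite(early_s)) || any(early_s <= 0)) {
    stop("`early_s` must be positive", call. = FALSE)
  }
  100 * (early_s - g2) / early_s
}

#' Flag suspicious no-RT controls
#'
#' No-reverse-transcriptase controls are accepted in input tables and only
#' validated, never subtracted: a control amplifying within `min_separation`
#' cycles of its RT sample indicates DNA contamination.
#'
#' @param ct_rt Ct of the reverse-transcribed sample.
#' @param ct_no_rt Ct of the matching no-RT control (may be `NA`/`Inf` for
#'   no amplification).
#' @param min_separation Minimum acceptable Ct separation (default 5).
#' @return Logical: `TRUE` where the control is suspicious.
#' @export
flag_no_rt <- function(ct_rt, ct_no_rt, min_separation = 5) {
  sep <- ct_no_rt - ct_rt
  out <- !is.na(sep) & is.finite(sep) & sep < min_separation
  if (any(out)) {
    warning(sum(out), " no-RT control(s) within ", min_separation,
            " cycles of the RT sample", call. = FALSE)
  }
  out
}
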