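#' ChIP enrichment as percent input
#'
#' Immunoprecipitated signal over the dilution-corrected Input signal:
#' `100 * ip / (input / input_fraction)`. The default `input_fraction` of
#' 0.05 corresponds to keeping 50 ul of a 1 ml ChIP extract as Input; R-ChIP
#' dot-blot quantification reuses this with `input_fraction = 1/60`.
#'
#' @param ip_signal IP signal, arbitrary units (>= 0). Vectorized.
#' @param input_signal Input signal, same units (> 0).
#' @param input_fraction Fraction of the extract taken as Input, in (0, 1].
#' @return Percent input.
#' @examples
#' percent_input(2, 8, 0.05) # 1.25
#' @export
percent_input <- function(ip_signal, input_signal, input_fraction = 0.05) {
  if (any(!is.finite(input_signal)) || any(input_signal <= 0)) {
    stop("zero or invalid input signal", call. = FALSE)
  }
  if (any(input_fraction <= 0) || any(input_fraction > 1)) {
    stop("`input_fraction` must be in (0, 1]", call. = FALSE)
  }
  if (any(ip_signal < 0)) stop("negative IP signal", call. = FALSE)
  100 * ip_signal / (input_signal / input_fraction)
}

#' Fold change of ChIP enrichment relative to wild type
#'
#' Survivor percent input divided by the percent input of the isogenic
#' wild type collected on the same day.
#'
#' @param survivor_pct,wildtype_pct Percent-input values (same locus and
#'   day). Vectorized.
#' @return Fold change.
#' @export
fold_change_to_wildtype <- function(survivor_pct, wildtype_pct) {
  if (any(!is.finite(wildtype_pct)) || any(wildtype_pct <= 0)) {
    stop("zero or invalid wild-type value", call. = FALSE)
  }
  survivor_pct / wildtype_pct
}

#' TAP-tag background correction
#'
#' Divides the percent input of the tagged strain by that of the untagged
#' equivalent, removing antibody/bead background; applied before the
#' wild-type fold change in TAP experiments.
#'
#' @param tagged_pct,untagged_pct Percent-input values. Vectorized.
#' @return Corrected ratio.
#' @export
tap_normalize <- function(tagged_pct, untagged_pct) {
  if (any(!is.finite(untagged_pct)) || any(untagged_pct <= 0)) {
    stop("zero or invalid untagged value", call. = FALSE)
  }
  tagged_pct / untagged_pct
}

#' Full ChIP-qPCR normalization chain
#'
#' Data-frame-first normalization of a long ChIP record table: computes
#' percent input per record, optionally applies the TAP untagged correction
#' per (genotype, locus, day), and divides by the reference genotype paired
#' on the same day (falling back to the reference-genotype mean at the locus
#' when no same-day pair exists).
#'
#' @param data Tibble with columns `genotype`, `locus`, `day`, `ip_signal`,
#'   `input_signal`, `input_fraction`, and `tag` when `tap = TRUE`.
#' @param tap Apply the tagged/untagged correction chain (default `FALSE`;
#'   without it, only `tag == "tagged"` rows — or all rows if no `tag`
#'   column — are normalized).
#' @param reference_genotype Genotype used as denominator (default
#'   `"wild-type"`).
#' @return Tibble with one row per non-reference genotype x locus x day:
#'   `genotype`, `locus`, `day`, `fold_change`.
#' @export
chip_fold_change <- function(data, tap = FALSE,
                             reference_genotype = "wild-type") {
  need <- c("genotype", "locus", "day", "ip_signal", "input_signal",
            "input_fraction")
  if (!all(need %in% names(data))) {
    stop("data needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  data <- dplyr::mutate(data, .pct = percent_input(
    .data$ip_signal, .data$input_signal, .data$input_fraction
  ))
  if (tap) {
    if (!"tag" %in% names(data)) {
      stop("`tap = TRUE` needs a `tag` column", call. = FALSE)
    }
    sig <- data |>
      dplyr::group_by(.data$genotype, .data$locus, .data$day) |>
      dplyr::summarise(
        value = tap_normalize(
          mean(.data$.pct[.data$tag == "tagged"]),
          mean(.data$.pct[.data$tag == "untagged"])
        ),
        .groups = "drop"
      )
  } else {
    if ("tag" %in% names(data)) {
      data <- dplyr::filter(data, .data$tag == "tagged")
    }
    sig <- data |>
      dplyr::group_by(.data$genotype, .data$locus, .data$day) |>
      dplyr::summarise(value = mean(.data$.pct), .groups = "drop")
  }
  ref <- dplyr::filter(sig, .data$genotype == reference_genotype)
  if (nrow(ref) == 0) {
    stop("no records for reference genotype `", reference_genotype, "`",
         call. = FALSE)
  }
  ref_day <- dplyr::select(ref, "locus", "day", ref_value = "value")
  ref_mean <- ref |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(ref_locus_mean = mean(.data$value), .groups = "drop")
  sig |>
    dplyr::filter(.data$genotype != reference_genotype) |>
    dplyr::left_join(ref_day, by = c("locus", "day")) |>
    dplyr::left_join(ref_mean, by = "locus") |>
    dplyr::mutate(fold_change = fold_change_to_wildtype(
      .data$value, dplyr::coalesce(.data$ref_value, .data$ref_locus_mean)
    )) |>
    dplyr::select("genotype", "locus", "day", "fold_change")
}
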