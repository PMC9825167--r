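#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a telomere-length trajectory
#'
#' Length versus cumulative PD with HDR events highlighted.
#'
#' @param object A `telo_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.telo_trajectory <- function(object, ...) {
  ev <- dplyr::filter(object, .data$event != "none")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pd, y = .data$length_bp)) +
    ggplot2::geom_line(color = "grey30") +
    ggplot2::geom_point(data = ev,
                        ggplot2::aes(color = .data$event), size = 2) +
    ggplot2::labs(x = "population doublings",
                  y = "telomere length (bp)", color = "HDR event") +
    ggplot2::theme_minimal()
}

#' Plot replicative-potential profiles
#'
#' Percent replicative potential against cumulative PD, one line per clone,
#' colored by condition — the SAS profile view.
#'
#' @param object A `potential_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.potential_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$pd_cumulative, y = .data$potential_pct,
    group = interaction(.data$clone_id, .data$condition),
    color = .data$condition
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "population doublings", y = "% replicative potential",
                  color = "condition") +
    ggplot2::theme_minimal()
}

#' Plot a densitometry lane profile
#'
#' Intensity over the migration coordinate; detected bands (at the given
#' prominence) are marked with vertical lines.
#'
#' @param object A `lane_profile`.
#' @param min_prominence Prominence threshold passed to [detect_bands()];
#'   `NULL` suppresses band marking.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lane_profile <- function(object, min_prominence = 0.05, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$coordinate,
                                            y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "migration coordinate (x = 0 at image edge)",
                  y = "intensity") +
    ggplot2::theme_minimal()
  if (!is.null(min_prominence)) {
    bands <- detect_bands(object, min_prominence = min_prominence)
    p <- p + ggplot2::geom_vline(xintercept = bands, linetype = "dashed",
                                 color = "firebrick")
  }
  p
}

#' Plot a SAS-rate comparison
#'
#' Per-clone PDs-to-minimum by condition with group means, the Fig-4E-style
#' summary view.
#'
#' @param object A `sas_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sas_comparison <- function(object, ...) {
  df <- tibble::tibble(
    condition = rep(c(object$condition_a, object$condition_b),
                    c(length(object$values_a), length(object$values_b))),
    pd_to_min = c(object$values_a, object$values_b)
  )
  means <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition,
                                   y = .data$pd_to_min)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.7) +
    ggplot2::geom_crossbar(
      data = means,
      ggplot2::aes(x = .data$condition, y = .data$mean_pd_to_min,
                   ymin = .data$mean_pd_to_min, ymax = .data$mean_pd_to_min),
      width = 0.4, color = "firebrick"
    ) +
    ggplot2::labs(x = NULL, y = "PDs to selected minimum") +
    ggplot2::theme_minimal()
}
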