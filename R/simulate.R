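#' Simulate a clonal telomere-length trajectory
#'
#' Steps a single telomere through the population doublings implied by
#' `n_days` of daily serial dilution. Per PD the length shrinks by a draw from
#' Normal(`shorten_rate_mean`, `shorten_rate_sd`) truncated to be positive;
#' while the telomere is below `critical_length`, an HDR event fires with
#' probability `hdr_prob_per_pd` per PD. An event is type II (lognormal
#' TG-repeat gain) with probability `type2_fraction`, otherwise type I (fixed
#' `type1_gain`, the Y'-element-like addition). Long telomeres never
#' recombine.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @param clone_id Label carried into the output.
#' @param n_pd Number of PDs to simulate. The default covers `n_days` of
#'   growth at `max_doublings_per_day` with a 25% margin.
#' @return A `telo_trajectory` tibble with columns `clone_id`, `pd`,
#'   `length_bp` and `event` (`"none"`, `"type1"` or `"type2"`).
#' @examples
#' traj <- simulate_telomere_trajectory(sim_config(n_days = 30), seed = 7)
#' head(traj)
#' @export
simulate_telomere_trajectory <- function(config, seed = config$seed,
                                         clone_id = "clone1", n_pd = NULL) {
  validate_sim_config(config)
  if (is.null(n_pd)) {
    n_pd <- ceiling(config$n_days * config$max_doublings_per_day * 1.25) + 2
  }
  withr::local_seed(as.integer(seed))

  length_bp <- numeric(n_pd + 1)
  event <- character(n_pd + 1)
  length_bp[1] <- config$initial_length
  event[1] <- "none"
  for (t in seq_len(n_pd)) {
    cur <- length_bp[t]
    fired <- cur < config$critical_length &&
      stats::runif(1) < config$hdr_prob_per_pd
    if (fired) {
      if (stats::runif(1) < config$type2_fraction) {
        gain <- stats::rlnorm(1, config$type2_gain_log_mean,
                              config$type2_gain_log_sd)
        event[t + 1] <- "type2"
      } else {
        gain <- config$type1_gain
        event[t + 1] <- "type1"
      }
      length_bp[t + 1] <- cur + gain
    } else {
      draw <- stats::rnorm(1, config$shorten_rate_mean, config$shorten_rate_sd)
      # truncate at 0 (clip, preserving the nominal mean to ~0.4% even at
      # low rates); a single PD cannot erode more than half the tract
      draw <- min(max(draw, 0), cur / 2)
      length_bp[t + 1] <- cur - draw
      event[t + 1] <- "none"
    }
  }
  out <- tibble::tibble(
    clone_id = clone_id,
    pd = as.numeric(0:n_pd),
    length_bp = length_bp,
    event = event
  )
  class(out) <- c("telo_trajectory", class(out))
  attr(out, "config") <- config
  out
}

#' Records preceding the first HDR event
#'
#' Shortening-rate estimation is only meaningful on the monotone shortening
#' phase, so this returns the trajectory records strictly before the first
#' annotated HDR event (the whole trajectory if none occurred).
#'
#' @param traj A `telo_trajectory` tibble.
#' @return The leading event-free rows.
#' @export
pre_event_segment <- function(traj) {
  stopifnot(all(c("pd", "length_bp", "event") %in% names(traj)))
  hit <- which(traj$event != "none")
  if (length(hit) == 0) return(traj)
  traj[seq_len(hit[1] - 1L), , drop = FALSE]
}

#' Daily doublings as a function of telomere length
#'
#' Maps the current length of the shortest telomere to the number of
#' population doublings the culture achieves in 24 h. Above `senesce_length`
#' the culture grows at `max_doublings_per_day`; between `senesce_length` and
#' `critical_length` the rate interpolates linearly down to
#' `min_doublings_per_day`; below `critical_length` it keeps falling linearly
#' toward 0 at length 0, so growth is a strictly increasing readout of length
#' everywhere below `senesce_length` and the worst-growth day is always the
#' shortest-telomere day.
#'
#' @param length_bp Telomere length(s), bp.
#' @param config A [sim_config()].
#' @return Doublings per day, same length as `length_bp`.
#' @export
doubling_rate <- function(length_bp, config) {
  lo <- config$critical_length
  hi <- config$senesce_length
  dmin <- config$min_doublings_per_day
  dmax <- config$max_doublings_per_day
  mid <- dmin + (dmax - dmin) * (length_bp - lo) / (hi - lo)
  ifelse(length_bp >= hi, dmax,
         ifelse(length_bp >= lo, mid, dmin * length_bp / lo))
}

#' Simulate daily serial-dilution growth of a clone
#'
#' Emulates the replicative-potential protocol: every 24 h the culture is
#' diluted to `dilution_od`, grown overnight, and its OD600 recorded. The
#' realized daily doublings follow [doubling_rate()] evaluated at the
#' telomere length at the start of the day; `od_end` carries multiplicative
#' lognormal noise with coefficient of variation `od_noise_cv` (mean 1).
#' Cumulative PD is the running sum of realized `log2(od_end / od_start)`.
#'
#' @param traj A `telo_trajectory` spanning at least the PDs realized over
#'   `n_days` (see [simulate_telomere_trajectory()]).
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed + 1`.
#' @param condition Condition label (e.g. `"EV"` or `"RNH1"`).
#' @return A `growth_series` tibble with columns `clone_id`, `condition`,
#'   `day` (0-based), `od_start`, `od_end`, `pd_cumulative`, and the
#'   ground-truth sidecar column `length_bp` (telomere length at the start of
#'   the day).
#' @export
simulate_daily_culture <- function(traj, config, seed = config$seed + 1L,
                                   condition = "EV") {
  validate_sim_config(config)
  if (nrow(traj) == 0) stop("empty trajectory", call. = FALSE)
  withr::local_seed(as.integer(seed))

  len_at <- stats::approxfun(traj$pd, traj$length_bp, method = "constant",
                             rule = 2)
  n <- config$n_days
  sdlog <- sqrt(log1p(config$od_noise_cv^2))
  day <- 0:(n - 1)
  od_end <- pd_cum <- length_day <- numeric(n)
  pd <- 0
  for (i in seq_len(n)) {
    if (pd > max(traj$pd)) {
      stop("trajectory does not span the simulated days", call. = FALSE)
    }
    L <- len_at(pd)
    d <- doubling_rate(L, config)
    noise <- if (sdlog > 0) {
      stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else 1
    od <- config$dilution_od * 2^d * noise
    pd <- pd + log2(od / config$dilution_od)
    length_day[i] <- L
    od_end[i] <- od
    pd_cum[i] <- pd
  }
  out <- tibble::tibble(
    clone_id = traj$clone_id[1],
    condition = condition,
    day = day,
    od_start = config$dilution_od,
    od_end = od_end,
    pd_cumulative = pd_cum,
    length_bp = length_day
  )
  class(out) <- c("growth_series", class(out))
  out
}

#' Expected TERRA fold as a function of telomere length
#'
#' Saturating logistic coupling between telomere length and TERRA abundance:
#' the expected fold over the long-telomere baseline is exactly 1 at or above
#' `senesce_length`, exactly `terra_fold_short` at or below
#' `critical_length`, and decreases monotonically in length in between with
#' logistic shape (length scale `terra_length_scale`).
#'
#' @param length_bp Telomere length(s), bp.
#' @param config A [sim_config()].
#' @return Expected fold(s) in `[1, terra_fold_short]`.
#' @export
terra_fold_expected <- function(length_bp, config) {
  lo <- config$critical_length
  hi <- config$senesce_length
  mid <- (lo + hi) / 2
  raw <- stats::plogis((mid - length_bp) / config$terra_length_scale)
  r_lo <- stats::plogis((mid - hi) / config$terra_length_scale)
  r_hi <- stats::plogis((mid - lo) / config$terra_length_scale)
  u <- pmin(pmax((raw - r_lo) / (r_hi - r_lo), 0), 1)
  1 + (config$terra_fold_short - 1) * u
}

#' Simulate TERRA RT-qPCR Ct pairs along a trajectory
#'
#' Samples the trajectory at the given PDs and emits paired threshold cycles
#' for TERRA (target) and actin mRNA (reference). The expected TERRA fold
#' over the long-telomere baseline follows [terra_fold_expected()]; a fold
#' `f` shifts the target Ct by `-log2(f)` relative to the long-telomere
#' baseline `baseline_dct`. Both Cts carry additive Gaussian noise with SD
#' `ct_noise_sd`.
#'
#' @param traj A `telo_trajectory`.
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed + 2`.
#' @param at_pd PDs at which to sample; default every 10 PD over the
#'   trajectory.
#' @param locus Locus label for the output table.
#' @param baseline_dct Ct(TERRA) - Ct(actin) at long telomeres, cycles. The
#'   default 8 puts baseline TERRA at ~0.4% of actin mRNA.
#' @param ct_reference_mean Mean actin Ct, cycles.
#' @return A tibble with columns `sample_id`, `clone_id`, `group`, `locus`,
#'   `pd`, `ct_target`, `ct_reference`, and ground-truth sidecar columns
#'   `length_bp` and `true_fold`.
#' @export
simulate_terra_cts <- function(traj, config, seed = config$seed + 2L,
                               at_pd = NULL, locus = "1L",
                               baseline_dct = 8, ct_reference_mean = 15) {
  validate_sim_config(config)
  if (nrow(traj) == 0) stop("empty trajectory", call. = FALSE)
  if (config$terra_fold_short < 1) {
    stop("`terra_fold_short` must be >= 1", call. = FALSE)
  }
  withr::local_seed(as.integer(seed))
  if (is.null(at_pd)) at_pd <- seq(0, max(traj$pd), by = 10)
  len_at <- stats::approxfun(traj$pd, traj$length_bp, method = "constant",
                             rule = 2)
  L <- len_at(at_pd)
  fold <- terra_fold_expected(L, config)
  n <- length(at_pd)
  ct_ref <- ct_reference_mean + stats::rnorm(n, 0, config$ct_noise_sd)
  ct_tar <- ct_ref + baseline_dct - log2(fold) +
    stats::rnorm(n, 0, config$ct_noise_sd)
  tibble::tibble(
    sample_id = sprintf("%s_pd%03d", traj$clone_id[1], round(at_pd)),
    clone_id = traj$clone_id[1],
    group = "survivor",
    locus = locus,
    pd = at_pd,
    ct_target = ct_tar,
    ct_reference = ct_ref,
    length_bp = L,
    true_fold = fold
  )
}

#' Generate a synthetic densitometry lane profile
#'
#' Builds a one-dimensional lane-intensity profile as a sum of Gaussian bands
#' on a migration coordinate, emulating an ImageJ profile of a rotated
#' Southern blot where x = 0 is the image edge and larger x means a longer
#' telomere. Band centers are a linear (through-origin) map of length, so
#' position ratios equal length ratios; centers are jittered by
#' `band_position_noise_sd` and the profile carries non-negative background
#' noise.
#'
#' @param lengths Telomere lengths (bp), all positive.
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed + 3`.
#' @param n_grid Number of coordinate samples across `[0, 1]`.
#' @param band_width Gaussian SD of a band, coordinate units.
#' @param background_sd SD of the half-normal background noise (0 = clean).
#' @return A `lane_profile` tibble with columns `coordinate` and `intensity`;
#'   the ground-truth band table (columns `length_bp`, `center_true`,
#'   `center_used`) is attached as attribute `"bands"`.
#' @export
generate_lane_profile <- function(lengths, config, seed = config$seed + 3L,
                                  n_grid = 500, band_width = 0.02,
                                  background_sd = 0) {
  if (length(lengths) == 0) stop("empty length list", call. = FALSE)
  if (any(lengths <= 0)) stop("all lengths must be positive", call. = FALSE)
  withr::local_seed(as.integer(seed))
  centers <- lengths / (1.1 * max(lengths))
  used <- centers + stats::rnorm(length(centers), 0,
                                 config$band_position_noise_sd)
  x <- seq(0, 1, length.out = n_grid)
  intensity <- rowSums(vapply(
    used,
    function(c0) exp(-(x - c0)^2 / (2 * band_width^2)),
    numeric(n_grid)
  ))
  if (background_sd > 0) {
    intensity <- intensity + abs(stats::rnorm(n_grid, 0, background_sd))
  }
  out <- tibble::tibble(coordinate = x, intensity = intensity)
  class(out) <- c("lane_profile", class(out))
  attr(out, "bands") <- tibble::tibble(
    length_bp = lengths, center_true = centers, center_used = used
  )
  out
}

#' Generate a synthetic ChIP-qPCR dataset
#'
#' Emits IP and Input signals for survivor and wild-type cells, tagged and
#' untagged, across loci with configurable true survivor/wild-type
#' enrichment ratios. The default ratios put the telomeric loci at the
#' paper-scale ~50% reduction of factor binding in survivors and leave the
#' actin control unchanged. Signals carry multiplicative lognormal noise.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed + 4`.
#' @param ratios Named numeric vector of true survivor/wild-type percent-input
#'   ratios per locus.
#' @param n_days Number of same-day survivor/wild-type batches.
#' @param wt_percent_input True percent input of the tagged wild-type sample.
#' @param background_percent_input True percent input of untagged samples.
#' @param input_fraction Fraction of the ChIP extract kept as Input.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @return A tibble with columns `sample_id`, `genotype`, `tag`, `locus`,
#'   `day`, `ip_signal`, `input_signal`, `input_fraction` and the
#'   ground-truth sidecar column `true_ratio`.
#' @export
generate_chip_dataset <- function(config, seed = config$seed + 4L,
                                  ratios = c("1L" = 0.5, "15L" = 0.7,
                                             "6Y" = 0.5, "ACT1" = 1),
                                  n_days = 3,
                                  wt_percent_input = 2,
                                  background_percent_input = 0.1,
                                  input_fraction = 0.05,
                                  noise_cv = 0) {
  validate_sim_config(config)
  withr::local_seed(as.integer(seed))
  grid <- tidyr::expand_grid(
    day = seq_len(n_days),
    genotype = c("survivor", "wild-type"),
    tag = c("tagged", "untagged"),
    locus = names(ratios)
  )
  sdlog <- sqrt(log1p(noise_cv^2))
  grid <- dplyr::mutate(
    grid,
    true_ratio = unname(ratios[.data$locus]),
    true_pct = dplyr::case_when(
      .data$tag == "untagged" ~ background_percent_input,
      .data$genotype == "wild-type" ~ wt_percent_input,
      TRUE ~ wt_percent_input * .data$true_ratio
    ),
    input_signal = 100,
    ip_signal = (.data$input_signal / input_fraction) * .data$true_pct / 100,
    input_fraction = input_fraction,
    sample_id = sprintf("d%d_%s_%s_%s", .data$day, .data$genotype,
                        .data$tag, .data$locus)
  )
  if (sdlog > 0) {
    n <- nrow(grid)
    grid$ip_signal <- grid$ip_signal *
      stats::rlnorm(n, -sdlog^2 / 2, sdlog)
    grid$input_signal <- grid$input_signal *
      stats::rlnorm(n, -sdlog^2 / 2, sdlog)
  }
  dplyr::select(grid, "sample_id", "genotype", "tag", "locus", "day",
                "ip_signal", "input_signal", "input_fraction", "true_ratio")
}
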