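#' Simulator configuration
#'
#' Builds a validated configuration for the clonal survivor simulator. The
#' defaults describe a typical telomerase-negative type II survivor clone
#' followed by daily serial dilution: a single telomere starting at 350 bp
#' shortens by about 2.7 bp per population doubling (PD), becomes critically
#' short near 100 bp, and is then re-elongated by homology-directed repair
#' (HDR), either by a fixed Y'-element-like addition (type I) or a
#' heterogeneous, heavy-tailed TG-repeat addition (type II). Culture growth
#' slows as the telomere shortens below `senesce_length`; TERRA rises up to
#' `terra_fold_short`-fold as the telomere approaches `critical_length`.
#'
#' @param shorten_rate_mean Mean telomere shortening rate, bp per PD (> 0).
#' @param shorten_rate_sd SD of the per-PD shortening draw, bp (>= 0).
#' @param initial_length Starting telomere length, bp.
#' @param critical_length Length (bp) below which HDR can fire.
#' @param senesce_length Length (bp) below which growth starts to slow; must
#'   exceed `critical_length` and be below `initial_length`.
#' @param hdr_prob_per_pd Per-PD probability of an HDR event while the
#'   telomere is below `critical_length`, in `[0, 1]`.
#' @param type2_fraction Probability that an HDR event is type II, in `[0, 1]`.
#' @param type1_gain Fixed length gain of a type I event, bp.
#' @param type2_gain_log_mean,type2_gain_log_sd Meanlog/sdlog of the lognormal
#'   type II gain distribution (bp).
#' @param terra_fold_short TERRA fold increase at critically short vs long
#'   telomeres (>= 1). The paper-scale default is 6.
#' @param terra_length_scale Length scale (bp) of the logistic TERRA-length
#'   coupling.
#' @param max_doublings_per_day Daily doublings of a healthy culture (PD/day).
#' @param min_doublings_per_day Daily doublings at the critical length
#'   (PD/day). The default pair (5, 1.68) gives a ~10-fold OD span between
#'   healthy and critically short cultures.
#' @param dilution_od OD600 to which cultures are diluted daily.
#' @param od_noise_cv Coefficient of variation of multiplicative OD noise.
#' @param ct_noise_sd Additive SD on simulated qPCR Ct values, cycles.
#' @param band_position_noise_sd Additive SD on simulated band positions,
#'   migration-coordinate units.
#' @param n_days Number of simulated culture days.
#' @param seed Default integer seed carried with the configuration.
#'
#' @return An object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(shorten_rate_mean = 2.7)
#' cfg$critical_length
#' @export
sim_config <- function(shorten_rate_mean = 2.7,
                       shorten_rate_sd = 0.5,
                       initial_length = 350,
                       critical_length = 100,
                       senesce_length = 200,
                       hdr_prob_per_pd = 0.5,
                       type2_fraction = 0.5,
                       type1_gain = 150,
                       type2_gain_log_mean = log(250),
                       type2_gain_log_sd = 0.6,
                       terra_fold_short = 6,
                       terra_length_scale = 25,
                       max_doublings_per_day = 5,
                       min_doublings_per_day = 1.68,
                       dilution_od = 0.01,
                       od_noise_cv = 0.05,
                       ct_noise_sd = 0.15,
                       band_position_noise_sd = 0.005,
                       n_days = 60,
                       seed = 1L) {
  cfg <- list(
    shorten_rate_mean = shorten_rate_mean,
    shorten_rate_sd = shorten_rate_sd,
    initial_length = initial_length,
    critical_length = critical_length,
    senesce_length = senesce_length,
    hdr_prob_per_pd = hdr_prob_per_pd,
    type2_fraction = type2_fraction,
    type1_gain = type1_gain,
    type2_gain_log_mean = type2_gain_log_mean,
    type2_gain_log_sd = type2_gain_log_sd,
    terra_fold_short = terra_fold_short,
    terra_length_scale = terra_length_scale,
    max_doublings_per_day = max_doublings_per_day,
    min_doublings_per_day = min_doublings_per_day,
    dilution_od = dilution_od,
    od_noise_cv = od_noise_cv,
    ct_noise_sd = ct_noise_sd,
    band_position_noise_sd = band_position_noise_sd,
    n_days = as.integer(n_days),
    seed = as.integer(seed)
  )
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  chk <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  for (f in setdiff(names(cfg), c("n_days", "seed"))) {
    chk(num1(cfg[[f]]), paste0("`", f, "` must be a single finite number"))
  }
  chk(cfg$shorten_rate_mean > 0, "`shorten_rate_mean` must be > 0")
  chk(cfg$shorten_rate_sd >= 0, "`shorten_rate_sd` must be >= 0")
  chk(cfg$initial_length > 0, "`initial_length` must be positive")
  chk(cfg$critical_length > 0 && cfg$critical_length < cfg$initial_length,
      "`critical_length` must lie in (0, initial_length)")
  chk(cfg$senesce_length > cfg$critical_length &&
        cfg$senesce_length < cfg$initial_length,
      "must have critical_length < senesce_length < initial_length")
  chk(cfg$hdr_prob_per_pd >= 0 && cfg$hdr_prob_per_pd <= 1,
      "`hdr_prob_per_pd` must be in [0, 1]")
  chk(cfg$type2_fraction >= 0 && cfg$type2_fraction <= 1,
      "`type2_fraction` must be in [0, 1]")
  chk(cfg$type1_gain > 0, "`type1_gain` must be positive")
  chk(cfg$type2_gain_log_sd >= 0, "`type2_gain_log_sd` must be >= 0")
  chk(cfg$terra_fold_short >= 1, "`terra_fold_short` must be >= 1")
  chk(cfg$terra_length_scale > 0, "`terra_length_scale` must be positive")
  chk(cfg$max_doublings_per_day > 0, "`max_doublings_per_day` must be > 0")
  chk(cfg$min_doublings_per_day > 0 &&
        cfg$min_doublings_per_day <= cfg$max_doublings_per_day,
      "`min_doublings_per_day` must be in (0, max_doublings_per_day]")
  chk(cfg$dilution_od > 0, "`dilution_od` must be positive")
  chk(cfg$od_noise_cv >= 0, "`od_noise_cv` must be >= 0")
  chk(cfg$ct_noise_sd >= 0, "`ct_noise_sd` must be >= 0")
  chk(cfg$band_position_noise_sd >= 0,
      "`band_position_noise_sd` must be >= 0")
  chk(is.numeric(cfg$n_days) && cfg$n_days >= 1, "`n_days` must be >= 1")
  cfg
}

#' Read a simulator configuration from a YAML or JSON file
#'
#' Unspecified fields take the [sim_config()] defaults, so a config file only
#' needs to list the parameters it overrides.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file of `sim_config` fields.
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown) > 0) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(sim_config, vals)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (f in names(x)) cat(sprintf("  %-24s %s\n", f, format(x[[f]])))
  invisible(x)
}
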