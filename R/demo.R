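update_sim_config <- function(config, ...) {
  vals <- utils::modifyList(unclass(config), list(...))
  do.call(sim_config, vals)
}

demo_clone_seed <- function(seed, clone, arm) {
  # keep derived seeds well below 2^31 for any small grader seed
  (abs(as.integer(seed)) %% 100000L) * 10000L + clone * 10L + arm
}

#' Simulate a survivor cohort and run the full analysis pipeline
#'
#' End-to-end demonstration mirroring the clonal-propagation experimental
#' design: `n_clones` survivor clones are each propagated under an
#' empty-vector arm (`EV`, shortening at `config$shorten_rate_mean`) and an
#' R-loop-depleted arm (`RNH1`, shortening `rate_factor` times faster). For
#' every clone the pipeline computes replicative-potential series (each arm
#' referenced to the clone's EV day-0 OD), SAS rates, pre-HDR shortening
#' rates by regression with per-clone RNH1/EV fold changes, TERRA Ct tables
#' with recovered folds, and a TAP-corrected ChIP fold-change table. All
#' tables are written as TSV alongside a JSON run manifest carrying the seed,
#' the config digest and the MD5 of every output, so a rerun with the same
#' seed is bit-identical.
#'
#' @param config A [sim_config()] describing the EV arm.
#' @param seed Integer master seed.
#' @param outdir Output directory (created if missing).
#' @param n_clones Clones per arm (>= 1).
#' @param rate_factor Shortening-rate multiplier of the RNH1 arm
#'   (default 1.6, the paper-scale effect of R-loop removal).
#' @return Invisibly, a list with `manifest` (list), `tables` (named list of
#'   tibbles) and `paths` (named file paths).
#' @export
run_demo <- function(config = sim_config(), seed = config$seed,
                     outdir = tempfile("telosas_demo_"),
                     n_clones = 5, rate_factor = 1.6) {
  validate_sim_config(config)
  if (!is.numeric(n_clones) || n_clones < 1) {
    stop("`n_clones` must be >= 1", call. = FALSE)
  }
  n_clones <- as.integer(n_clones)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  cfg_ev <- config
  cfg_rnh1 <- update_sim_config(config,
                                shorten_rate_mean =
                                  config$shorten_rate_mean * rate_factor)
  arms <- list(EV = cfg_ev, RNH1 = cfg_rnh1)

  growth <- potential <- lengths <- terra <- list()
  for (cl in seq_len(n_clones)) {
    id <- sprintf("clone%02d", cl)
    arm_growth <- list()
    for (a in seq_along(arms)) {
      cond <- names(arms)[a]
      cfg <- arms[[a]]
      traj <- simulate_telomere_trajectory(
        cfg, seed = demo_clone_seed(seed, cl, 2L * a), clone_id = id
      )
      g <- simulate_daily_culture(
        traj, cfg, seed = demo_clone_seed(seed, cl, 2L * a + 1L),
        condition = cond
      )
      arm_growth[[cond]] <- g
      pre <- pre_event_segment(traj)
      lengths[[paste(id, cond)]] <- tibble::tibble(
        clone_id = id, condition = cond, pd = pre$pd,
        length_bp = pre$length_bp
      )
      if (cond == "EV") {
        terra[[id]] <- simulate_terra_cts(
          traj, cfg, seed = demo_clone_seed(seed, cl, 9L)
        )
      }
    }
    for (cond in names(arm_growth)) {
      growth[[paste(id, cond)]] <- arm_growth[[cond]]
      potential[[paste(id, cond)]] <-
        replicative_potential(arm_growth[[cond]], arm_growth[["EV"]])
    }
  }
  growth <- purrr::list_rbind(growth)
  potential <- purrr::list_rbind(potential)
  lengths <- purrr::list_rbind(lengths)
  terra <- purrr::list_rbind(terra)

  sas <- sas_rate(potential)
  cmp <- compare_sas(dplyr::filter(sas, .data$condition == "EV"),
                     dplyr::filter(sas, .data$condition == "RNH1"))
  rates <- shortening_rates(lengths, method = "regression")
  rate_folds <- rates |>
    tidyr::pivot_wider(id_cols = "clone_id", names_from = "condition",
                       values_from = "rate_bp_per_pd") |>
    dplyr::mutate(fold_change = .data$RNH1 / .data$EV)

  baseline_pct <- percent_reference(8, 0)  # long-telomere TERRA baseline
  terra <- terra |>
    terra_quant() |>
    dplyr::mutate(fold_recovered = .data$pct_reference / baseline_pct)
  terra_fold <- {
    short <- terra$fold_recovered[terra$length_bp <= config$critical_length]
    long <- terra$fold_recovered[terra$length_bp >= config$senesce_length]
    if (length(short) > 0 && length(long) > 0) {
      mean(short) / mean(long)
    } else NA_real_
  }

  chip_raw <- generate_chip_dataset(config,
                                    seed = demo_clone_seed(seed, 0L, 5L))
  chip <- chip_fold_change(chip_raw, tap = TRUE)

  summary_tbl <- dplyr::bind_rows(
    sas |>
      dplyr::group_by(.data$condition) |>
      dplyr::summarise(value = mean(.data$pd_to_min), .groups = "drop") |>
      dplyr::mutate(metric = "mean_pd_to_min", .before = 1) |>
      dplyr::rename(group = "condition"),
    rates |>
      dplyr::group_by(.data$condition) |>
      dplyr::summarise(value = mean(.data$rate_bp_per_pd),
                       .groups = "drop") |>
      dplyr::mutate(metric = "mean_shortening_rate_bp_per_pd", .before = 1) |>
      dplyr::rename(group = "condition"),
    tibble::tibble(metric = "mean_rate_fold_change_rnh1_vs_ev",
                   group = "RNH1/EV",
                   value = mean(rate_folds$fold_change)),
    tibble::tibble(metric = "sas_pd_mean_difference_ev_minus_rnh1",
                   group = "EV-RNH1", value = cmp$mean_difference),
    tibble::tibble(metric = "terra_fold_short_vs_long", group = "EV",
                   value = terra_fold),
    chip |>
      dplyr::group_by(.data$locus) |>
      dplyr::summarise(value = mean(.data$fold_change), .groups = "drop") |>
      dplyr::mutate(metric = "chip_fold_change_to_wildtype", .before = 1) |>
      dplyr::rename(group = "locus")
  )

  tables <- list(
    growth = growth,
    potential = potential,
    lengths = lengths,
    sas = dplyr::select(sas, -"minima_indices"),
    rates = rates,
    rate_folds = rate_folds,
    terra = terra,
    chip = chip,
    summary = summary_tbl
  )
  paths <- character(0)
  cfg_path <- file.path(outdir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths["config"] <- cfg_path
  for (nm in names(tables)) {
    p <- file.path(outdir, paste0(nm, ".tsv"))
    readr::write_tsv(tables[[nm]], p)
    paths[nm] <- p
  }
  manifest <- list(
    package = "telosas",
    version = as.character(utils::packageVersion("telosas")),
    subcommand = "demo",
    seed = as.integer(seed),
    n_clones = n_clones,
    rate_factor = rate_factor,
    config_digest = unname(tools::md5sum(cfg_path)),
    outputs = as.list(tools::md5sum(unname(paths))),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  manifest_path <- file.path(outdir, "manifest.json")
  tmp <- tempfile(tmpdir = outdir)
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE)
  file.rename(tmp, manifest_path)
  paths["manifest"] <- manifest_path

  invisible(list(manifest = manifest, tables = tables, paths = paths))
}
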