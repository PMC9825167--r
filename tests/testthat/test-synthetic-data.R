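test_that("trajectory follows deterministic linear decay without noise", {
  cfg <- sim_config(shorten_rate_mean = 2, shorten_rate_sd = 0,
                    hdr_prob_per_pd = 0)
  traj <- simulate_telomere_trajectory(cfg, seed = 1, n_pd = 10)
  expect_equal(traj$length_bp, 350 - 2 * (0:10))
  expect_true(all(traj$event == "none"))
})

test_that("a forced HDR event fires at the first sub-critical PD", {
  cfg <- sim_config(shorten_rate_mean = 5, shorten_rate_sd = 0,
                    hdr_prob_per_pd = 1, type2_fraction = 0,
                    initial_length = 110, critical_length = 100,
                    senesce_length = 105)
  traj <- simulate_telomere_trajectory(cfg, seed = 1, n_pd = 10)
  below <- which(traj$length_bp < 100)[1]
  expect_equal(traj$event[below + 1], "type1")
  expect_equal(traj$length_bp[below + 1],
               traj$length_bp[below] + cfg$type1_gain)
})

test_that("trajectory invariants hold at the default configuration", {
  cfg <- sim_config()
  for (s in 1:5) {
    traj <- simulate_telomere_trajectory(cfg, seed = s)
    expect_true(all(diff(traj$pd) > 0))
    expect_true(all(traj$length_bp > 0))
    d <- diff(traj$length_bp)
    ev <- traj$event[-1]
    expect_true(all(d[ev == "none"] < 0))
    expect_true(all(d[ev != "none"] > 0))
    # events only fire below the critical length
    pre <- traj$length_bp[-nrow(traj)]
    expect_true(all(pre[ev != "none"] < cfg$critical_length))
  }
})

test_that("identical config and seed reproduce every output bit-identically", {
  cfg <- sim_config(n_days = 15, od_noise_cv = 0.05)
  t1 <- simulate_telomere_trajectory(cfg, seed = 42)
  t2 <- simulate_telomere_trajectory(cfg, seed = 42)
  expect_identical(t1, t2)
  expect_identical(simulate_daily_culture(t1, cfg, seed = 7),
                   simulate_daily_culture(t2, cfg, seed = 7))
  expect_identical(simulate_terra_cts(t1, cfg, seed = 7),
                   simulate_terra_cts(t2, cfg, seed = 7))
  expect_identical(generate_lane_profile(c(100, 250), cfg, seed = 7),
                   generate_lane_profile(c(100, 250), cfg, seed = 7))
  expect_identical(generate_chip_dataset(cfg, seed = 7, noise_cv = 0.1),
                   generate_chip_dataset(cfg, seed = 7, noise_cv = 0.1))
})

test_that("daily culture reproduces the dilution protocol exactly", {
  # healthy culture: every od_end is 0.01 * 2^5 = 0.32
  cfg <- sim_config(od_noise_cv = 0, n_days = 10, max_doublings_per_day = 5)
  g <- simulate_daily_culture(flat_trajectory(300), cfg, seed = 1)
  expect_equal(g$od_end, rep(0.32, 10))
  expect_equal(g$od_start, rep(0.01, 10))
  expect_equal(g$pd_cumulative, 5 * (1:10))
  # fully senescent culture pinned at the critical length
  cfg2 <- sim_config(od_noise_cv = 0, n_days = 10,
                     min_doublings_per_day = 1)
  g2 <- simulate_daily_culture(flat_trajectory(cfg2$critical_length), cfg2,
                               seed = 1)
  expect_equal(g2$od_end, rep(0.02, 10))
  expect_error(simulate_daily_culture(flat_trajectory(300)[0, ], cfg2,
                                      seed = 1),
               "empty trajectory")
})

test_that("cumulative PD equals the sum of realized daily doublings", {
  cfg <- sim_config(n_days = 20)
  traj <- simulate_telomere_trajectory(cfg, seed = 5)
  g <- simulate_daily_culture(traj, cfg, seed = 6)
  expect_equal(g$pd_cumulative,
               cumsum(population_doublings(g$od_end, g$od_start)))
})

test_that("worst growth day matches shortest-telomere day on clean runs", {
  cfg <- sim_config(od_noise_cv = 0)
  for (s in 1:10) {
    traj <- simulate_telomere_trajectory(cfg, seed = s)
    g <- simulate_daily_culture(traj, cfg, seed = s + 100)
    expect_equal(which.min(g$od_end), which.min(g$length_bp))
  }
})

test_that("TERRA coupling hits its endpoints exactly and is monotone", {
  cfg <- sim_config(ct_noise_sd = 0)
  # long telomere: recovered fold exactly 1
  ct_long <- simulate_terra_cts(flat_trajectory(300), cfg, seed = 1,
                                at_pd = 0)
  expect_equal(ct_long$ct_target - ct_long$ct_reference, 8)
  expect_equal(ct_long$true_fold, 1)
  # critically short: recovered fold exactly terra_fold_short = 6
  ct_short <- simulate_terra_cts(flat_trajectory(50), cfg, seed = 1,
                                 at_pd = 0)
  expect_equal(ct_short$true_fold, 6)
  fold_rec <- percent_reference(ct_short$ct_target, ct_short$ct_reference) /
    percent_reference(8, 0)
  expect_equal(fold_rec, 6)
  # fold 4 shifts the delta-Ct by exactly -2 cycles
  L4 <- uniroot(function(L) terra_fold_expected(L, cfg) - 4,
                c(cfg$critical_length, cfg$senesce_length),
                tol = 1e-12)$root
  ct4 <- simulate_terra_cts(flat_trajectory(L4), cfg, seed = 1, at_pd = 0)
  expect_equal(ct4$ct_target - ct4$ct_reference, 8 - 2, tolerance = 1e-9)
  # monotone non-increasing in length for random valid configs
  withr::with_seed(11, {
    for (i in 1:20) {
      lo <- runif(1, 20, 150)
      hi <- lo + runif(1, 20, 200)
      cfgi <- sim_config(initial_length = hi + 50, critical_length = lo,
                         senesce_length = hi,
                         terra_fold_short = runif(1, 1, 10),
                         terra_length_scale = runif(1, 5, 100))
      L <- seq(1, hi + 100, length.out = 300)
      expect_true(all(diff(terra_fold_expected(L, cfgi)) <= 1e-12))
    }
  })
  expect_error(simulate_terra_cts(flat_trajectory(300)[0, ], cfg, seed = 1),
               "empty trajectory")
})

test_that("lane profiles encode band positions recoverably", {
  cfg <- sim_config(band_position_noise_sd = 0)
  one <- generate_lane_profile(200, cfg, seed = 1)
  expect_equal(one$coordinate[which.max(one$intensity)],
               attr(one, "bands")$center_true,
               tolerance = 2 / nrow(one))
  cfg_n <- sim_config(band_position_noise_sd = 0.005)
  two <- generate_lane_profile(c(100, 300), cfg_n, seed = 2)
  found <- detect_bands(two, min_prominence = 0.2)
  truth <- sort(attr(two, "bands")$center_true)
  expect_equal(found, truth, tolerance = 3 * 0.005)
  # zero-noise three-band profile: relative lengths from detected positions
  # equal relative lengths from the true lengths
  three <- generate_lane_profile(c(80, 180, 330), cfg, seed = 3)
  pos <- detect_bands(three, min_prominence = 0.2)
  expect_equal(relative_length(pos), c(80, 180, 330) / 330,
               tolerance = 1e-2)
  expect_error(generate_lane_profile(numeric(0), cfg), "empty length list")
  expect_error(generate_lane_profile(c(100, -5), cfg), "positive")
})

test_that("ChIP generator encodes ground-truth enrichment ratios", {
  cfg <- sim_config()
  chip <- generate_chip_dataset(cfg, seed = 1, noise_cv = 0)
  # noise 0, ratio 1 at the actin control -> fold change exactly 1
  fc <- chip_fold_change(chip, tap = FALSE)
  act <- fc$fold_change[fc$locus == "ACT1"]
  expect_equal(act, rep(1, length(act)))
  # configured ratio 0.5 recovered exactly at the telomeric locus
  expect_equal(fc$fold_change[fc$locus == "1L"], rep(0.5, 3))
  # untagged signal equals tagged -> TAP-corrected fold change 1 everywhere
  flat <- dplyr::mutate(chip, ip_signal = (input_signal / input_fraction) *
                          0.5 / 100)
  tapfc <- chip_fold_change(flat, tap = TRUE)
  expect_equal(tapfc$fold_change, rep(1, nrow(tapfc)))
})
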