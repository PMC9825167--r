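test_that("band detection finds Gaussian peaks and rejects flat lanes", {
  x <- seq(0, 1, length.out = 501)
  one <- tibble::tibble(coordinate = x,
                        intensity = exp(-(x - 0.4)^2 / (2 * 0.02^2)))
  expect_equal(detect_bands(one), 0.4, tolerance = 1e-6)
  flat <- tibble::tibble(coordinate = x, intensity = rep(1, length(x)))
  expect_error(detect_bands(flat), "no peak")
  cfg <- sim_config(band_position_noise_sd = 0)
  three <- generate_lane_profile(c(90, 200, 320), cfg, seed = 2)
  expect_equal(detect_bands(three, min_prominence = 0.2),
               sort(attr(three, "bands")$center_true), tolerance = 5e-3)
})

test_that("relative lengths are normalized to the longest band", {
  expect_equal(relative_length(c(2, 4, 8)), c(0.25, 0.5, 1))
  expect_equal(relative_length(5), 1)
  withr::with_seed(41, {
    p <- runif(20, 0.1, 1)
    r <- relative_length(p)
    expect_true(all(r > 0 & r <= 1))
    expect_identical(order(r), order(p))  # order preserved
  })
  expect_error(relative_length(c(1, 0)), "positive")
})

test_that("percent of first scales to the reference strain", {
  expect_equal(percent_of_first(c(3, 3, 3), 3), c(100, 100, 100))
  expect_equal(percent_of_first(2, 4), 50)
  expect_error(percent_of_first(1, 0), "positive")
})

test_that("difference-quotient rates average consecutive bp/PD ratios", {
  expect_equal(rate_diffquot(c(350, 340, 330), c(0, 10, 20))$rate, 1)
  expect_equal(rate_diffquot(rep(300, 4), c(0, 5, 9, 20))$rate, 0)
  withr::with_seed(42, {
    for (i in 1:20) {
      n <- sample(3:30, 1)
      pds <- sort(sample(0:500, n))
      lens <- 350 - cumsum(runif(n, 0, 10))
      expect_equal(rate_diffquot(lens, pds)$rate, brute_diffquot(lens, pds))
    }
  })
  # telescoping: equally spaced PDs reduce to (first - last) / span
  lens <- c(350, 342, 330, 329, 310)
  expect_equal(rate_diffquot(lens, seq(0, 40, 10))$rate, (350 - 310) / 40)
  expect_error(rate_diffquot(c(1, 2), c(3, 3)), "duplicate PD")
  expect_error(rate_diffquot(350, 0), ">= 2")
})

test_that("regression rates equal the sign-flipped OLS slope", {
  pds <- c(0, 8, 15, 30, 44)
  expect_equal(rate_regression(500 - 2.7 * pds, pds)$rate, 2.7)
  withr::with_seed(43, {
    for (i in 1:20) {
      n <- sample(5:40, 1)
      pds <- sort(runif(n, 0, 200))
      lens <- 400 - runif(1, 0.5, 8) * pds + rnorm(n, 0, 5)
      expect_equal(rate_regression(lens, pds)$rate, -ols_slope(pds, lens))
    }
  })
  expect_error(rate_regression(c(1, 2, 3), c(5, 5, 5)), "degenerate")
})

test_that("both estimators agree exactly on noise-free linear series and
           are invariant to constant length shifts", {
  pds <- c(0, 10, 25, 31, 50)
  lens <- 420 - 3.1 * pds
  expect_equal(rate_diffquot(lens, pds)$rate, 3.1)
  expect_equal(rate_regression(lens, pds)$rate, 3.1)
  withr::with_seed(44, {
    lens2 <- 350 - cumsum(runif(5, 0, 8))
    for (f in list(rate_diffquot, rate_regression)) {
      expect_equal(f(lens2 + 1000, pds)$rate, f(lens2, pds)$rate)
    }
  })
})

test_that("rate fold changes compare like estimates only", {
  pds <- seq(0, 40, 10)
  ev <- rate_regression(350 - 2.7 * pds, pds)
  rn <- rate_regression(350 - 5.4 * pds, pds)
  expect_equal(rate_fold_change(ev, ev), 1)
  expect_equal(rate_fold_change(rn, ev), 2)
  dq <- rate_diffquot(350 - 2.7 * pds, pds)
  expect_error(rate_fold_change(dq, ev), "method mismatch")
  zero <- rate_diffquot(rep(300, 5), pds)
  expect_error(rate_fold_change(dq, zero), "zero control rate")
})

test_that("shortening_rates maps estimators over a long table", {
  pds <- seq(0, 90, 10)
  tbl <- dplyr::bind_rows(
    tibble::tibble(clone_id = "a", condition = "EV", pd = pds,
                   length_bp = 350 - 2.7 * pds),
    tibble::tibble(clone_id = "b", condition = "RNH1", pd = pds,
                   length_bp = 350 - 6.7 * pds)
  )
  out <- shortening_rates(tbl, method = "regression")
  expect_equal(out$rate_bp_per_pd[order(out$clone_id)], c(2.7, 6.7))
  out2 <- shortening_rates(tbl, method = "diffquot")
  expect_equal(out2$rate_bp_per_pd[order(out2$clone_id)], c(2.7, 6.7))
  # tidiers expose the estimate in broom shape
  est <- rate_regression(350 - 2.7 * pds, pds, clone_id = "a",
                         condition = "EV")
  expect_equal(tidy(est)$estimate, 2.7)
  expect_equal(glance(est)$r.squared, 1)
})
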