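test_that("pairwise smoothing averages consecutive values", {
  expect_equal(smooth_pairwise(c(4, 4, 4)), c(4, 4))
  expect_equal(smooth_pairwise(c(0, 2, 4)), c(1, 3))
  withr::with_seed(21, {
    v <- rnorm(50)
    expect_equal(smooth_pairwise(v), brute_smooth2(v))
  })
  expect_equal(smooth_pairwise(c(0, 2, 4), passes = 2), 2)
  expect_error(smooth_pairwise(1), "at least 2")
})

test_that("local minima follow the neighborhood-window rule", {
  # strictly decreasing: every candidate is undercut by its successor
  expect_length(find_local_minima(20:1, k = 4), 0)
  # the worked window example: only the value 5 survives
  expect_equal(find_local_minima(c(9, 8, 7, 6, 5, 6, 7, 8, 9, 10, 11), k = 4),
               5)
  # constant series: earliest full-window position only, per tie rule
  expect_equal(find_local_minima(rep(1, 20), k = 4), 5)
  expect_error(find_local_minima(1:8, k = 4), "too short")
})

test_that("local minima agree with the exhaustive window scan", {
  withr::with_seed(31, {
    for (i in 1:50) {
      n <- sample(30:100, 1)
      k <- sample(c(2, 4, 6), 1)
      v <- rnorm(n)
      if (i %% 3 == 0) v <- round(v)  # force ties
      expect_identical(find_local_minima(v, k), brute_local_minima(v, k))
    }
  })
})

test_that("minima positions are invariant to adding a constant", {
  withr::with_seed(32, {
    v <- rnorm(60)
    expect_identical(find_local_minima(v + 123.4, 4), find_local_minima(v, 4))
  })
})

test_that("minimum selection honors the early-day exclusion and override", {
  series <- tibble::tibble(day = 0:19)
  # positions with days 2 and 9: the day-2 minimum is excluded
  expect_equal(select_minimum(c(3, 10), series, exclude_days = 3), 10)
  # single admissible minimum after day 3
  expect_equal(select_minimum(8, series), 8)
  expect_equal(select_minimum(c(3, 10), series, forced = 3), 3)
  expect_error(select_minimum(integer(0), series), "no admissible minimum")
  expect_error(select_minimum(2, series, exclude_days = 3),
               "no admissible minimum")
})

test_that("PD counting runs from the start to the selected minimum", {
  series <- tibble::tibble(day = 0:10, pd_cumulative = 5 * (0:10))
  expect_equal(sas_pd_count(series, 1), 0)
  expect_equal(sas_pd_count(series, 11), 50)
})

test_that("sas_rate recovers the simulator ground-truth minimum day", {
  # one senescence cycle with a short pre-senescent lead-in (a long flat
  # lead-in would itself count as a plateau minimum under the tie rule),
  # so the global length minimum is the minimum the earliest-admissible
  # rule selects
  cfg <- sim_config(od_noise_cv = 0, n_days = 30, initial_length = 250)
  p <- sim_clone_potential(cfg, seed = 3)
  res <- sas_rate(p)
  expect_s3_class(res, "sas_result")
  truth_day <- p$day[which.min(p$length_bp)]
  # smoothing shifts the detected position by at most one day
  expect_lte(abs(res$day_min - truth_day), 1)
  expect_equal(res$pd_to_min,
               p$pd_cumulative[res$selected_index] - p$pd_cumulative[1])
})

test_that("SAS comparisons report group means and the t summary", {
  a <- tibble::tibble(clone_id = paste0("c", 1:4), condition = "EV",
                      pd_to_min = c(80, 95, 70, 90))
  b <- dplyr::mutate(a, condition = "RNH1", pd_to_min = pd_to_min + 10)
  same <- compare_sas(a, a)
  expect_equal(same$mean_difference, 0)
  shift <- compare_sas(a, b)
  expect_equal(shift$mean_difference, -10)
  td <- tidy(shift)
  expect_equal(td$mean_pd_to_min, c(mean(a$pd_to_min), mean(b$pd_to_min)))
  gl <- glance(shift)
  expect_true(is.finite(gl$p.value))
  expect_match(gl$method, "t-test")
  # groups of one: means still reported, no test
  gl1 <- glance(compare_sas(a[1, ], b[1, ]))
  expect_true(is.na(gl1$p.value))
  expect_error(compare_sas(a[0, ], b), "non-empty")
})
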