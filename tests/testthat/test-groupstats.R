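test_that("noiseless identical participants give exact parameters and zero-width CIs", {
  series <- simulate_group_series(6, 50, intercept = 5, slope = -0.002,
                                  participant_sd = 0, trial_sd = 0,
                                  floor = 0)
  fit <- bootstrap_fit(series, "poly1", n_boot = 50, seed = 1)
  expect_equal(unname(fit$estimate["p2"]), 5, tolerance = 1e-10)
  expect_equal(unname(fit$estimate["p1"]), -0.002, tolerance = 1e-10)
  ci <- tidy(fit)
  expect_equal(ci$conf.low[ci$term == "p1"], ci$conf.high[ci$term == "p1"],
               tolerance = 1e-12)
})

test_that("bootstrap is reproducible under a fixed seed", {
  series <- simulate_group_series(8, 40, seed = 3)
  a <- bootstrap_fit(series, "poly1", n_boot = 40, seed = 11)
  b <- bootstrap_fit(series, "poly1", n_boot = 40, seed = 11)
  expect_identical(a$draws, b$draws)
  expect_identical(a$ci, b$ci)
})

test_that("generative parameters are recovered within the 95% CI", {
  series <- simulate_group_series(15, 200, intercept = 5, slope = -0.002,
                                  participant_sd = 0.3, trial_sd = 0.2,
                                  seed = 4)
  fit <- bootstrap_fit(series, "poly1", n_boot = 300, seed = 5)
  ci <- tidy(fit)
  p1 <- ci[ci$term == "p1", ]
  p2 <- ci[ci$term == "p2", ]
  expect_gt(-0.002, p1$conf.low); expect_lt(-0.002, p1$conf.high)
  expect_gt(5, p2$conf.low); expect_lt(5, p2$conf.high)
  # point estimate inside its own interval
  expect_true(p1$estimate >= p1$conf.low & p1$estimate <= p1$conf.high)
})

test_that("a constant series yields a slope interval containing zero", {
  series <- simulate_group_series(6, 30, intercept = 4, slope = 0,
                                  participant_sd = 0.2, trial_sd = 0.1,
                                  seed = 6)
  fit <- bootstrap_fit(series, "poly1", n_boot = 100, seed = 7)
  ci <- tidy(fit)
  p1 <- ci[ci$term == "p1", ]
  expect_lt(p1$conf.low, 0)
  expect_gt(p1$conf.high, 0)
})

test_that("CI width shrinks as participant noise vanishes", {
  width <- function(psd) {
    s <- simulate_group_series(10, 60, participant_sd = psd,
                               trial_sd = 0.05, seed = 8)
    ci <- tidy(bootstrap_fit(s, "poly1", n_boot = 100, seed = 9))
    diff(unlist(ci[ci$term == "p2", c("conf.low", "conf.high")]))
  }
  expect_lt(width(0.01), width(0.5))
})

test_that("family comparison ranks the generative family first", {
  lin <- simulate_group_series(10, 120, intercept = 6, slope = -0.02,
                               participant_sd = 0.05, trial_sd = 0.05,
                               seed = 10, floor = 0)
  cmp_lin <- compare_families(lin, n_boot = 60, seed = 11)
  poly_row <- cmp_lin[cmp_lin$family == "poly1", ]
  expect_gte(poly_row$r_squared_mean,
             max(cmp_lin$r_squared_mean[cmp_lin$family != "poly1"]) - 1e-6)

  # strong exponential curvature
  expo <- tidyr::expand_grid(participant = 1:10, trial = 1:120) |>
    dplyr::mutate(value = 5 * exp(-0.03 * trial) +
                    rnorm(1200, 0, 0.02) + 0.02 * participant)
  set.seed(12)
  cmp_exp <- compare_families(expo, n_boot = 60, seed = 13)
  expect_identical(cmp_exp$family[1], "exp1")
})

test_that("pure noise yields near-zero fit quality for all families", {
  noise <- simulate_group_series(8, 80, intercept = 5, slope = 0,
                                 participant_sd = 0.1, trial_sd = 0.3,
                                 seed = 14)
  cmp <- compare_families(noise, n_boot = 40, seed = 15)
  expect_true(all(cmp$r_squared_mean < 0.2))
  expect_true(all(cmp$overlaps_best))
})

test_that("group contrasts separate distinct slopes and not identical ones", {
  fast <- simulate_group_series(12, 150, intercept = 5, slope = -0.006,
                                participant_sd = 0.2, trial_sd = 0.15,
                                seed = 16)
  slow <- simulate_group_series(12, 150, intercept = 5, slope = -0.002,
                                participant_sd = 0.2, trial_sd = 0.15,
                                seed = 17)
  fa <- bootstrap_fit(fast, "poly1", n_boot = 200, seed = 18)
  fb <- bootstrap_fit(slow, "poly1", n_boot = 200, seed = 18)
  con <- group_contrast(fa, fb, "p1")
  expect_true(con$significant)
  expect_lt(con$conf.high, 0)

  self <- group_contrast(fa, fa, "p1")
  expect_equal(self$estimate, 0)
  expect_equal(self$conf.low, 0)
  expect_false(self$significant)

  fx <- bootstrap_fit(fast, "exp1", n_boot = 30, seed = 19)
  expect_error(group_contrast(fa, fx, "p1"),
               class = "seqreach_parameter_error")
})

test_that("baseline correction removes participant offsets", {
  series <- simulate_group_series(5, 20, participant_sd = 1,
                                  trial_sd = 0.05, seed = 20, floor = -100)
  base <- series |>
    dplyr::group_by(participant) |>
    dplyr::summarise(baseline = value[trial == 1])
  corr <- baseline_correct(series, base)
  start <- corr |>
    dplyr::group_by(participant) |>
    dplyr::summarise(v1 = value[trial == 1])
  expect_true(all(abs(start$v1) < 1e-12))

  # translation invariance: shifting one participant and their baseline
  shifted <- series |>
    dplyr::mutate(value = value + 3 * (participant == 2))
  base2 <- dplyr::mutate(base,
                         baseline = baseline + 3 * (participant == 2))
  expect_equal(baseline_correct(shifted, base2)$value, corr$value)

  expect_error(baseline_correct(series, base[-1, ]),
               class = "seqreach_data_error")
})

test_that("baseline correction shrinks between-participant variance", {
  series <- simulate_group_series(30, 40, participant_sd = 1,
                                  trial_sd = 0.2, seed = 21, floor = -100)
  base <- series |>
    dplyr::group_by(participant) |>
    dplyr::summarise(baseline = mean(value[trial <= 5]))
  corr <- baseline_correct(series, base)
  v_raw <- var(series$value[series$trial == 10])
  v_corr <- var(corr$value[corr$trial == 10])
  expect_lt(v_corr, v_raw / 2)
  expect_lt(v_corr, 5 * 0.2^2)
})

test_that("early-training means match direct averages", {
  series <- tibble::tibble(participant = rep(1:2, each = 6),
                           trial = rep(1:6, 2),
                           value = c(5, 5, 5, 5, 5, 9, 1:6))
  em <- early_training_mean(series, 5)
  expect_equal(em$early_mean, c(5, 3))
  expect_error(early_training_mean(series[series$trial <= 3, ], 5),
               class = "seqreach_data_error")
})

test_that("slope estimates are robust to dropping the first five trials", {
  series <- simulate_group_series(12, 150, intercept = 5, slope = -0.004,
                                  participant_sd = 0.2, trial_sd = 0.15,
                                  seed = 22)
  full <- bootstrap_fit(series, "poly1", n_boot = 150, seed = 23)
  trimmed <- bootstrap_fit(dplyr::filter(series, trial > 5), "poly1",
                           n_boot = 150, seed = 23)
  ci <- tidy(full)
  half_width <- diff(unlist(ci[ci$term == "p1",
                               c("conf.low", "conf.high")])) / 2
  expect_lt(abs(unname(trimmed$estimate["p1"] - full$estimate["p1"])),
            half_width)
})
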