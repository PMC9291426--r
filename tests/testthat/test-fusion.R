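test_that("fusion index matches its defining anchors", {
  expect_equal(fusion_index(20, 20, 20), 1)       # fully coarticulated
  expect_equal(fusion_index(20, 30, 0), 0)        # full stop
  expect_equal(fusion_index(20, 30, 10), 0.4)     # 1 - (25 - 10)/25
  expect_equal(fusion_index(8, 12, 5), 0.5)
})

test_that("fusion index is scale invariant and clamped under noise", {
  for (c in c(0.1, 1, 7.3)) {
    expect_equal(fusion_index(c * 20, c * 30, c * 10), 0.4)
  }
  expect_warning(fi <- fusion_index(10, 10, 15), "clamped")
  expect_equal(fi, 1)
  expect_error(fusion_index(0, 10, 5), class = "seqreach_parameter_error")
  expect_error(fusion_index(10, 10, -1), class = "seqreach_parameter_error")
})

test_that("per-trial fusion sums the 7 transition indices", {
  mk <- function(vmax, vmin) {
    tibble::tibble(vmax_per_segment = list(vmax),
                   vmin_per_transition = list(vmin))
  }
  full <- trial_fusion(mk(rep(20, 8), rep(20, 7)))
  expect_equal(full$fi_trial, 7)
  none <- trial_fusion(mk(rep(20, 8), rep(0, 7)))
  expect_equal(none$fi_trial, 0)
  # mixed, against per-transition hand computation
  vmax <- c(10, 20, 30, 20, 10, 20, 30, 20)
  vmin <- c(5, 10, 0, 15, 15, 25, 10)
  got <- trial_fusion(mk(vmax, vmin))
  by_hand <- pmin(pmax(vmin / ((head(vmax, -1) + tail(vmax, -1)) / 2), 0), 1)
  expect_equal(got$fi_per_transition[[1]], by_hand)
  expect_equal(got$fi_trial, sum(by_hand))
  expect_error(trial_fusion(mk(rep(20, 8), rep(1, 5))),
               class = "seqreach_parameter_error")
})

test_that("radial distance hits its printed anchors", {
  # synthetic analyzed table: peaks placed by hand on each segment
  W <- seqreach:::waypoint_matrix(fixture_geometry)
  place <- function(frac) {
    # peak at `frac` of the straight line from segment start to end
    lapply(1:10, function(i) {
      t(vapply(1:8, function(k) {
        W[k, ] + frac * (W[k + 1, ] - W[k, ])
      }, numeric(2)))
    })
  }
  mk <- function(locs) {
    tibble::tibble(trial = seq_along(locs), vmax_location = locs)
  }
  # centroid exactly on the via point -> 100%
  at_via <- lapply(1:10, function(i) {
    matrix(rep(W[1, ], 8), 8, 2, byrow = TRUE)
  })
  rd100 <- radial_distance(mk(at_via), fixture_geometry, window = 10)
  expect_true(all(rd100$rd_percent == 100))
  # peak at the reach midpoint -> 50%
  rd50 <- radial_distance(mk(place(0.5)), fixture_geometry, window = 10)
  expect_equal(rd50$rd_percent, rep(50, 6), tolerance = 1e-10)
  # centroid 2.5 cm short of the via on a 10-cm reach -> 75%
  locs <- place(1)
  locs <- lapply(locs, function(m) {
    m[2, ] <- W[3, ] + c(0, -2.5) * sign(W[2, 2] - W[3, 2])  # on t1->via
    m
  })
  rd <- radial_distance(mk(locs), fixture_geometry, window = 10)
  expect_equal(rd$rd_percent[rd$segment == 2][1], 75)
})

test_that("noiseless zero-fusion trials land in the 45-55% band", {
  cfg <- simulation_config(seed = 3, movement_time_s = 4, fusion_level = 0,
                           learning_model = list(intercept = 4, slope = 0,
                                                 participant_sd = 0,
                                                 trial_sd = 0, floor = 1),
                           fusion_trend = list(intercept = 0, slope = 0))
  ds <- simulate_learning_dataset(fixture_geometry, cfg, 1, 12)
  an <- analyze_trials(ds$trajectories, fixture_geometry)
  rd <- radial_distance(an, fixture_geometry, window = 10)
  expect_true(all(rd$rd_percent > 45 & rd$rd_percent < 55))
})

test_that("radial distance is invariant under rigid motions", {
  cfg <- simulation_config(seed = 4, movement_time_s = 4,
                           fusion_level = 0.5)
  an <- purrr::map(1:10, function(i) {
    res <- analyze_one(sim_trial(fusion_level = 0.5))
    res$met$trial <- i
    res$met
  }) |> purrr::list_rbind()
  rd1 <- radial_distance(an, fixture_geometry, window = 10)

  th <- 1.1; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- c(-4, 9)
  an2 <- an
  an2$vmax_location <- lapply(an$vmax_location, function(m) {
    m %*% t(R) + rep(shift, each = nrow(m))
  })
  geom2 <- fixture_geometry
  wxy <- as.matrix(geom2$waypoints[, c("x", "y")]) %*% t(R) +
    rep(shift, each = 9)
  geom2$waypoints$x <- wxy[, 1]; geom2$waypoints$y <- wxy[, 2]
  rd2 <- radial_distance(an2, geom2, window = 10)
  expect_equal(rd1$rd_percent, rd2$rd_percent, tolerance = 1e-8)
})

test_that("degenerate scatter gives a zero-axis ellipse and valid centroid", {
  locs <- lapply(1:10, function(i) matrix(rep(c(1, 2), 8), 8, 2,
                                          byrow = TRUE))
  rd <- radial_distance(tibble::tibble(trial = 1:10,
                                       vmax_location = locs),
                        fixture_geometry, window = 10)
  expect_true(all(rd$ellipse_major == 0))
  expect_true(all(rd$centroid_x == 1 & rd$centroid_y == 2))
  expect_error(radial_distance(tibble::tibble(trial = 1:5,
                                              vmax_location = locs[1:5]),
                               fixture_geometry, window = 10),
               class = "seqreach_parameter_error")
})

test_that("confidence ellipse covers ~95% of bivariate-normal points", {
  set.seed(8)
  S <- matrix(c(2, 0.7, 0.7, 1), 2)
  xy <- MASS::mvrnorm(4000, c(1, -1), S)
  ell <- seqreach:::confidence_ellipse(xy, 0.95)
  R <- cbind(c(cos(ell$angle), sin(ell$angle)),
             c(-sin(ell$angle), cos(ell$angle)))
  rel <- (xy - rep(ell$centroid, each = nrow(xy))) %*% R
  inside <- (rel[, 1] / ell$axes[1])^2 + (rel[, 2] / ell$axes[2])^2 <= 1
  expect_gt(mean(inside), 0.93)
  expect_lt(mean(inside), 0.97)
})

test_that("piecewise fit recovers a noiseless hinge exactly", {
  x <- seq(0, 4, length.out = 200)
  y <- -0.1 * x + 1 * pmax(0, x - 1.6)   # slopes -0.1 then +0.9
  fit <- piecewise_fit(x, y)
  expect_equal(fit$knot, 1.6, tolerance = 1e-3)
  expect_equal(unname(fit$slopes), c(-0.1, 0.9), tolerance = 1e-3)
  expect_lt(fit$sse, 1e-6)
})

test_that("piecewise fit recovers a noisy hinge within 0.15", {
  set.seed(21)
  x <- runif(500, 0, 4)
  y <- -0.1 * x + 1 * pmax(0, x - 1.6) + rnorm(500, 0, 0.5)
  fit <- piecewise_fit(x, y)
  expect_lt(abs(fit$knot - 1.6), 0.15)
})

test_that("two-segment fit nests the single line", {
  set.seed(3)
  x <- seq(0, 10, length.out = 60)
  y <- 2 + 0.5 * x + rnorm(60, 0, 0.1)
  fit <- piecewise_fit(x, y)
  lin <- lm(y ~ x)
  expect_lte(fit$sse, sum(resid(lin)^2) + 1e-10)
  expect_equal(unname(fit$slopes[1]), unname(fit$slopes[2]),
               tolerance = 0.15)
  expect_error(piecewise_fit(1:4, 1:4), class = "seqreach_fit_error")
})
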