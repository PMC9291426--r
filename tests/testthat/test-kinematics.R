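test_that("velocity of stationary and uniform motion is exact", {
  t <- seq(0, 1, by = 1 / 110)
  still <- tibble::tibble(t = t, x = 3, y = -2)
  expect_true(all(compute_velocity(still)$speed < 1e-10))

  uni <- tibble::tibble(t = t, x = 4 * t, y = 0)
  v <- compute_velocity(uni)
  interior <- v$speed[10:(length(t) - 10)]
  expect_equal(interior, rep(4, length(interior)), tolerance = 1e-6)
})

test_that("minimum-jerk reach peak speed survives smoothing within 2%", {
  t <- seq(0, 1, by = 1 / 110)
  mj <- predict(min_jerk_trajectory(c(0, 0), c(10, 0), duration = 1),
                times = t)
  v <- compute_velocity(tibble::tibble(t = t, x = mj$x, y = mj$y))
  expect_equal(max(v$speed), 18.75, tolerance = 0.02)
})

test_that("velocity computation rejects bad input", {
  t <- seq(0, 1, by = 0.1)
  expect_error(compute_velocity(tibble::tibble(t = c(0, 0.1), x = 0:1,
                                               y = 0:1)),
               class = "seqreach_data_error")
  bad <- tibble::tibble(t = c(0, 0.2, 0.1), x = 1:3, y = 1:3)
  expect_error(compute_velocity(bad), class = "seqreach_data_error")
})

test_that("a clean full-sequence trial yields 8 segments and 7 transitions", {
  for (f in c(0, 1)) {
    traj <- sim_trial(fusion_level = f)
    seg <- segment_trial(compute_velocity(traj), traj, fixture_geometry)
    expect_identical(nrow(seg$segments), 8L)
    expect_identical(nrow(seg$transitions), 7L)
    expect_true(all(seg$segments$start_idx <= seg$segments$end_idx))
    expect_true(all(diff(seg$segments$end_idx) > 0))
  }
})

test_that("an aborted trajectory raises an incomplete-trial error naming the waypoint", {
  traj <- sim_trial()
  W <- seqreach:::waypoint_matrix(fixture_geometry)
  # cut the trajectory after the third waypoint is reached
  d3 <- sqrt((traj$x - W[4, 1])^2 + (traj$y - W[4, 2])^2)
  cut <- which(d3 < fixture_geometry$proximity_radius)[1] + 3L
  err <- expect_error(
    segment_trial(compute_velocity(traj[1:cut, ]), traj[1:cut, ],
                  fixture_geometry),
    class = "seqreach_incomplete_trial_error")
  expect_match(conditionMessage(err), "waypoint 5")
})

test_that("segment boundaries equal the first proximity-entry samples", {
  traj <- sim_trial(fusion_level = 0.3)
  vel <- compute_velocity(traj)
  seg <- segment_trial(vel, traj, fixture_geometry)
  W <- seqreach:::waypoint_matrix(fixture_geometry)
  # independent oracle: walk the proximity predicate directly
  cursor <- 1L
  for (k in 1:8) {
    d <- sqrt((traj$x - W[k + 1, 1])^2 + (traj$y - W[k + 1, 2])^2)
    hit <- which(d[cursor:nrow(traj)] < 2)[1] + cursor - 1L
    expect_identical(seg$segments$end_idx[k], hit)
    cursor <- hit + 1L
  }
})

test_that("segmentation is invariant under rigid rotation and translation", {
  traj <- sim_trial(fusion_level = 0.5)
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- c(12, -7)
  rot <- function(x, y) cbind(x, y) %*% t(R) + rep(shift, each = length(x))
  traj2 <- traj
  xy <- rot(traj$x, traj$y)
  traj2$x <- xy[, 1]; traj2$y <- xy[, 2]

  geom2 <- fixture_geometry
  wxy <- rot(geom2$waypoints$x, geom2$waypoints$y)
  geom2$waypoints$x <- wxy[, 1]; geom2$waypoints$y <- wxy[, 2]

  s1 <- segment_trial(compute_velocity(traj), traj, fixture_geometry)
  s2 <- segment_trial(compute_velocity(traj2), traj2, geom2)
  expect_identical(s1$segments, s2$segments)
  expect_identical(s1$transitions, s2$transitions)
})

test_that("per-segment maxima and transition minima obey their definitions", {
  traj <- sim_trial(fusion_level = 0.5)
  vel <- compute_velocity(traj)
  seg <- segment_trial(vel, traj, fixture_geometry)
  met <- trial_metrics(seg, vel, traj, fixture_geometry)
  vmax <- met$vmax_per_segment[[1]]
  vmin <- met$vmin_per_transition[[1]]
  expect_length(vmax, 8L)
  expect_length(vmin, 7L)
  for (k in 1:8) {
    idx <- seg$segments$start_idx[k]:seg$segments$end_idx[k]
    expect_equal(vmax[k], max(vel$speed[idx]))
  }
  expect_equal(met$vmax_mean, mean(vmax))
  expect_equal(met$vmin_mean, mean(vmin))
  # noiseless: each transition minimum below both adjacent peaks
  expect_true(all(vmin <= pmin(head(vmax, -1), tail(vmax, -1)) + 1e-9))
})

test_that("peak speed trades off against configured movement time", {
  fast <- analyze_one(sim_trial(movement_time_s = 3))$met$vmax_mean
  slow <- analyze_one(sim_trial(movement_time_s = 6))$met$vmax_mean
  expect_gt(fast, slow)
})

test_that("corrective submovements are detected and clean trials are not", {
  expect_false(analyze_one(sim_trial(fusion_level = 0.4))$met$corrected)
  for (mw in c(2, 4, 6, 8)) {
    traj <- sim_trial(fusion_level = 0.4, corrected = TRUE,
                      miss_waypoint = mw)
    expect_true(analyze_one(traj)$met$corrected)
  }
})

test_that("detected corrected fraction matches the injection probability", {
  cfg <- simulation_config(seed = 5, corrected_trial_prob = 0.2,
                           noise_sd_cm = 0.03, movement_time_s = 4)
  ds <- simulate_learning_dataset(fixture_geometry, cfg, 4, 15)
  an <- analyze_trials(ds$trajectories, fixture_geometry)
  joined <- dplyr::inner_join(
    an[, c("participant", "trial", "corrected")],
    ds$truth[, c("participant", "trial", "corrected")],
    by = c("participant", "trial"), suffix = c("_det", "_true"))
  # detection must agree with the ground truth labels
  expect_equal(joined$corrected_det, joined$corrected_true)
  # and the flagged fraction lies inside binomial 95% bounds for p = 0.2
  n <- nrow(joined)
  bounds <- qbinom(c(0.025, 0.975), n, 0.2) / n
  expect_gte(mean(joined$corrected_det), bounds[1])
  expect_lte(mean(joined$corrected_det), bounds[2])
})
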