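# Synthetic trial and dataset generation.
#
# The generator builds each trial from a "knot plan": one row per waypoint
# of the reach sequence carrying the boundary conditions (position,
# velocity, acceleration) imposed at that waypoint and the dwell spent
# there. Between knots the motion is the clamped minimum-jerk quintic for
# those boundary conditions. Boundary velocities/accelerations at the
# interior waypoints are fusion_level times the values of the fully fused
# C^4 via-point pass, so fusion_level = 0 gives discrete point-to-point
# reaches with full stops and fusion_level = 1 reproduces the single fused
# minimum-jerk pass exactly.

#' Simulation configuration
#'
#' Bundles the tunable parameters of the synthetic trajectory generator.
#'
#' @param fusion_level Fusion level in `[0, 1]`: 0 = full stop at every via
#'   transition, 1 = one merged minimum-jerk via-point pass.
#' @param movement_time_s Target measured movement time in seconds: the time
#'   between leaving the 2-cm start region and first entering the 2-cm
#'   region of the final waypoint (the generator calibrates the trajectory
#'   so the measured MT equals this value).
#' @param dwell_s Stop duration (s) at each transition when fully unfused;
#'   the realized dwell is `(1 - fusion_level) * dwell_s`.
#' @param sampling_rate_hz Sampling rate (Hz), 110 by default.
#' @param noise_sd_cm Standard deviation (cm) of additive isotropic Gaussian
#'   position noise applied to every sample.
#' @param reaction_time_s Stationary lead-in before motion onset (s),
#'   emulating reaction time.
#' @param seed Optional integer seed; when set, stochastic generation is
#'   reproducible and the caller's RNG state is untouched.
#' @param corrected_trial_prob Probability that a trial contains a
#'   corrective submovement (a missed target re-acquired after a reversal).
#' @param miss_cm Lateral miss distance (cm) used when injecting a
#'   corrective submovement; must exceed the proximity radius for the miss
#'   to register.
#' @param learning_model List with `intercept` (s), `slope` (s/trial),
#'   `participant_sd` (s), `trial_sd` (s), and `floor` (s): the trial-wise
#'   movement-time generative model for multi-participant datasets.
#' @param fusion_trend List with `intercept` and `slope`: trial-wise true
#'   fusion level, clamped to `[0, 1]`.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- simulation_config(fusion_level = 0.5, movement_time_s = 4)
#' @export
simulation_config <- function(fusion_level = 0,
                              movement_time_s = 5,
                              dwell_s = 0.25,
                              sampling_rate_hz = 110,
                              noise_sd_cm = 0,
                              reaction_time_s = 0.3,
                              seed = NULL,
                              corrected_trial_prob = 0,
                              miss_cm = 3,
                              learning_model = list(intercept = 5,
                                                    slope = -0.002,
                                                    participant_sd = 0.3,
                                                    trial_sd = 0.2,
                                                    floor = 1),
                              fusion_trend = list(intercept = 0.05,
                                                  slope = 0.002)) {
  check_number(fusion_level, "fusion_level", lower = 0, upper = 1)
  check_number(movement_time_s, "movement_time_s", lower = 0)
  if (movement_time_s <= 0) {
    abort("`movement_time_s` must be positive.",
          class = "seqreach_parameter_error")
  }
  check_number(dwell_s, "dwell_s", lower = 0)
  check_number(sampling_rate_hz, "sampling_rate_hz", lower = 0)
  if (sampling_rate_hz <= 0) {
    abort("`sampling_rate_hz` must be positive.",
          class = "seqreach_parameter_error")
  }
  check_number(noise_sd_cm, "noise_sd_cm", lower = 0)
  check_number(reaction_time_s, "reaction_time_s", lower = 0)
  check_number(corrected_trial_prob, "corrected_trial_prob",
               lower = 0, upper = 1)
  structure(
    list(fusion_level = fusion_level, movement_time_s = movement_time_s,
         dwell_s = dwell_s, sampling_rate_hz = sampling_rate_hz,
         noise_sd_cm = noise_sd_cm, reaction_time_s = reaction_time_s,
         seed = seed, corrected_trial_prob = corrected_trial_prob,
         miss_cm = miss_cm, learning_model = learning_model,
         fusion_trend = fusion_trend),
    class = "sim_config"
  )
}

# Build the knot plan for one trial. Each interior knot carries a
# fusion-scaled passage velocity and a dwell of (1 - f) * dwell_s; during
# the dwell the motion coasts linearly through the waypoint at the passage
# velocity (a true stop when f = 0), so the speed profile stays continuous
# and its transition minimum equals f times the fused via speed.
build_trial_plan <- function(geometry, config, corrected = FALSE,
                             miss_waypoint = NULL) {
  W <- waypoint_matrix(geometry)
  f <- config$fusion_level
  n_seg <- nrow(W) - 1L

  chord <- sqrt(rowSums((W[-1L, , drop = FALSE] -
                           W[-nrow(W), , drop = FALSE])^2))
  T_move <- config$movement_time_s
  d <- T_move * chord / sum(chord)

  # fully fused reference pass: C^4 via-point solution at these times
  cx <- mj_solve_axis(W[, 1L], d)
  cy <- mj_solve_axis(W[, 2L], d)
  kt <- c(0, cumsum(d))
  inner <- kt[-c(1L, length(kt))]
  v_via <- cbind(mj_eval(cx, kt, inner, 1L), mj_eval(cy, kt, inner, 1L))
  a_via <- cbind(mj_eval(cx, kt, inner, 2L), mj_eval(cy, kt, inner, 2L))

  # per-knot boundary conditions: fusion_level-scaled fused values
  knots <- tibble(
    x = W[, 1L], y = W[, 2L],
    vx = c(0, f * v_via[, 1L], 0), vy = c(0, f * v_via[, 2L], 0),
    ax = c(0, f * a_via[, 1L], 0), ay = c(0, f * a_via[, 2L], 0),
    dwell_after = c(0, rep((1 - f) * config$dwell_s, n_seg - 1L), 0)
  )

  if (corrected) {
    # inject a missed-then-corrected target at one interior waypoint: the
    # main reach aims past the target (lateral offset plus overshoot along
    # the incoming direction), stops, then a corrective submovement
    # re-acquires the true waypoint after the heading reversal.
    k <- miss_waypoint %||% 2L           # row index into knots (2..n_seg)
    inc <- c(knots$x[k] - knots$x[k - 1L], knots$y[k] - knots$y[k - 1L])
    L_in <- sqrt(sum(inc^2))
    inc <- inc / L_in
    perp <- c(-inc[2L], inc[1L])
    # miss on the side the entry velocity already bends toward, so the
    # approach curve does not have to cross the target line
    v_in <- c(knots$vx[k - 1L], knots$vy[k - 1L])
    bend <- inc[1L] * v_in[2L] - inc[2L] * v_in[1L]
    if (is.finite(bend) && bend < 0) perp <- -perp
    w_k <- c(knots$x[k], knots$y[k])
    clear <- min(config$miss_cm, 0.7 * L_in)  # closest-approach distance
    over <- 2.5                               # overshoot past the target
    # flyby knot pins the path at the clearance offset while still moving
    # forward, so the miss registers regardless of the entry curvature
    flyby <- w_k + clear * perp
    v_pass <- 0.6 * L_in / (T_move / (nrow(knots) - 1L))
    flyby_row <- tibble(x = flyby[1L], y = flyby[2L],
                        vx = v_pass * inc[1L], vy = v_pass * inc[2L],
                        ax = 0, ay = 0, dwell_after = 0)
    miss <- w_k + clear * perp + over * inc
    miss_row <- tibble(x = miss[1L], y = miss[2L], vx = 0, vy = 0,
                       ax = 0, ay = 0, dwell_after = 0.05)
    knots$vx[k] <- knots$vy[k] <- knots$ax[k] <- knots$ay[k] <- 0
    knots$dwell_after[k] <- max(knots$dwell_after[k], 0.05)
    knots <- bind_rows(knots[seq_len(k - 1L), ], flyby_row, miss_row,
                       knots[k:nrow(knots), ])
    chord <- sqrt(diff(knots$x)^2 + diff(knots$y)^2)
    d <- T_move * chord / sum(chord)
  }

  list(knots = knots, durations = d)
}

# Continuous-time evaluator for a plan: function(t) -> cbind(x, y).
# Interior knots with a dwell are traversed as a linear coast at the
# boundary velocity, centred on the waypoint; quintic segments connect the
# coast endpoints with clamped boundary conditions (boundary acceleration
# is zeroed next to a coast, which moves at constant velocity).
plan_evaluator <- function(plan) {
  knots <- plan$knots
  d <- plan$durations
  n_seg <- length(d)
  n_k <- nrow(knots)

  dw <- knots$dwell_after
  vx <- knots$vx; vy <- knots$vy
  # coast entry/exit positions around each knot
  ex_x <- knots$x - vx * dw / 2   # entry
  ex_y <- knots$y - vy * dw / 2
  xx_x <- knots$x + vx * dw / 2   # exit
  xx_y <- knots$y + vy * dw / 2

  coef_x <- matrix(0, n_seg, 6L)
  coef_y <- matrix(0, n_seg, 6L)
  for (i in seq_len(n_seg)) {
    a0x <- if (dw[i] > 0) 0 else knots$ax[i]
    a0y <- if (dw[i] > 0) 0 else knots$ay[i]
    a1x <- if (dw[i + 1L] > 0) 0 else knots$ax[i + 1L]
    a1y <- if (dw[i + 1L] > 0) 0 else knots$ay[i + 1L]
    coef_x[i, ] <- mj_clamped_segment(xx_x[i], ex_x[i + 1L],
                                      vx[i], vx[i + 1L], a0x, a1x, d[i])
    coef_y[i, ] <- mj_clamped_segment(xx_y[i], ex_y[i + 1L],
                                      vy[i], vy[i + 1L], a0y, a1y, d[i])
  }

  # piece schedule: segment i, then coast after knot i+1 (duration may be 0)
  seg_start <- cumsum(c(0, head(d + dw[-1L], -1L)))
  seg_end <- seg_start + d
  total <- seg_end[n_seg] + dw[n_k]
  eval_pos <- function(t) {
    i <- findInterval(t, seg_start)
    i[i < 1L] <- 1L
    i[i > n_seg] <- n_seg
    n <- length(t)
    x <- numeric(n); y <- numeric(n)
    in_coast <- t > seg_end[i]          # inside the dwell after segment i
    for (j in seq_len(n)) {
      if (in_coast[j]) {
        k <- i[j] + 1L                  # coasting knot
        tau <- min(t[j] - seg_end[i[j]], dw[k]) - dw[k] / 2
        x[j] <- knots$x[k] + vx[k] * tau
        y[j] <- knots$y[k] + vy[k] * tau
      } else {
        u <- min(max((t[j] - seg_start[i[j]]) / d[i[j]], 0), 1)
        x[j] <- sum(coef_x[i[j], ] * quintic_row(u, 0L))
        y[j] <- sum(coef_y[i[j], ] * quintic_row(u, 0L))
      }
    }
    cbind(x, y)
  }
  list(eval = eval_pos, total = total, seg_start = seg_start,
       seg_end = seg_end)
}

# First continuous time at which the plan's noiseless path crosses
# distance `r` from point `p` (increasing = moving away).
crossing_time <- function(ev, p, r, from, to, outward = TRUE) {
  g <- function(t) {
    q <- ev$eval(t)
    sqrt((q[, 1L] - p[1L])^2 + (q[, 2L] - p[2L])^2) - r
  }
  grid <- seq(from, to, length.out = 400L)
  v <- g(grid)
  sgn <- if (outward) v > 0 else v < 0
  i <- which(sgn)[1L]
  if (is.na(i) || i == 1L) return(grid[which(sgn)[1L]] %||% NA_real_)
  stats::uniroot(g, c(grid[i - 1L], grid[i]), tol = 1e-8)$root
}

#' Simulate one trial of the sequential reaching task
#'
#' Generates a uniformly sampled 2-D trajectory traversing the full reach
#' sequence of `geometry`. At `fusion_level = 0` every movement is a
#' point-to-point minimum-jerk reach separated by a full stop of
#' `dwell_s` seconds; at `fusion_level = 1` the whole sequence is a single
#' C^4 minimum-jerk via-point pass with no stops; intermediate levels scale
#' both the dwell and the via passage velocity/acceleration. The trajectory
#' is time-calibrated so that the measured movement time (2-cm start-region
#' exit to first 2-cm entry of the final waypoint) equals
#' `movement_time_s`, then sampled at `sampling_rate_hz` with optional
#' additive Gaussian position noise.
#'
#' @param geometry A [build_geometry()] object.
#' @param config A [simulation_config()].
#' @param corrected If `TRUE`, inject a corrective submovement: one target
#'   is missed laterally by `miss_cm` and re-acquired after a reversal.
#' @param miss_waypoint Waypoint index (2..8) to miss when
#'   `corrected = TRUE`; defaults to the first outward target.
#' @return A tibble with columns `t`, `x`, `y` (seconds, cm).
#' @examples
#' geom <- build_geometry()
#' traj <- simulate_trial(geom, simulation_config(movement_time_s = 4))
#' @export
simulate_trial <- function(geometry, config, corrected = FALSE,
                           miss_waypoint = NULL) {
  stopifnot(inherits(geometry, "reach_geometry"),
            inherits(config, "sim_config"))
  with_seed_if(config$seed, {
    simulate_trial_impl(geometry, config, corrected, miss_waypoint)
  })
}

simulate_trial_impl <- function(geometry, config, corrected = FALSE,
                                miss_waypoint = NULL) {
  plan <- build_trial_plan(geometry, config, corrected = corrected,
                           miss_waypoint = miss_waypoint)
  ev <- plan_evaluator(plan)
  W <- waypoint_matrix(geometry)
  p0 <- W[1L, ]
  pN <- W[nrow(W), ]
  r <- geometry$proximity_radius

  # measured MT in unscaled time: 2-cm exit from start to first 2-cm entry
  # of the final waypoint (searched within the last segment)
  n_seg <- length(plan$durations)
  t_exit <- crossing_time(ev, p0, r, 0, ev$seg_end[1L], outward = TRUE)
  t_entry <- crossing_time(ev, pN, r, ev$seg_start[n_seg],
                           ev$seg_end[n_seg], outward = FALSE)
  s <- (t_entry - t_exit) / config$movement_time_s  # global time rescale

  fs <- config$sampling_rate_hz
  lead <- config$reaction_time_s
  total_scaled <- ev$total / s
  t_grid <- seq(0, lead + total_scaled + 2 / fs, by = 1 / fs)
  moving <- t_grid > lead
  pos <- matrix(rep(p0, each = length(t_grid)), ncol = 2L)
  if (any(moving)) {
    pos[moving, ] <- ev$eval(pmin((t_grid[moving] - lead) * s, ev$total))
  }
  if (config$noise_sd_cm > 0) {
    pos <- pos + rnorm(length(pos), sd = config$noise_sd_cm)
  }
  tibble(t = t_grid, x = pos[, 1L], y = pos[, 2L])
}

#' Simulate trial-wise value series for a group of participants
#'
#' Draws per-participant, per-trial values from the additive learning-curve
#' model used by the trajectory generator: value =
#' `intercept + slope * trial + participant offset + trial noise`, truncated
#' below at `floor`. This is the generative model behind the movement-time
#' trends of [simulate_learning_dataset()] and is useful on its own for
#' parameter-recovery studies of the bootstrap fitting stage.
#'
#' @param n_participants,n_trials Counts.
#' @param intercept,slope Fixed-effect intercept and per-trial slope.
#' @param participant_sd SD of the participant-level offset.
#' @param trial_sd SD of the trial-level noise.
#' @param floor Lower truncation bound.
#' @param group Optional group label attached to the output.
#' @param seed Optional seed.
#' @return A tibble with `participant`, `trial`, `value` (and `group`).
#' @examples
#' series <- simulate_group_series(5, 50, intercept = 5, slope = -0.002,
#'                                 seed = 1)
#' @export
simulate_group_series <- function(n_participants, n_trials,
                                  intercept = 5, slope = -0.002,
                                  participant_sd = 0.3, trial_sd = 0.2,
                                  floor = 1, group = NULL, seed = NULL) {
  check_count(n_participants, "n_participants")
  check_count(n_trials, "n_trials", lower = 2L)
  with_seed_if(seed, {
    offsets <- rnorm(n_participants, 0, participant_sd)
    out <- tidyr::expand_grid(participant = seq_len(n_participants),
                              trial = seq_len(n_trials))
    out$value <- pmax(
      intercept + slope * out$trial + offsets[out$participant] +
        rnorm(nrow(out), 0, trial_sd),
      floor
    )
    if (!is.null(group)) out$group <- group
    out
  })
}

#' Simulate a multi-participant learning dataset of full trajectories
#'
#' Generates per-trial trajectories for `n_participants` participants over
#' `n_trials` trials. Each participant's true movement time follows the
#' additive learning model in `config$learning_model`; the true fusion
#' level follows `config$fusion_trend` (clamped to `[0, 1]`); corrective
#' submovements are injected independently with probability
#' `config$corrected_trial_prob`. All ground-truth labels are returned
#' alongside the trajectories for parameter-recovery testing.
#'
#' @param geometry A [build_geometry()] object.
#' @param config A [simulation_config()]; its `seed` drives all randomness.
#' @param n_participants,n_trials Counts (`n_trials >= 2`).
#' @param group Group label stored with every trial.
#' @return A list of class `reach_dataset` with `trajectories` (long tibble:
#'   `participant`, `trial`, `t`, `x`, `y`), `truth` (tibble: `participant`,
#'   `trial`, `true_mt`, `true_fusion`, `corrected`, `group`), plus the
#'   `geometry` and `config` used.
#' @examples
#' geom <- build_geometry()
#' cfg <- simulation_config(seed = 1, noise_sd_cm = 0.05)
#' ds <- simulate_learning_dataset(geom, cfg, n_participants = 2,
#'                                 n_trials = 3)
#' @export
simulate_learning_dataset <- function(geometry, config, n_participants,
                                      n_trials, group = "sim") {
  stopifnot(inherits(geometry, "reach_geometry"),
            inherits(config, "sim_config"))
  check_count(n_participants, "n_participants")
  check_count(n_trials, "n_trials", lower = 2L)
  lm_par <- config$learning_model
  ft <- config$fusion_trend

  with_seed_if(config$seed, {
    mts <- simulate_group_series(
      n_participants, n_trials,
      intercept = lm_par$intercept, slope = lm_par$slope,
      participant_sd = lm_par$participant_sd, trial_sd = lm_par$trial_sd,
      floor = lm_par$floor %||% 1
    )
    truth <- mts |>
      dplyr::rename(true_mt = "value") |>
      mutate(
        true_fusion = pmin(pmax(ft$intercept + ft$slope * .data$trial, 0), 1),
        corrected = runif(dplyr::n()) < config$corrected_trial_prob,
        group = group
      )
    miss_candidates <- c(2L, 4L, 6L, 8L)  # outward targets in the sequence
    trajectories <- purrr::pmap(
      list(truth$participant, truth$trial, truth$true_mt,
           truth$true_fusion, truth$corrected),
      function(p, tr, mt, fus, corr) {
        cfg_i <- config
        cfg_i$seed <- NULL
        cfg_i$movement_time_s <- mt
        cfg_i$fusion_level <- fus
        traj <- simulate_trial_impl(
          geometry, cfg_i, corrected = corr,
          miss_waypoint = if (corr) sample(miss_candidates, 1L) else NULL
        )
        traj$participant <- p
        traj$trial <- tr
        traj
      }
    ) |>
      purrr::list_rbind() |>
      select("participant", "trial", "t", "x", "y")

    structure(
      list(trajectories = trajectories, truth = truth,
           geometry = geometry, config = config),
      class = "reach_dataset"
    )
  })
}

#' @export
print.reach_dataset <- function(x, ...) {
  cat("<reach_dataset>\n")
  cat(sprintf("  %d participant(s) x %d trial(s); %d samples total\n",
              dplyr::n_distinct(x$truth$participant),
              dplyr::n_distinct(x$truth$trial), nrow(x$trajectories)))
  cat(sprintf("  corrected trials: %d\n", sum(x$truth$corrected)))
  invisible(x)
}
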