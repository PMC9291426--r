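# Velocity profiles, proximity-based segmentation, and per-trial
# kinematic measures.

# Gaussian smoothing in the sample domain (MATLAB-style convention: sigma
# expressed in samples), kernel truncated at 4*sigma, reflected boundaries.
gaussian_smooth <- function(x, sd_samples) {
  if (sd_samples <= 0) return(x)
  half <- max(1L, ceiling(4 * sd_samples))
  k <- stats::dnorm(-half:half, sd = sd_samples)
  k <- k / sum(k)
  n <- length(x)
  pad <- c(x[pmin(half:1 + 1L, n)], x, x[pmax(n - (1:half), 1L)])
  stats::convolve(pad, rev(k), type = "filter")
}

#' Compute a smoothed tangential velocity profile
#'
#' Differentiates the 2-D positional data by central finite differences
#' (one-sided at the ends, robust to slightly nonuniform timestamps), takes
#' the tangential speed (magnitude of the planar velocity), and smooths it
#' with a Gaussian kernel of standard deviation `smoothing_sd_samples`
#' samples (default 2), truncated at four standard deviations with
#' reflected boundaries.
#'
#' @param trajectory Data frame with columns `t` (s, strictly increasing),
#'   `x`, `y` (cm); at least 3 samples.
#' @param smoothing_sd_samples Gaussian kernel SD in samples.
#' @return A tibble with `t` and `speed` (cm/s), one row per input sample,
#'   with the smoothing SD recorded in attribute `smoothing_sd_samples`
#'   and the median sampling rate in attribute `sampling_rate_hz`.
#' @examples
#' geom <- build_geometry()
#' traj <- simulate_trial(geom, simulation_config(movement_time_s = 4))
#' vel <- compute_velocity(traj)
#' @export
compute_velocity <- function(trajectory, smoothing_sd_samples = 2) {
  check_trajectory_df(trajectory, min_samples = 3L)
  check_number(smoothing_sd_samples, "smoothing_sd_samples", lower = 0)
  t <- trajectory$t
  n <- length(t)
  grad <- function(p) {
    g <- numeric(n)
    g[1L] <- (p[2L] - p[1L]) / (t[2L] - t[1L])
    g[n] <- (p[n] - p[n - 1L]) / (t[n] - t[n - 1L])
    i <- 2:(n - 1L)
    g[i] <- (p[i + 1L] - p[i - 1L]) / (t[i + 1L] - t[i - 1L])
    g
  }
  speed <- sqrt(grad(trajectory$x)^2 + grad(trajectory$y)^2)
  speed <- pmax(gaussian_smooth(speed, smoothing_sd_samples), 0)
  out <- tibble(t = t, speed = speed)
  attr(out, "smoothing_sd_samples") <- smoothing_sd_samples
  attr(out, "sampling_rate_hz") <- 1 / median(diff(t))
  out
}

#' Segment a trial into submovements by target proximity
#'
#' Walks the reach sequence of `geometry` through the trajectory: segment
#' *k* ends at the first sample whose position lies strictly within the
#' proximity radius (2 cm by default) of the *k*-th upcoming waypoint and
#' after the previous segment's end; segment *k + 1* starts at the next
#' sample. Transition window *k* is the maximal contiguous run of samples
#' within the proximity radius of intermediate waypoint *k* that contains
#' the segment boundary. A complete trial yields 8 segments and 7
#' transitions.
#'
#' @param profile A [compute_velocity()] profile for the same trial.
#' @param trajectory The trial's trajectory (`t`, `x`, `y`).
#' @param geometry A [build_geometry()] object.
#' @return An object of class `segmented_trial`: a list with tibbles
#'   `segments` (`segment`, `waypoint_id`, `start_idx`, `end_idx`) and
#'   `transitions` (`transition`, `waypoint_id`, `start_idx`, `end_idx`,
#'   `boundary_idx`).
#' @examples
#' geom <- build_geometry()
#' traj <- simulate_trial(geom, simulation_config(movement_time_s = 4))
#' seg <- segment_trial(compute_velocity(traj), traj, geom)
#' seg$segments
#' @export
segment_trial <- function(profile, trajectory, geometry) {
  stopifnot(inherits(geometry, "reach_geometry"))
  check_trajectory_df(trajectory, min_samples = 3L)
  if (nrow(profile) != nrow(trajectory)) {
    abort("`profile` and `trajectory` must have the same number of samples.",
          class = "seqreach_data_error")
  }
  W <- waypoint_matrix(geometry)
  ids <- geometry$reach_sequence
  r <- geometry$proximity_radius
  n <- nrow(trajectory)
  n_seg <- nrow(W) - 1L

  dist_to <- function(k) {
    sqrt((trajectory$x - W[k, 1L])^2 + (trajectory$y - W[k, 2L])^2)
  }

  ends <- integer(n_seg)
  cursor <- 1L
  for (k in seq_len(n_seg)) {
    d <- dist_to(k + 1L)
    hit <- which(d[cursor:n] < r)
    if (!length(hit)) {
      abort(
        sprintf(
          "Incomplete trial: waypoint %d ('%s') never approached within %.1f cm.",
          k + 1L, ids[k + 1L], r),
        class = "seqreach_incomplete_trial_error",
        waypoint = k + 1L
      )
    }
    ends[k] <- cursor + hit[1L] - 1L
    cursor <- min(ends[k] + 1L, n)
  }
  starts <- c(1L, head(ends, -1L) + 1L)

  segments <- tibble(
    segment = seq_len(n_seg),
    waypoint_id = ids[-1L],
    start_idx = starts,
    end_idx = ends
  )

  transitions <- purrr::map(seq_len(n_seg - 1L), function(k) {
    d <- dist_to(k + 1L)
    b <- ends[k]
    inside <- d < r
    lo <- b
    while (lo > 1L && inside[lo - 1L]) lo <- lo - 1L
    hi <- b
    while (hi < n && inside[hi + 1L]) hi <- hi + 1L
    tibble(transition = k, waypoint_id = ids[k + 1L],
           start_idx = lo, end_idx = hi, boundary_idx = b)
  }) |> purrr::list_rbind()

  structure(list(segments = segments, transitions = transitions),
            class = "segmented_trial")
}

#' @export
print.segmented_trial <- function(x, ...) {
  cat("<segmented_trial>\n")
  cat(sprintf("  %d segments, %d transitions\n",
              nrow(x$segments), nrow(x$transitions)))
  invisible(x)
}

#' Per-trial kinematic measures
#'
#' Extracts the trial-level measures from a segmented velocity profile:
#' per-segment maximum speed (and its spatial location), per-transition
#' minimum speed over the transition window, their trial means, movement
#' time (first sample strictly more than 2 cm from the start position to
#' the first entry of the final waypoint's proximity region), reaction time
#' (trial onset to that start-region exit), and the corrected-trial flag
#' from [detect_corrected()].
#'
#' @param segmented A [segment_trial()] result.
#' @param profile The matching velocity profile.
#' @param trajectory The matching trajectory.
#' @param geometry The task geometry.
#' @return A one-row tibble with `movement_time`, `reaction_time`,
#'   `vmax_mean`, `vmin_mean`, `corrected`, and list-columns
#'   `vmax_per_segment` (8 values), `vmin_per_transition` (7 values) and
#'   `vmax_location` (8 x 2 matrix of peak-speed positions).
#' @examples
#' geom <- build_geometry()
#' traj <- simulate_trial(geom, simulation_config(movement_time_s = 4))
#' vel <- compute_velocity(traj)
#' trial_metrics(segment_trial(vel, traj, geom), vel, traj, geom)
#' @export
trial_metrics <- function(segmented, profile, trajectory, geometry) {
  stopifnot(inherits(segmented, "segmented_trial"))
  seg <- segmented$segments
  tra <- segmented$transitions

  vmax <- numeric(nrow(seg))
  vmax_loc <- matrix(NA_real_, nrow(seg), 2L)
  for (i in seq_len(nrow(seg))) {
    idx <- seg$start_idx[i]:seg$end_idx[i]
    j <- idx[which.max(profile$speed[idx])]
    vmax[i] <- profile$speed[j]
    vmax_loc[i, ] <- c(trajectory$x[j], trajectory$y[j])
  }

  vmin <- numeric(nrow(tra))
  for (i in seq_len(nrow(tra))) {
    idx <- tra$start_idx[i]:tra$end_idx[i]
    if (!length(idx)) {
      abort("Empty transition window.", class = "seqreach_data_error")
    }
    vmin[i] <- min(profile$speed[idx])
  }

  p0 <- c(trajectory$x[1L], trajectory$y[1L])
  d0 <- sqrt((trajectory$x - p0[1L])^2 + (trajectory$y - p0[2L])^2)
  exit_idx <- which(d0 > geometry$proximity_radius)[1L]
  if (is.na(exit_idx)) {
    abort("Start-region exit not found; trajectory never leaves 2 cm.",
          class = "seqreach_data_error")
  }
  mt_end <- trajectory$t[seg$end_idx[nrow(seg)]]
  mt_start <- trajectory$t[exit_idx]

  corrected <- detect_corrected(segmented, trajectory, geometry)

  tibble(
    movement_time = mt_end - mt_start,
    reaction_time = mt_start - trajectory$t[1L],
    vmax_mean = mean(vmax),
    vmin_mean = mean(vmin),
    corrected = corrected,
    vmax_per_segment = list(vmax),
    vmin_per_transition = list(vmin),
    vmax_location = list(vmax_loc)
  )
}

#' Detect corrective submovements
#'
#' A trial is flagged as corrected when some waypoint of the reach sequence
#' is first passed at a distance greater than the proximity radius (a miss)
#' and only afterwards re-approached within the target radius following a
#' reversal of heading. Operationally: within the approach window of each
#' waypoint, a strict local minimum of the distance-to-waypoint series
#' whose value exceeds the proximity radius, with a subsequent rise of at
#' least `hysteresis_cm` before the final entry, marks a corrective
#' submovement.
#'
#' @inheritParams trial_metrics
#' @param hysteresis_cm Minimum rebound (cm) after a missed approach for it
#'   to count as a reversal; guards against noise-induced wiggles.
#' @return Logical scalar.
#' @export
detect_corrected <- function(segmented, trajectory, geometry,
                             hysteresis_cm = 0.5) {
  stopifnot(inherits(segmented, "segmented_trial"))
  W <- waypoint_matrix(geometry)
  seg <- segmented$segments
  r <- geometry$proximity_radius

  for (k in seq_len(nrow(seg))) {
    idx <- seg$start_idx[k]:seg$end_idx[k]
    # a waypoint cannot be "passed" while still inside the previous
    # waypoint's proximity region: start the search after leaving it
    d_prev <- sqrt((trajectory$x[idx] - W[k, 1L])^2 +
                     (trajectory$y[idx] - W[k, 2L])^2)
    out <- which(d_prev >= r)
    if (!length(out)) next
    idx <- idx[out[1L]:length(idx)]
    if (length(idx) < 3L) next
    d <- sqrt((trajectory$x[idx] - W[k + 1L, 1L])^2 +
                (trajectory$y[idx] - W[k + 1L, 2L])^2)
    m <- length(d)
    i <- 2:(m - 1L)
    is_min <- d[i] < d[i - 1L] & d[i] < d[i + 1L] & d[i] > r
    if (!any(is_min)) next
    for (j in i[is_min]) {
      if (max(d[j:m]) >= d[j] + hysteresis_cm) return(TRUE)
    }
  }
  FALSE
}

#' Analyse a batch of trials
#'
#' Runs velocity computation, segmentation, kinematic measures and the
#' per-trial fusion index over every trial of a long trajectory table,
#' returning one row per trial. Incomplete trials (a waypoint never
#' approached within the proximity radius) are dropped with a warning and
#' listed in the `excluded` attribute.
#'
#' @param trajectories Long tibble with columns `participant`, `trial`,
#'   `t`, `x`, `y` (as produced by [simulate_learning_dataset()] or
#'   [read_trajectories()]).
#' @param geometry A [build_geometry()] object.
#' @param smoothing_sd_samples Gaussian kernel SD in samples.
#' @return A tibble with one row per trial: identifiers, the
#'   [trial_metrics()] columns, `fi_per_transition` and `fi_trial`.
#' @examples
#' geom <- build_geometry()
#' cfg <- simulation_config(seed = 1)
#' ds <- simulate_learning_dataset(geom, cfg, 2, 2)
#' analyze_trials(ds$trajectories, geom)
#' @export
analyze_trials <- function(trajectories, geometry,
                           smoothing_sd_samples = 2) {
  stopifnot(inherits(geometry, "reach_geometry"))
  keys <- dplyr::distinct(trajectories, .data$participant, .data$trial)
  excluded <- list()
  rows <- purrr::pmap(keys, function(participant, trial) {
    traj <- dplyr::filter(trajectories,
                          .data$participant == !!participant,
                          .data$trial == !!trial)
    vel <- compute_velocity(traj, smoothing_sd_samples)
    seg <- tryCatch(segment_trial(vel, traj, geometry),
                    seqreach_incomplete_trial_error = function(e) e)
    if (inherits(seg, "error")) {
      excluded[[length(excluded) + 1L]] <<-
        tibble(participant = participant, trial = trial,
               reason = conditionMessage(seg))
      return(NULL)
    }
    met <- trial_metrics(seg, vel, traj, geometry)
    met$participant <- participant
    met$trial <- trial
    met
  })
  out <- purrr::list_rbind(purrr::compact(rows))
  if (length(excluded)) {
    warn(sprintf("%d incomplete trial(s) excluded from analysis.",
                 length(excluded)))
    attr(out, "excluded") <- purrr::list_rbind(excluded)
  }
  out <- trial_fusion(out)
  select(out, "participant", "trial", dplyr::everything())
}
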