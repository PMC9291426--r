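# Smoothness scoring: minimum-jerk reference profiles, velocity-profile
# MSE, and spectral arc length.

#' Minimum-jerk reference for the full reach sequence
#'
#' Builds the minimum-jerk via-point trajectory for a task geometry: start
#' and end at the first and last waypoints of the reach sequence, passing
#' through the 7 intermediate waypoints, over a given movement time. The
#' shape of the normalized velocity profile is invariant to the movement
#' time (time rescaling leaves the minimum-jerk solution's path unchanged),
#' so a single reference can score trials of any duration; the jerk cost
#' scales as `T^-5`.
#'
#' @param geometry A [build_geometry()] object.
#' @param duration Movement time in seconds (affects jerk cost, not the
#'   normalized profile shape).
#' @param optimize_times Optimize via passage times (default) or use
#'   distance-proportional times.
#' @return A [min_jerk_trajectory()] object.
#' @export
min_jerk_reference <- function(geometry, duration = 1,
                               optimize_times = TRUE) {
  stopifnot(inherits(geometry, "reach_geometry"))
  W <- waypoint_matrix(geometry)
  min_jerk_trajectory(
    start = W[1L, ], end = W[nrow(W), ],
    via_points = W[2:(nrow(W) - 1L), , drop = FALSE],
    duration = duration, optimize_times = optimize_times
  )
}

#' Trim a velocity profile to its moving part
#'
#' Restricts a profile to the span between the first and last samples whose
#' speed exceeds a fraction of the profile peak, removing the stationary
#' lead-in and tail so that time normalization compares like with like.
#'
#' @param profile A [compute_velocity()] profile.
#' @param threshold Fraction of the peak speed (0.05 by default).
#' @return The trimmed profile.
#' @export
moving_window <- function(profile, threshold = 0.05) {
  above <- which(profile$speed > threshold * max(profile$speed))
  profile[above[1L]:above[length(above)], ]
}

# Normalize a speed profile: time to [0, 1], amplitude to unit peak,
# linearly interpolated to n points.
normalize_profile <- function(t, speed, n = 500L, amplitude = c("peak",
                                                                "integral")) {
  amplitude <- match.arg(amplitude)
  if (length(speed) < 2L || all(speed == 0)) {
    abort("Cannot normalize an all-zero or single-sample speed profile.",
          class = "seqreach_data_error")
  }
  tt <- (t - t[1L]) / (t[length(t)] - t[1L])
  y <- approx(tt, speed, xout = seq(0, 1, length.out = n))$y
  denom <- if (amplitude == "peak") max(y) else mean(y)
  if (denom <= 0) {
    abort("Degenerate speed profile after interpolation.",
          class = "seqreach_data_error")
  }
  y / denom
}

#' Mean squared error between observed and predicted velocity profiles
#'
#' Both profiles are mapped to normalized time `[0, 1]`,
#' amplitude-normalized (unit peak by default), linearly interpolated to
#' `n_interp` points, and compared pointwise.
#'
#' @param observed A [compute_velocity()] profile (tibble with `t`,
#'   `speed`) or a numeric speed vector (assumed uniformly sampled).
#' @param predicted A predicted profile in the same forms (e.g.
#'   `predict(min_jerk_reference(geom))`).
#' @param n_interp Number of interpolation points (500 by default).
#' @param amplitude Amplitude normalization: `"peak"` (unit maximum) or
#'   `"integral"` (unit mean).
#' @return Nonnegative scalar MSE (dimensionless).
#' @examples
#' geom <- build_geometry()
#' mj <- predict(min_jerk_reference(geom, optimize_times = FALSE))
#' mse_to_model(mj, mj)  # 0 against itself
#' @export
mse_to_model <- function(observed, predicted, n_interp = 500L,
                         amplitude = "peak") {
  as_ts <- function(p) {
    if (is.numeric(p)) list(t = seq_along(p), speed = p)
    else list(t = p$t, speed = p$speed)
  }
  o <- as_ts(observed)
  p <- as_ts(predicted)
  yo <- normalize_profile(o$t, o$speed, n_interp, amplitude)
  yp <- normalize_profile(p$t, p$speed, n_interp, amplitude)
  mean((yo - yp)^2)
}

#' Spectral arc length (SPARC) of a velocity profile
#'
#' Smoothness measure equal to the negative arc length of the normalized
#' magnitude spectrum of the speed profile over normalized frequency.
#' The spectrum (zero-padded FFT) is normalized by its DC value, restricted
#' to frequencies up to `cutoff_hz`, and further trimmed by an adaptive
#' cutoff at the last frequency where the normalized magnitude exceeds
#' `amp_threshold`. Values closer to 0 indicate smoother movement.
#'
#' @param profile A [compute_velocity()] profile, or a numeric speed vector
#'   with `fs` supplied.
#' @param fs Sampling rate in Hz (taken from the profile attribute when
#'   available).
#' @param cutoff_hz Maximum frequency considered (20 Hz by default).
#' @param amp_threshold Adaptive amplitude threshold (0.05 by default).
#' @param pad_pow2 Zero-padding exponent: the FFT length is
#'   `2^(nextpow2(n) + pad_pow2)`.
#' @return Negative scalar; more negative = less smooth.
#' @examples
#' geom <- build_geometry()
#' traj <- simulate_trial(geom, simulation_config(movement_time_s = 4))
#' spectral_arc_length(compute_velocity(traj))
#' @export
spectral_arc_length <- function(profile, fs = NULL, cutoff_hz = 20,
                                amp_threshold = 0.05, pad_pow2 = 4L) {
  if (is.numeric(profile)) {
    speed <- profile
    if (is.null(fs)) {
      abort("`fs` must be supplied for a bare speed vector.",
            class = "seqreach_parameter_error")
    }
  } else {
    speed <- profile$speed
    fs <- fs %||% attr(profile, "sampling_rate_hz")
    if (is.null(fs)) fs <- 1 / median(diff(profile$t))
  }
  n <- length(speed)
  if (n < 8L) {
    abort("Need at least 8 samples for the spectral arc length.",
          class = "seqreach_data_error")
  }
  if (all(speed == 0)) {
    abort("Zero-power speed profile.", class = "seqreach_data_error")
  }
  nfft <- 2^(ceiling(log2(n)) + pad_pow2)
  spec <- Mod(fft(c(speed, rep(0, nfft - n))))
  freq <- (0:(nfft - 1L)) * fs / nfft
  half <- seq_len(nfft %/% 2 + 1L)
  spec <- spec[half] / spec[1L]
  freq <- freq[half]
  keep <- freq <= cutoff_hz
  spec <- spec[keep]
  freq <- freq[keep]
  # adaptive cutoff: last frequency with magnitude above threshold
  above <- which(spec >= amp_threshold)
  hi <- min(length(spec), max(above) + 1L)
  spec <- spec[seq_len(hi)]
  freq <- freq[seq_len(hi)]
  f_range <- freq[length(freq)] - freq[1L]
  -sum(sqrt((diff(freq) / f_range)^2 + diff(spec)^2))
}

#' Exclude corrected trials from smoothness analyses
#'
#' Removes trials flagged as corrected (at least one corrective movement to
#' hit a previously missed target) and reports how many were dropped.
#' Corrective submovements add spurious peaks to the velocity profile,
#' which distorts both the model MSE and the spectral arc length.
#'
#' @param metrics A per-trial table carrying a logical `corrected` column.
#' @return The non-corrected rows, with attribute `exclusion_report`: a
#'   one-row tibble with `n_total`, `n_excluded`, `pct_excluded`. An
#'   all-corrected input returns an empty table with a warning.
#' @export
exclude_corrected <- function(metrics) {
  if (!"corrected" %in% names(metrics)) {
    abort("`metrics` must have a logical `corrected` column.",
          class = "seqreach_parameter_error")
  }
  n_total <- nrow(metrics)
  out <- filter(metrics, !.data$corrected)
  n_exc <- n_total - nrow(out)
  if (nrow(out) == 0L && n_total > 0L) {
    warn("All trials are flagged corrected; returning an empty set.")
  }
  attr(out, "exclusion_report") <- tibble(
    n_total = n_total, n_excluded = n_exc,
    pct_excluded = if (n_total > 0) 100 * n_exc / n_total else 0
  )
  out
}

#' Smoothness scores for a batch of trials
#'
#' Scores each non-corrected trial against the minimum-jerk via-point
#' reference: velocity-profile MSE ([mse_to_model()]), spectral arc length
#' ([spectral_arc_length()]), and the model's jerk cost rescaled to the
#' trial's movement time (jerk cost scales as `T^-5`).
#'
#' @param trajectories Long trajectory tibble (`participant`, `trial`,
#'   `t`, `x`, `y`).
#' @param analyzed The matching [analyze_trials()] table (provides
#'   segmentation bounds, movement times and corrected flags).
#' @param geometry A [build_geometry()] object.
#' @param reference Optional precomputed [min_jerk_reference()]; computed
#'   once (with passage-time optimization) when absent.
#' @param smoothing_sd_samples Gaussian kernel SD in samples.
#' @return A tibble with one row per analysed trial: `participant`,
#'   `trial`, `mse`, `sparc`, `jerk_cost`, `excluded` (corrected flag);
#'   excluded trials carry `NA` scores. The exclusion report of
#'   [exclude_corrected()] is attached as attribute `exclusion_report`.
#' @export
trial_smoothness <- function(trajectories, analyzed, geometry,
                             reference = NULL, smoothing_sd_samples = 2) {
  stopifnot(inherits(geometry, "reach_geometry"))
  reference <- reference %||% min_jerk_reference(geometry)
  # window the model profile exactly as the observed ones, so the
  # normalized time axes cover comparable motion spans
  ref_profile <- moving_window(predict(reference, n = 500L))
  kept <- exclude_corrected(analyzed)
  report <- attr(kept, "exclusion_report")

  rows <- purrr::pmap(
    list(analyzed$participant, analyzed$trial, analyzed$corrected,
         analyzed$movement_time),
    function(p, tr, corr, mt) {
      if (corr) {
        return(tibble(participant = p, trial = tr, mse = NA_real_,
                      sparc = NA_real_, jerk_cost = NA_real_,
                      excluded = TRUE))
      }
      traj <- dplyr::filter(trajectories, .data$participant == !!p,
                            .data$trial == !!tr)
      vel <- compute_velocity(traj, smoothing_sd_samples)
      obs <- moving_window(vel)
      tibble(
        participant = p, trial = tr,
        mse = mse_to_model(obs, ref_profile),
        sparc = spectral_arc_length(vel),
        jerk_cost = reference$jerk_cost * (reference$duration / mt)^5,
        excluded = FALSE
      )
    }
  ) |> purrr::list_rbind()
  attr(rows, "exclusion_report") <- report
  rows
}
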