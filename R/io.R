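# Delimited-text trajectory IO and the end-to-end pipeline runner.

trajectory_cols <- c("participant_id", "group", "day", "trial", "t_s",
                     "x_cm", "y_cm")

#' Write trajectories to delimited text
#'
#' One row per sample with header `participant_id, group, day, trial, t_s,
#' x_cm, y_cm` (UTF-8, '.' decimal separator), sorted by participant, day,
#' trial, time.
#'
#' @param trajectories Long tibble with `participant`, `trial`, `t`, `x`,
#'   `y` and optionally `group`, `day`.
#' @param path Output file path (CSV).
#' @param group,day Defaults used when the columns are absent.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path, group = "sim",
                               day = 1L) {
  df <- as_tibble(trajectories)
  if (!"group" %in% names(df)) df$group <- group
  if (!"day" %in% names(df)) df$day <- day
  out <- df |>
    dplyr::transmute(participant_id = .data$participant,
                     group = .data$group, day = .data$day,
                     trial = .data$trial, t_s = .data$t,
                     x_cm = .data$x, y_cm = .data$y) |>
    arrange(.data$participant_id, .data$day, .data$trial, .data$t_s)
  readr::write_csv(out, path)
  invisible(path)
}

#' Read trajectories from delimited text
#'
#' Reads the schema written by [write_trajectories()], validates it, and
#' returns the package's long trajectory layout. Rows are sorted by
#' (participant, day, trial, time) unless `strict = TRUE`, in which case
#' out-of-order rows are an error.
#'
#' @param path Input file path.
#' @param strict Reject files whose rows are not already sorted.
#' @return Long tibble with `participant`, `group`, `day`, `trial`, `t`,
#'   `x`, `y`.
#' @export
read_trajectories <- function(path, strict = FALSE) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(trajectory_cols, names(df))
  if (length(missing)) {
    abort(paste0("Trajectory file is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "seqreach_parse_error")
  }
  sorted <- df |>
    arrange(.data$participant_id, .data$day, .data$trial, .data$t_s)
  if (strict && !identical(sorted$t_s, df$t_s)) {
    abort("Rows are not sorted by (participant, day, trial, t_s).",
          class = "seqreach_parse_error")
  }
  out <- sorted |>
    dplyr::transmute(participant = .data$participant_id,
                     group = .data$group, day = .data$day,
                     trial = .data$trial, t = .data$t_s,
                     x = .data$x_cm, y = .data$y_cm)
  bad <- out |>
    group_by(.data$participant, .data$day, .data$trial) |>
    summarise(mono = all(diff(.data$t) > 0), .groups = "drop")
  if (!all(bad$mono)) {
    culprit <- bad[!bad$mono, ][1L, ]
    abort(sprintf(
      "Non-monotone timestamps in participant %s, trial %s.",
      culprit$participant, culprit$trial),
      class = "seqreach_data_error")
  }
  out
}

#' Run the full analysis pipeline
#'
#' Ties the stages together: simulate (or load) trajectories, compute
#' per-trial kinematics and fusion indices, sliding-window radial
#' distances, smoothness scores (with corrected-trial exclusion), a
#' closed-loop reward replay of each participant's movement times, and a
#' participant-bootstrap learning-curve fit of MT. Deterministic for a
#' fixed seed.
#'
#' @param geometry A [build_geometry()] object.
#' @param config A [simulation_config()]; its `seed` drives all
#'   randomness (simulation and bootstrap).
#' @param input `"simulate"` or a path to a trajectory file readable by
#'   [read_trajectories()].
#' @param n_participants,n_trials Dataset size when simulating.
#' @param window Sliding-window size for radial distance.
#' @param n_boot Bootstrap draws for the learning-curve fit.
#' @param family Curve family for the learning-curve fit.
#' @return A list of class `reach_pipeline`: `metrics`, `radial_distance`,
#'   `smoothness`, `reward`, `fit` (a [bootstrap_fit()]), `truth` (when
#'   simulated) and `manifest` (config hash, seed, counts).
#' @export
run_pipeline <- function(geometry, config, input = "simulate",
                         n_participants = 4L, n_trials = 20L,
                         window = 10L, n_boot = 200L, family = "poly1") {
  stopifnot(inherits(geometry, "reach_geometry"))
  truth <- NULL
  if (identical(input, "simulate")) {
    ds <- simulate_learning_dataset(geometry, config, n_participants,
                                    n_trials)
    trajectories <- ds$trajectories
    truth <- ds$truth
  } else {
    trajectories <- read_trajectories(input)
  }

  metrics <- analyze_trials(trajectories, geometry)

  rd <- metrics |>
    group_by(.data$participant) |>
    dplyr::group_modify(function(d, g) {
      if (nrow(d) < window) return(tibble())
      radial_distance(d, geometry, window = window)
    }) |>
    ungroup()

  reference <- min_jerk_reference(geometry)
  smoothness <- trial_smoothness(trajectories, metrics, geometry,
                                 reference = reference)

  reward <- metrics |>
    group_by(.data$participant) |>
    dplyr::group_modify(function(d, g) {
      session_feedback(arrange(d, .data$trial)$movement_time)
    }) |>
    ungroup()

  series <- metrics |>
    dplyr::transmute(.data$participant, .data$trial,
                     value = .data$movement_time)
  fit <- bootstrap_fit(series, family, n_boot = n_boot,
                       seed = config$seed)

  manifest <- tibble(
    config_hash = rlang::hash(config),
    seed = config$seed %||% NA_integer_,
    n_trials_analyzed = nrow(metrics),
    n_corrected = sum(metrics$corrected),
    n_excluded_smoothness =
      attr(smoothness, "exclusion_report")$n_excluded,
    package_version = as.character(utils::packageVersion("seqreach"))
  )

  structure(
    list(metrics = metrics, radial_distance = rd, smoothness = smoothness,
         reward = reward, fit = fit, truth = truth, manifest = manifest),
    class = "reach_pipeline"
  )
}

#' @export
print.reach_pipeline <- function(x, ...) {
  cat("<reach_pipeline>\n")
  cat(sprintf("  %d trials analysed (%d corrected); config %s\n",
              x$manifest$n_trials_analyzed, x$manifest$n_corrected,
              x$manifest$config_hash))
  cat(sprintf("  learning-curve fit: %s\n", x$fit$family))
  invisible(x)
}
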