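# Closed-loop rank-based reward schedule and random-feedback draws.

#' Rank-percentile reward schedule
#'
#' The closed-loop payout schedule: a trial's movement time is ranked
#' against a reference window of the 20 preceding trials; the rank
#' percentile maps to a payout in pence via the cut points
#' `>= 90% -> 5p`, `[80, 90) -> 4p`, `[60, 80) -> 3p`, `[40, 60) -> 2p`,
#' `[20, 40) -> 1p`, `< 20% -> 0p`.
#'
#' @param window Number of reference trials (20 by default).
#' @return A list of class `reward_schedule` with `window`, `cuts`
#'   (lower percentile bounds) and `payouts` (pence).
#' @export
reward_schedule <- function(window = 20L) {
  check_count(window, "window", lower = 1L)
  structure(
    list(window = window,
         cuts = c(90, 80, 60, 40, 20, 0),
         payouts = c(5L, 4L, 3L, 2L, 1L, 0L)),
    class = "reward_schedule"
  )
}

payout_for_percentile <- function(percentile, schedule) {
  breaks <- c(0, rev(schedule$cuts)[-1L])       # 0, 20, 40, 60, 80, 90
  rev(schedule$payouts)[findInterval(percentile, breaks)]
}

#' Closed-loop feedback for one trial
#'
#' Ranks `current_mt` within a reference window of movement times: the
#' percentile is 100 times the fraction of reference MTs strictly slower
#' (larger) than the current one, and the payout follows the schedule's
#' cut points. Deterministic in its inputs.
#'
#' @param current_mt Current trial's movement time (s).
#' @param reference_mts Numeric vector of exactly `schedule$window`
#'   positive movement times.
#' @param schedule A [reward_schedule()].
#' @param trial Optional trial index recorded in the output.
#' @return One-row tibble (a feedback event): `trial`, `mt`, `percentile`,
#'   `payout`, `source = "closed_loop"`.
#' @examples
#' sched <- reward_schedule()
#' closed_loop_feedback(3.5, seq(4, 6, length.out = 20), sched)$payout
#' @export
closed_loop_feedback <- function(current_mt, reference_mts,
                                 schedule = reward_schedule(),
                                 trial = NA_integer_) {
  check_number(current_mt, "current_mt", lower = 0)
  if (length(reference_mts) != schedule$window) {
    abort(sprintf("`reference_mts` must hold exactly %d values, got %d.",
                  schedule$window, length(reference_mts)),
          class = "seqreach_parameter_error")
  }
  if (any(!is.finite(reference_mts)) || any(reference_mts <= 0)) {
    abort("All reference movement times must be positive.",
          class = "seqreach_parameter_error")
  }
  percentile <- 100 * mean(reference_mts > current_mt)
  tibble(
    trial = trial, mt = current_mt, percentile = percentile,
    payout = payout_for_percentile(percentile, schedule),
    source = "closed_loop"
  )
}

#' Random feedback drawn from a payout pool
#'
#' Emulates the random-feedback condition: the payout is drawn uniformly
#' from a pool of previously awarded payouts, so the marginal payout
#' distribution matches the pool's empirical distribution without relating
#' to the current trial's performance.
#'
#' @param pool Nonempty vector of payouts (pence) to draw from.
#' @param n Number of events to draw.
#' @param seed Optional seed for reproducible draws.
#' @param mts Optional movement times recorded alongside the events.
#' @return Tibble of feedback events with `source = "random"`.
#' @export
random_feedback <- function(pool, n = 1L, seed = NULL, mts = NA_real_) {
  if (!length(pool)) {
    abort("`pool` must be nonempty.", class = "seqreach_parameter_error")
  }
  check_count(n, "n")
  draws <- with_seed_if(seed,
    pool[sample.int(length(pool), n, replace = TRUE)])
  tibble(
    trial = seq_len(n), mt = rep_len(mts, n), percentile = NA_real_,
    payout = as.integer(draws), source = "random"
  )
}

#' Closed-loop feedback over a whole session
#'
#' Applies [closed_loop_feedback()] trial by trial with a rolling reference
#' window: each trial is ranked against the `window` preceding movement
#' times, starting from a carryover window (e.g. the last 20 trials of the
#' previous block). Cumulative earnings are accumulated over the session.
#'
#' @param mts Per-trial movement times (s) in session order.
#' @param schedule A [reward_schedule()].
#' @param carryover Movement times of at least `schedule$window` preceding
#'   trials supplying the initial reference window; if the session itself
#'   must warm the window up, pass `carryover = NULL` and the first
#'   `window` trials receive no feedback.
#' @return Tibble of feedback events with an added `cumulative_pence`
#'   column; warm-up trials (no reference window yet) have `NA` payout.
#' @export
session_feedback <- function(mts, schedule = reward_schedule(),
                             carryover = NULL) {
  if (!length(mts) || any(!is.finite(mts)) || any(mts <= 0)) {
    abort("`mts` must be positive movement times.",
          class = "seqreach_parameter_error")
  }
  w <- schedule$window
  if (!is.null(carryover)) {
    if (length(carryover) < w) {
      abort(sprintf(
        "`carryover` must supply at least %d baseline movement times; pass NULL to warm up within the session.",
        w), class = "seqreach_parameter_error")
    }
    history <- tail(carryover, w)
    warmup <- 0L
  } else {
    history <- numeric(0)
    warmup <- w
  }

  events <- purrr::imap(mts, function(mt, i) {
    if (i <= warmup) {
      history <<- c(history, mt)
      return(tibble(trial = i, mt = mt, percentile = NA_real_,
                    payout = NA_integer_, source = "closed_loop"))
    }
    ev <- closed_loop_feedback(mt, tail(history, w), schedule, trial = i)
    history <<- c(history, mt)
    ev
  }) |> purrr::list_rbind()
  events$cumulative_pence <- cumsum(dplyr::coalesce(events$payout, 0L))
  events
}
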