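# Participant-bootstrap learning-curve inference: resampling, three curve
# families, percentile CIs, model comparison, baseline correction.

# Fit one curve family to (x, y) by least squares. Returns named
# parameters and r_squared, or signals a condition on failure.
fit_family <- function(x, y, family = c("poly1", "exp1", "power1"),
                       jitter = 0) {
  family <- match.arg(family)
  r2 <- function(fitted) 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  if (family == "poly1") {
    cf <- stats::coef(stats::lm.fit(cbind(x, 1), y))
    return(list(parameters = c(p1 = unname(cf[1L]), p2 = unname(cf[2L])),
                r_squared = r2(cf[1L] * x + cf[2L])))
  }
  eps <- 1e-8
  ylog <- log(pmax(y, eps))
  if (family == "exp1") {
    init <- unname(stats::coef(stats::lm.fit(cbind(1, x), ylog)))
    start <- list(a = exp(init[1L]) * (1 + jitter),
                  b = init[2L] * (1 + jitter) + jitter * 1e-4)
    fit <- minpack.lm::nlsLM(y ~ a * exp(b * x), start = start,
                             control = minpack.lm::nls.lm.control(
                               maxiter = 200))
    cf <- coef(fit)
    return(list(parameters = c(a = unname(cf[["a"]]), b = unname(cf[["b"]])),
                r_squared = r2(predict(fit))))
  }
  # power1: y = a * x^b, x must be positive (trial indices are)
  init <- unname(stats::coef(stats::lm.fit(cbind(1, log(pmax(x, eps))), ylog)))
  start <- list(a = exp(init[1L]) * (1 + jitter),
                b = init[2L] * (1 + jitter) + jitter * 1e-4)
  fit <- minpack.lm::nlsLM(y ~ a * x^b, start = start,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200))
  cf <- coef(fit)
  list(parameters = c(a = unname(cf[["a"]]), b = unname(cf[["b"]])),
       r_squared = r2(predict(fit)))
}

fit_family_robust <- function(x, y, family) {
  for (jit in c(0, 0.05, -0.05, 0.2)) {
    out <- tryCatch(fit_family(x, y, family, jitter = jit),
                    error = function(e) NULL)
    if (!is.null(out) && all(is.finite(out$parameters))) return(out)
  }
  NULL
}

check_series <- function(series) {
  miss <- setdiff(c("participant", "trial", "value"), names(series))
  if (length(miss)) {
    abort(paste0("`series` is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "seqreach_parameter_error")
  }
  invisible(series)
}

# Trial-wise mean across participants (mean over available participants
# per trial; missing trials are simply absent from the average).
trialwise_mean <- function(series) {
  series |>
    group_by(.data$trial) |>
    summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop") |>
    arrange(.data$trial)
}

#' Participant-bootstrap fit of a learning curve
#'
#' Fits a trial-by-trial curve to the group mean of a per-participant
#' measure, with uncertainty from a participant-level bootstrap: each of
#' `n_boot` draws resamples participants with replacement to the original
#' group size, averages the resampled participants' values per trial, and
#' refits the curve. Three families are available: `poly1`
#' (`f(x) = p1 * x + p2`: `p2` the early-training intercept, `p1` the
#' learning rate), `exp1` (`f(x) = a * exp(b * x)`) and `power1`
#' (`f(x) = a * x^b`). Confidence intervals are percentile-based
#' (2.5/97.5%).
#'
#' @param series Tibble with columns `participant`, `trial`, `value`
#'   (optionally `group`); at least 2 participants and 3 trials.
#' @param family Curve family.
#' @param n_boot Number of bootstrap draws (1000 by default).
#' @param seed Optional seed for reproducible resampling.
#' @param max_fail_frac Maximum tolerated fraction of failed draws (each
#'   failed draw is retried from jittered starts first).
#' @return An object of class `bootstrap_fit`: list with `family`,
#'   `estimate` (parameters + r_squared of the fit to the unresampled
#'   group mean), `draws` (tibble of per-draw parameters), `ci` (percentile
#'   intervals), `n_boot`, `n_failed`, `seed`, `group`. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @examples
#' series <- simulate_group_series(6, 60, seed = 1)
#' fit <- bootstrap_fit(series, "poly1", n_boot = 50, seed = 2)
#' tidy(fit)
#' @export
bootstrap_fit <- function(series, family = c("poly1", "exp1", "power1"),
                          n_boot = 1000L, seed = NULL,
                          max_fail_frac = 0.05) {
  family <- match.arg(family)
  check_series(series)
  check_count(n_boot, "n_boot")
  participants <- unique(series$participant)
  if (length(participants) < 2L) {
    abort("Need at least 2 participants.",
          class = "seqreach_parameter_error")
  }
  if (dplyr::n_distinct(series$trial) < 3L) {
    abort("Need at least 3 trials.", class = "seqreach_parameter_error")
  }

  gm <- trialwise_mean(series)
  point <- fit_family_robust(gm$trial, gm$value, family)
  if (is.null(point)) {
    abort(sprintf("The %s fit to the group mean failed to converge.",
                  family), class = "seqreach_fit_error")
  }

  # matrix of participant x trial values for fast resampling
  wide <- tidyr::pivot_wider(series[, c("participant", "trial", "value")],
                             names_from = "trial", values_from = "value")
  wide <- wide[match(participants, wide$participant), , drop = FALSE]
  vals <- as.matrix(wide[, -1L, drop = FALSE])
  trials <- as.numeric(colnames(vals))
  ord <- order(trials)
  trials <- trials[ord]
  vals <- vals[, ord, drop = FALSE]

  n_p <- length(participants)
  draws <- with_seed_if(seed, {
    purrr::map(seq_len(n_boot), function(b) {
      pick <- sample.int(n_p, n_p, replace = TRUE)
      ybar <- colMeans(vals[pick, , drop = FALSE], na.rm = TRUE)
      fit <- fit_family_robust(trials, ybar, family)
      if (is.null(fit)) return(NULL)
      tibble(draw = b, !!!as.list(fit$parameters),
             r_squared = fit$r_squared)
    })
  })
  n_failed <- sum(purrr::map_lgl(draws, is.null))
  if (n_failed > max_fail_frac * n_boot) {
    abort(sprintf("%d of %d bootstrap draws failed to fit (> %.0f%%).",
                  n_failed, n_boot, 100 * max_fail_frac),
          class = "seqreach_fit_error")
  }
  draws <- purrr::list_rbind(purrr::compact(draws))

  par_names <- c(names(point$parameters), "r_squared")
  ci <- purrr::map(par_names, function(p) {
    q <- quantile(draws[[p]], c(0.025, 0.975), names = FALSE)
    tibble(parameter = p, lower = q[1L], upper = q[2L])
  }) |> purrr::list_rbind()

  structure(
    list(family = family,
         estimate = c(point$parameters, r_squared = point$r_squared),
         draws = draws, ci = ci, n_boot = n_boot, n_failed = n_failed,
         seed = seed,
         group = if ("group" %in% names(series)) series$group[1L]
                 else NA_character_,
         group_mean = gm),
    class = "bootstrap_fit"
  )
}

#' @export
print.bootstrap_fit <- function(x, ...) {
  cat(sprintf("<bootstrap_fit: %s, %d draws%s>\n", x$family, x$n_boot,
              if (!is.na(x$group)) paste0(", group ", x$group) else ""))
  print(tidy(x))
  invisible(x)
}

#' @describeIn bootstrap_fit Parameter estimates with percentile CIs.
#' @param x,object,... Method arguments.
#' @export
tidy.bootstrap_fit <- function(x, ...) {
  est <- x$estimate
  tibble(term = names(est), estimate = unname(est)) |>
    left_join(dplyr::rename(x$ci, term = "parameter",
                            conf.low = "lower", conf.high = "upper"),
              by = "term")
}

#' @describeIn bootstrap_fit One-row summary (family, r-squared, draws).
#' @export
glance.bootstrap_fit <- function(x, ...) {
  tibble(family = x$family, r_squared = unname(x$estimate["r_squared"]),
         n_boot = x$n_boot, n_failed = x$n_failed,
         group = x$group)
}

predict_family <- function(family, parameters, x) {
  switch(family,
         poly1 = parameters[["p1"]] * x + parameters[["p2"]],
         exp1 = parameters[["a"]] * exp(parameters[["b"]] * x),
         power1 = parameters[["a"]] * x^parameters[["b"]])
}

#' Compare curve families on the same series
#'
#' Runs [bootstrap_fit()] for each family and ranks them by the mean
#' bootstrap goodness of fit; 95% percentile intervals of r-squared are
#' reported so overlapping intervals can be read as "no clear difference".
#'
#' @inheritParams bootstrap_fit
#' @param families Character vector of at least two families.
#' @return Tibble ranked by mean r-squared: `family`, `r_squared_mean`,
#'   `r_squared_lower`, `r_squared_upper`, `rank`, `overlaps_best`.
#' @export
compare_families <- function(series, families = c("poly1", "exp1",
                                                  "power1"),
                             n_boot = 1000L, seed = NULL) {
  if (length(families) < 2L) {
    abort("Need at least two families to compare.",
          class = "seqreach_parameter_error")
  }
  fits <- purrr::map(families, function(f) {
    bootstrap_fit(series, f, n_boot = n_boot, seed = seed)
  })
  out <- purrr::map2(families, fits, function(f, fit) {
    q <- quantile(fit$draws$r_squared, c(0.025, 0.975), names = FALSE)
    tibble(family = f, r_squared_mean = mean(fit$draws$r_squared),
           r_squared_lower = q[1L], r_squared_upper = q[2L])
  }) |>
    purrr::list_rbind() |>
    arrange(dplyr::desc(.data$r_squared_mean)) |>
    mutate(rank = row_number())
  best <- out[1L, ]
  out$overlaps_best <- out$r_squared_upper >= best$r_squared_lower &
    out$r_squared_lower <= best$r_squared_upper
  attr(out, "fits") <- setNames(fits, families)
  out
}

#' Contrast a model parameter between two bootstrap fits
#'
#' Forms the per-draw difference (a minus b, paired by draw index) of one
#' parameter between two [bootstrap_fit()] results of the same family and
#' reports its 95% percentile interval; the difference is called
#' significant when that interval excludes zero. The per-group intervals
#' are also returned for the more conservative non-overlap reading.
#'
#' @param result_a,result_b [bootstrap_fit()] objects with matching family.
#' @param parameter Parameter name (e.g. `"p1"`, `"p2"`, `"r_squared"`).
#' @return One-row tibble: point difference, `conf.low`, `conf.high`,
#'   `significant`, and the two per-group intervals.
#' @export
group_contrast <- function(result_a, result_b, parameter = "p1") {
  stopifnot(inherits(result_a, "bootstrap_fit"),
            inherits(result_b, "bootstrap_fit"))
  if (result_a$family != result_b$family) {
    abort("Both fits must use the same curve family.",
          class = "seqreach_parameter_error")
  }
  if (!parameter %in% names(result_a$draws) ||
      !parameter %in% names(result_b$draws)) {
    abort(sprintf("Parameter '%s' not found in the bootstrap draws.",
                  parameter), class = "seqreach_parameter_error")
  }
  n <- min(nrow(result_a$draws), nrow(result_b$draws))
  diff <- result_a$draws[[parameter]][seq_len(n)] -
    result_b$draws[[parameter]][seq_len(n)]
  qd <- quantile(diff, c(0.025, 0.975), names = FALSE)
  ci_a <- filter(result_a$ci, .data$parameter == !!parameter)
  ci_b <- filter(result_b$ci, .data$parameter == !!parameter)
  tibble(
    parameter = parameter,
    estimate = unname(result_a$estimate[parameter] -
                        result_b$estimate[parameter]),
    conf.low = qd[1L], conf.high = qd[2L],
    significant = qd[1L] > 0 | qd[2L] < 0,
    a_lower = ci_a$lower, a_upper = ci_a$upper,
    b_lower = ci_b$lower, b_upper = ci_b$upper
  )
}

#' Baseline-correct a series per participant
#'
#' Subtracts each participant's baseline summary from all their training
#' values, removing stable between-participant offsets.
#'
#' @param series Tibble with `participant`, `trial`, `value`.
#' @param baseline_values Tibble with `participant` and `baseline` (one
#'   summary value per participant, e.g. the mean of baseline trials).
#' @return `series` with corrected `value`.
#' @export
baseline_correct <- function(series, baseline_values) {
  check_series(series)
  if (!all(c("participant", "baseline") %in% names(baseline_values))) {
    abort("`baseline_values` needs columns `participant` and `baseline`.",
          class = "seqreach_parameter_error")
  }
  missing <- setdiff(unique(series$participant),
                     baseline_values$participant)
  if (length(missing)) {
    abort(paste0("No baseline value for participant(s): ",
                 paste(missing, collapse = ", ")),
          class = "seqreach_data_error")
  }
  series |>
    left_join(baseline_values[, c("participant", "baseline")],
              by = "participant") |>
    mutate(value = .data$value - .data$baseline) |>
    select(-"baseline")
}

#' Early-training mean per participant
#'
#' Mean of each participant's first `n_trials` values; a summary short
#' enough to capture rapid (invigoration-like) performance changes.
#'
#' @param series Tibble with `participant`, `trial`, `value`.
#' @param n_trials Number of initial trials to average (5 by default).
#' @return Tibble with `participant` and `early_mean`.
#' @export
early_training_mean <- function(series, n_trials = 5L) {
  check_series(series)
  check_count(n_trials, "n_trials")
  out <- series |>
    group_by(.data$participant) |>
    arrange(.data$trial, .by_group = TRUE) |>
    summarise(n_avail = dplyr::n(),
              early_mean = mean(head(.data$value, n_trials)),
              .groups = "drop")
  if (any(out$n_avail < n_trials)) {
    abort(sprintf("Some participants have fewer than %d trials.", n_trials),
          class = "seqreach_data_error")
  }
  select(out, -"n_avail")
}
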