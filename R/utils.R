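# shared input checks ------------------------------------------------------

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "seqreach_parameter_error")
  }
  if (x < lower || x > upper || (!allow_zero && x == 0)) {
    abort(sprintf("`%s` = %g is outside its valid range [%g, %g].",
                  name, x, lower, upper),
          class = "seqreach_parameter_error")
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < lower) {
    abort(sprintf("`%s` must be a whole number >= %d.", name, lower),
          class = "seqreach_parameter_error")
  }
  invisible(as.integer(x))
}

check_trajectory_df <- function(trajectory, min_samples = 2L) {
  cols <- c("t", "x", "y")
  missing <- setdiff(cols, names(trajectory))
  if (length(missing)) {
    abort(paste0("Trajectory is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "seqreach_data_error")
  }
  if (nrow(trajectory) < min_samples) {
    abort(sprintf("Trajectory needs at least %d samples, got %d.",
                  min_samples, nrow(trajectory)),
          class = "seqreach_data_error")
  }
  if (anyNA(trajectory$t) || anyNA(trajectory$x) || anyNA(trajectory$y) ||
      any(!is.finite(trajectory$t)) || any(!is.finite(trajectory$x)) ||
      any(!is.finite(trajectory$y))) {
    abort("Trajectory contains missing or non-finite values.",
          class = "seqreach_data_error")
  }
  if (any(diff(trajectory$t) <= 0)) {
    abort("Trajectory timestamps must be strictly increasing.",
          class = "seqreach_data_error")
  }
  invisible(trajectory)
}

# Run `expr` under `seed` when supplied, leaving the caller's RNG untouched;
# otherwise use the current RNG stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}
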