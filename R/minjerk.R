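# Minimum-jerk trajectory machinery.
#
# A minimum-jerk trajectory minimizes the half-integral of the squared third
# derivative of position. With interpolation (via-point) constraints and
# clamped boundary conditions the optimum is a piecewise quintic polynomial
# that is C^4 across interior via points, so for fixed passage times the
# solution is obtained exactly from one linear system per axis. Passage
# times themselves are optimized by a bounded nonlinear search.
#
# Quintic coefficients are stored in normalized segment time u = s/d in
# [0, 1]; real-time derivatives of order k pick up a factor d^-k.

# Row of the k-th derivative of the quintic basis (1, u, ..., u^5) at u.
quintic_row <- function(u, deriv = 0L) {
  j <- 0:5
  out <- numeric(6L)
  keep <- j >= deriv
  fac <- factorial(j[keep]) / factorial(j[keep] - deriv)
  out[keep] <- fac * u^(j[keep] - deriv)
  out
}

# Exact C^4 piecewise-quintic interpolant through 1-D waypoints `w`
# (length n+1) with segment durations `d` (length n), zero velocity and
# acceleration at both ends. Returns an n x 6 coefficient matrix in
# normalized segment time. This is the minimum-jerk solution for fixed
# passage times.
mj_solve_axis <- function(w, d) {
  n <- length(d)
  stopifnot(length(w) == n + 1L)
  m <- 6L * n
  A <- matrix(0, m, m)
  b <- numeric(m)
  idx <- function(seg) ((seg - 1L) * 6L + 1L):(seg * 6L)
  row <- 0L
  put <- function(seg, u, deriv, rhs, scale = 1) {
    row <<- row + 1L
    A[row, idx(seg)] <<- quintic_row(u, deriv) * scale
    b[row] <<- rhs
  }
  # clamped start: position, zero velocity, zero acceleration
  put(1L, 0, 0L, w[1L])
  put(1L, 0, 1L, 0)
  put(1L, 0, 2L, 0)
  for (i in seq_len(n - 1L)) {
    put(i, 1, 0L, w[i + 1L])        # left segment reaches the via
    put(i + 1L, 0, 0L, w[i + 1L])   # right segment starts at the via
    for (k in 1:4) {                # C^1..C^4 continuity in real time
      row <- row + 1L
      A[row, idx(i)] <- quintic_row(1, k) / d[i]^k
      A[row, idx(i + 1L)] <- -quintic_row(0, k) / d[i + 1L]^k
      b[row] <- 0
    }
  }
  put(n, 1, 0L, w[n + 1L])
  put(n, 1, 1L, 0)
  put(n, 1, 2L, 0)
  matrix(solve(A, b), nrow = n, ncol = 6L, byrow = TRUE)
}

# Single quintic segment (normalized time) with fully clamped boundary
# conditions given in real time; `d` is the segment duration.
mj_clamped_segment <- function(x0, x1, v0, v1, a0, a1, d) {
  c0 <- x0
  c1 <- v0 * d
  c2 <- a0 * d^2 / 2
  # remaining three coefficients from conditions at u = 1
  M <- rbind(quintic_row(1, 0L)[4:6],
             quintic_row(1, 1L)[4:6],
             quintic_row(1, 2L)[4:6])
  rhs <- c(x1, v1 * d, a1 * d^2) -
    c(sum(quintic_row(1, 0L)[1:3] * c(c0, c1, c2)),
      sum(quintic_row(1, 1L)[1:3] * c(c0, c1, c2)),
      sum(quintic_row(1, 2L)[1:3] * c(c0, c1, c2)))
  c(c0, c1, c2, solve(M, rhs))
}

# Half-integral of squared jerk for one axis: coefs is n x 6 (normalized
# time), d the segment durations (s). Exact polynomial integral.
mj_jerk_cost_axis <- function(coefs, d) {
  p1 <- 6 * coefs[, 4L]
  p2 <- 24 * coefs[, 5L]
  p3 <- 60 * coefs[, 6L]
  seg <- p1^2 + p1 * p2 + (p2^2 + 2 * p1 * p3) / 3 + p2 * p3 / 2 + p3^2 / 5
  0.5 * sum(seg / d^5)
}

mj_jerk_cost <- function(coefs_x, coefs_y, d) {
  mj_jerk_cost_axis(coefs_x, d) + mj_jerk_cost_axis(coefs_y, d)
}

# Evaluate a piecewise quintic at absolute times `t` (0 at motion onset).
# knot_t has length n+1 (cumulative durations including 0).
mj_eval <- function(coefs, knot_t, t, deriv = 0L) {
  d <- diff(knot_t)
  seg <- findInterval(t, knot_t, rightmost.closed = TRUE)
  seg[seg < 1L] <- 1L
  seg[seg > length(d)] <- length(d)
  u <- (t - knot_t[seg]) / d[seg]
  u <- pmin(pmax(u, 0), 1)
  vapply(seq_along(t), function(i) {
    sum(coefs[seg[i], ] * quintic_row(u[i], deriv)) / d[seg[i]]^deriv
  }, numeric(1))
}

#' Minimum-jerk trajectory through via points
#'
#' Computes the 2-D trajectory that minimizes the half-integral of squared
#' jerk (third derivative of position) over a fixed movement duration,
#' subject to passing exactly through an ordered set of via points, with
#' zero velocity and acceleration at the start and end. For fixed via
#' passage times the optimum is solved exactly as a C^4 piecewise-quintic
#' linear system (independently per axis); passage times are then optimized
#' by a nonlinear search over segment durations (softmax-parameterized so
#' durations stay positive and sum to `duration`), initialized proportional
#' to the straight-line distances between consecutive waypoints.
#'
#' @param start,end Numeric length-2 positions (cm).
#' @param via_points Matrix (k x 2) or data frame of interior via points in
#'   passage order; may be `NULL` or empty for a point-to-point reach.
#' @param duration Total movement duration in seconds.
#' @param passage_times Optional strictly increasing vector of k interior
#'   passage times in (0, duration) used as the fixed times (if
#'   `optimize_times = FALSE`) or as the starting point of the search.
#' @param optimize_times If `TRUE` (default) the via passage times are
#'   optimized to minimize the jerk cost; if `FALSE` they are held at
#'   `passage_times` (or at distance-proportional defaults).
#' @param control Passed to [stats::optim()] for the outer search.
#'
#' @return An object of class `min_jerk_trajectory` with elements
#'   `waypoints`, `knot_times` (0, passage times, duration), `jerk_cost`
#'   (cm^2/s^5, including the 1/2 factor), `coefs_x`, `coefs_y`, and
#'   `converged`. Use [predict()] to sample it.
#'
#' @examples
#' mj <- min_jerk_trajectory(c(0, 0), c(10, 0), duration = 1)
#' mj$jerk_cost            # 360 * L^2 / T^5 for a straight reach
#' head(predict(mj, n = 5))
#' @export
min_jerk_trajectory <- function(start, end, via_points = NULL, duration,
                                passage_times = NULL, optimize_times = TRUE,
                                control = list(maxit = 2000)) {
  check_number(duration, "duration", lower = 0)
  if (duration <= 0) {
    abort("`duration` must be positive.", class = "seqreach_parameter_error")
  }
  if (!is.null(via_points)) {
    via_points <- as.matrix(via_points)
    if (ncol(via_points) != 2L) {
      abort("`via_points` must have two columns (x, y).",
            class = "seqreach_parameter_error")
    }
  }
  W <- rbind(matrix(start, 1L), via_points, matrix(end, 1L))
  n <- nrow(W) - 1L
  chord <- sqrt(rowSums((W[-1L, , drop = FALSE] -
                           W[-nrow(W), , drop = FALSE])^2))
  if (any(chord < 1e-9)) {
    abort("Consecutive waypoints coincide; the geometry is degenerate.",
          class = "seqreach_degenerate_error")
  }

  solve_d <- function(d) {
    cx <- mj_solve_axis(W[, 1L], d)
    cy <- mj_solve_axis(W[, 2L], d)
    list(cx = cx, cy = cy, cost = mj_jerk_cost(cx, cy, d))
  }

  if (!is.null(passage_times)) {
    pt <- as.numeric(passage_times)
    if (length(pt) != n - 1L || any(diff(c(0, pt, duration)) <= 0)) {
      abort("`passage_times` must be strictly increasing inside (0, duration).",
            class = "seqreach_parameter_error")
    }
    d0 <- diff(c(0, pt, duration))
  } else {
    d0 <- duration * chord / sum(chord)
  }

  converged <- TRUE
  if (n == 1L || !optimize_times) {
    d <- d0
    sol <- solve_d(d)
  } else {
    obj <- function(u) {
      e <- exp(u - max(u))
      d <- duration * e / sum(e)
      if (any(d < duration * 1e-4)) return(1e12)
      solve_d(d)$cost
    }
    u0 <- log(d0 / duration)
    opt <- optim(u0, obj, method = "Nelder-Mead", control = control)
    converged <- opt$convergence == 0L
    e <- exp(opt$par - max(opt$par))
    d <- duration * e / sum(e)
    sol <- solve_d(d)
    if (sol$cost > solve_d(d0)$cost) {  # never worse than the start
      d <- d0
      sol <- solve_d(d)
      converged <- FALSE
    }
  }

  structure(
    list(waypoints = W, knot_times = c(0, cumsum(d)),
         jerk_cost = sol$cost, coefs_x = sol$cx, coefs_y = sol$cy,
         duration = duration, converged = converged),
    class = "min_jerk_trajectory"
  )
}

#' Sample a minimum-jerk trajectory
#'
#' @param object A [min_jerk_trajectory()] result.
#' @param times Optional vector of absolute times in `[0, duration]`.
#' @param n Number of uniformly spaced samples if `times` is not given.
#' @param ... Unused.
#' @return A tibble with `t`, `x`, `y`, `vx`, `vy`, `speed`.
#' @export
predict.min_jerk_trajectory <- function(object, times = NULL, n = 500L, ...) {
  if (is.null(times)) times <- seq(0, object$duration, length.out = n)
  kt <- object$knot_times
  vx <- mj_eval(object$coefs_x, kt, times, 1L)
  vy <- mj_eval(object$coefs_y, kt, times, 1L)
  tibble(
    t = times,
    x = mj_eval(object$coefs_x, kt, times, 0L),
    y = mj_eval(object$coefs_y, kt, times, 0L),
    vx = vx, vy = vy,
    speed = sqrt(vx^2 + vy^2)
  )
}

#' @export
print.min_jerk_trajectory <- function(x, ...) {
  cat("<min_jerk_trajectory>\n")
  cat(sprintf("  %d waypoint(s), duration %.3f s, jerk cost %.4g cm^2/s^5\n",
              nrow(x$waypoints), x$duration, x$jerk_cost))
  if (!x$converged) cat("  (passage-time search did not fully converge)\n")
  invisible(x)
}
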