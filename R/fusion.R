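# Movement-fusion metrics: per-transition fusion index, sliding-window
# spatial reorganization (radial distance), and the piecewise-linear
# FI-vs-RD relation.

#' Fusion index of one via transition
#'
#' Compares the mean of the two adjacent peak speeds with the minimum speed
#' at the transition: `FI = 1 - (m - vmin) / m` with
#' `m = (vmax1 + vmax2) / 2`, which simplifies to `vmin / m`. A value of 1
#' indicates a fully coarticulated (fused) transition, 0 a full stop.
#' Measurement noise can push the raw value outside `[0, 1]` (when `vmin`
#' exceeds the mean peak); such values are clamped with a warning.
#'
#' @param vmax1,vmax2 Peak speeds (cm/s) of the two flanking reaches; must
#'   be positive. Vectorized.
#' @param vmin Minimum speed (cm/s) at the transition; nonnegative.
#' @param warn_clamp Emit a warning when clamping occurs.
#' @return Numeric vector of fusion indices in `[0, 1]`.
#' @examples
#' fusion_index(20, 20, 20)   # fully fused -> 1
#' fusion_index(20, 30, 10)   # 1 - (25 - 10)/25 = 0.4
#' @export
fusion_index <- function(vmax1, vmax2, vmin, warn_clamp = TRUE) {
  if (any(!is.finite(vmax1)) || any(!is.finite(vmax2)) ||
      any(vmax1 <= 0) || any(vmax2 <= 0)) {
    abort("Peak speeds `vmax1` and `vmax2` must be positive.",
          class = "seqreach_parameter_error")
  }
  if (any(!is.finite(vmin)) || any(vmin < 0)) {
    abort("`vmin` must be nonnegative.", class = "seqreach_parameter_error")
  }
  m <- (vmax1 + vmax2) / 2
  fi <- 1 - (m - vmin) / m
  if (any(fi > 1) && warn_clamp) {
    warn(sprintf("%d fusion index value(s) exceeded 1 and were clamped.",
                 sum(fi > 1)))
  }
  pmin(pmax(fi, 0), 1)
}

#' Per-trial fusion metrics
#'
#' Applies [fusion_index()] to each of the 7 transition triplets
#' (`vmax_k`, `vmax_{k+1}`, `vmin_k`) of every trial in a metrics table and
#' sums them: with 7 transitions the maximum per-trial fusion index is 7.
#'
#' @param metrics A per-trial metrics tibble with list-columns
#'   `vmax_per_segment` and `vmin_per_transition` (from [trial_metrics()]
#'   or [analyze_trials()]).
#' @return `metrics` with list-column `fi_per_transition` and numeric
#'   column `fi_trial` appended.
#' @export
trial_fusion <- function(metrics) {
  if (!all(c("vmax_per_segment", "vmin_per_transition") %in%
           names(metrics))) {
    abort("`metrics` must carry `vmax_per_segment` and `vmin_per_transition`.",
          class = "seqreach_parameter_error")
  }
  fi_list <- purrr::map2(
    metrics$vmax_per_segment, metrics$vmin_per_transition,
    function(vmax, vmin) {
      if (length(vmax) != length(vmin) + 1L) {
        abort("Need one more peak than transition minima.",
              class = "seqreach_parameter_error")
      }
      fusion_index(head(vmax, -1L), tail(vmax, -1L), vmin,
                   warn_clamp = FALSE)
    }
  )
  raw_hi <- purrr::map2_int(
    metrics$vmax_per_segment, metrics$vmin_per_transition,
    function(vmax, vmin) {
      m <- (head(vmax, -1L) + tail(vmax, -1L)) / 2
      sum(vmin / m > 1)
    }
  )
  if (sum(raw_hi) > 0) {
    warn(sprintf("%d fusion index value(s) exceeded 1 and were clamped.",
                 sum(raw_hi)))
  }
  metrics$fi_per_transition <- fi_list
  metrics$fi_trial <- purrr::map_dbl(fi_list, sum)
  metrics
}

# 95% principal-axes ellipse of a 2-D scatter under a bivariate-normal
# assumption: chi-square(2) quantile scaling of the principal SDs.
confidence_ellipse <- function(xy, coverage = 0.95) {
  centroid <- colMeans(xy)
  if (nrow(xy) < 2L) {
    return(list(centroid = centroid, axes = c(0, 0), angle = 0))
  }
  S <- stats::cov(xy)
  e <- eigen(S, symmetric = TRUE)
  scale <- sqrt(stats::qchisq(coverage, df = 2))
  axes <- scale * sqrt(pmax(e$values, 0))
  angle <- atan2(e$vectors[2L, 1L], e$vectors[1L, 1L])
  list(centroid = centroid, axes = axes, angle = angle)
}

#' Sliding-window spatial reorganization (radial distance)
#'
#' For each sliding window of `window` trials (stride 1) and each reach
#' segment except the first and the last, collects the spatial locations of
#' the per-segment peak speed across the window's trials, fits a
#' principal-axes confidence ellipse (95% coverage under a
#' bivariate-normal assumption), and measures the Euclidean distance `d`
#' from the scatter centroid to the central via point. The radial-distance
#' percentage is `100 * (1 - d / L)` clamped to `[0, 100]`, with `L` the
#' straight-line length of that reach: 100% means the peak-speed centroid
#' sits on the via point; individually executed bell-shaped reaches put
#' the peak near the reach midpoint — and every included reach starts or
#' ends at the via — so they score close to 50%. As movements fuse, the
#' speed peaks drift toward the via passage and the percentage rises.
#'
#' @param analyzed A per-trial table from [analyze_trials()] (needs the
#'   `vmax_location` list-column), for a single participant/condition,
#'   ordered by trial.
#' @param geometry A [build_geometry()] object.
#' @param window Number of trials per window (10 by default).
#' @param coverage Ellipse coverage probability.
#' @return A tibble with one row per window x included segment:
#'   `window_start_trial`, `segment`, `waypoint_id`, centroid coordinates,
#'   ellipse axes and orientation, `d_cm`, `rd_percent`, plus the
#'   window-mean `rd_mean` repeated within each window.
#' @export
radial_distance <- function(analyzed, geometry, window = 10L,
                            coverage = 0.95) {
  stopifnot(inherits(geometry, "reach_geometry"))
  check_count(window, "window", lower = 2L)
  if (nrow(analyzed) < window) {
    abort(sprintf("Need at least %d trials for the sliding window, got %d.",
                  window, nrow(analyzed)),
          class = "seqreach_parameter_error")
  }
  analyzed <- arrange(analyzed, .data$trial)
  W <- waypoint_matrix(geometry)
  via <- W[1L, ]          # the sequence starts at the central via target
  ids <- geometry$reach_sequence
  n_seg <- nrow(W) - 1L
  segs <- 2:(n_seg - 1L)  # exclude first and last reaches
  L <- sqrt(rowSums((W[-1L, , drop = FALSE] -
                       W[-nrow(W), , drop = FALSE])^2))

  out <- purrr::map(seq_len(nrow(analyzed) - window + 1L), function(w0) {
    rows <- purrr::map(segs, function(k) {
      xy <- do.call(rbind, purrr::map(
        analyzed$vmax_location[w0:(w0 + window - 1L)],
        function(m) m[k, , drop = FALSE]
      ))
      ell <- confidence_ellipse(xy, coverage)
      d <- sqrt(sum((ell$centroid - via)^2))
      tibble(
        window_start_trial = analyzed$trial[w0],
        segment = k, waypoint_id = ids[k + 1L],
        centroid_x = ell$centroid[1L], centroid_y = ell$centroid[2L],
        ellipse_major = ell$axes[1L], ellipse_minor = ell$axes[2L],
        ellipse_angle = ell$angle,
        d_cm = d,
        rd_percent = pmin(pmax(100 * (1 - d / L[k]), 0), 100)
      )
    }) |> purrr::list_rbind()
    rows$rd_mean <- mean(rows$rd_percent)
    rows
  }) |> purrr::list_rbind()
  out
}

#' Continuous two-segment piecewise-linear (hinge) fit
#'
#' Least-squares fit of a continuous broken line with three knots: the two
#' outer knots fixed at the data range and one free interior knot (the
#' hinge). For a candidate hinge position the fit is linear
#' (`y ~ x + max(0, x - knot)`); the hinge is located by a grid search over
#' interior data quantiles refined by golden-section optimization of the
#' residual sum of squares.
#'
#' @param x,y Numeric vectors (at least 6 points, `x` spanning a positive
#'   range).
#' @param n_grid Number of quantile grid points for the coarse search.
#' @return An object of class `piecewise_fit`: list with `knot`, `slopes`
#'   (left/right), `intercept` (left-segment intercept), `sse`,
#'   `sse_linear` (single-line fit), and `fitted` accessors via
#'   [predict()]/[tidy()].
#' @examples
#' x <- seq(0, 4, length.out = 50)
#' y <- ifelse(x < 1.6, -0.1 * x, -0.16 + 0.9 * (x - 1.6))
#' piecewise_fit(x, y)$knot
#' @export
piecewise_fit <- function(x, y, n_grid = 50L) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 6L || diff(range(x)) <= 0) {
    abort("Need at least 6 points spanning a positive x range.",
          class = "seqreach_fit_error")
  }
  sse_at <- function(k) {
    h <- pmax(0, x - k)
    f <- lm(y ~ x + h)
    sum(resid(f)^2)
  }
  # knot restricted to interior quantiles so both segments keep >= 2 points
  qs <- quantile(x, probs = seq(0.05, 0.95, length.out = n_grid),
                 names = FALSE)
  qs <- unique(qs)
  sses <- vapply(qs, sse_at, numeric(1))
  k0 <- qs[which.min(sses)]
  span <- diff(range(x)) / n_grid
  opt <- optimize(sse_at, lower = max(min(x), k0 - 2 * span),
                  upper = min(max(x), k0 + 2 * span))
  knot <- if (opt$objective < min(sses)) opt$minimum else k0
  h <- pmax(0, x - knot)
  f <- lm(y ~ x + h)
  cf <- coef(f)
  cf[is.na(cf)] <- 0
  lin <- lm(y ~ x)
  structure(
    list(knot = unname(knot),
         slopes = unname(c(left = cf[["x"]], right = cf[["x"]] + cf[["h"]])),
         intercept = unname(cf[[1L]]),
         sse = sum(resid(f)^2),
         sse_linear = sum(resid(lin)^2),
         model = f, x = x, y = y),
    class = "piecewise_fit"
  )
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat("<piecewise_fit>\n")
  cat(sprintf("  interior knot at x = %.4g; slopes %.4g -> %.4g; sse %.4g\n",
              x$knot, x$slopes[1L], x$slopes[2L], x$sse))
  invisible(x)
}

#' @export
predict.piecewise_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x
       else if (is.numeric(newdata)) newdata
       else newdata$x
  object$intercept + object$slopes[1L] * x +
    (object$slopes[2L] - object$slopes[1L]) * pmax(0, x - object$knot)
}

#' @describeIn piecewise_fit One row per parameter (knot, slopes,
#'   left-segment intercept).
#' @param x,object,newdata,... Method arguments.
#' @export
tidy.piecewise_fit <- function(x, ...) {
  tibble(
    term = c("knot", "slope_left", "slope_right", "intercept"),
    estimate = c(x$knot, x$slopes[1L], x$slopes[2L], x$intercept)
  )
}

#' @describeIn piecewise_fit One-row goodness-of-fit summary.
#' @export
glance.piecewise_fit <- function(x, ...) {
  tibble(sse = x$sse, sse_linear = x$sse_linear,
         n = length(x$x),
         r_squared = 1 - x$sse / sum((x$y - mean(x$y))^2))
}
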