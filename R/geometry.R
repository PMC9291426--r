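#' Build the sequential-reaching task geometry
#'
#' Constructs the workspace layout of the 8-movement reaching task: four
#' circular targets arranged around a central via target. Targets 1 and 4 lie
#' on the y-axis at 10 cm from the via target (target 1 above, target 4
#' below); targets 2 and 3 lie at 5 cm from the via target, placed symmetric
#' about the y-axis with `angle_split` degrees between them. A trial
#' traverses the sequence 1-3-2-4 with a via passage between consecutive
#' targets, i.e. 9 waypoints, 8 movements, and 7 via transitions.
#'
#' The coordinate frame has its origin at the via centre with +y pointing
#' toward target 1 (units cm). All downstream metrics are invariant under
#' rigid rotation and translation, so the orientation of targets 2/3
#' (above or below the via) is configurable via `mirror`.
#'
#' @param angle_split Angle in degrees between targets 2 and 3 as seen from
#'   the via target. Default 126.
#' @param mirror If `TRUE`, targets 2 and 3 are placed below the via target
#'   (negative y); by default they are above.
#' @param target_radius Radius of each target circle in cm (1-cm diameter
#'   targets by default).
#' @param proximity_radius Radius in cm of the proximity region used for
#'   segmentation ("within 2 cm of a target").
#'
#' @return An object of class `reach_geometry`: a list with `via` (length-2
#'   numeric), `targets` (tibble with `target`, `x`, `y`), `target_radius`,
#'   `proximity_radius`, `reach_sequence` (character vector of 9 waypoint
#'   ids) and `waypoints` (tibble of the 9 ordered waypoints with
#'   coordinates).
#'
#' @examples
#' geom <- build_geometry()
#' geom$waypoints
#' @export
build_geometry <- function(angle_split = 126, mirror = FALSE,
                           target_radius = 0.5, proximity_radius = 2.0) {
  check_number(angle_split, "angle_split", lower = 0, upper = 180)
  if (angle_split <= 0 || angle_split >= 180) {
    abort("`angle_split` must lie strictly between 0 and 180 degrees.",
          class = "seqreach_parameter_error")
  }
  check_number(target_radius, "target_radius", lower = 0)
  check_number(proximity_radius, "proximity_radius", lower = 0)

  via <- c(x = 0, y = 0)
  half <- angle_split / 2 * pi / 180
  sgn <- if (mirror) -1 else 1
  # targets 2/3 at radius 5 cm, symmetric about the y-axis
  targets <- tibble(
    target = c("t1", "t2", "t3", "t4"),
    x = c(0, 5 * sin(half), -5 * sin(half), 0),
    y = c(10, sgn * 5 * cos(half), sgn * 5 * cos(half), -10)
  )

  reach_sequence <- c("via", "t1", "via", "t3", "via", "t2", "via", "t4",
                      "via")
  coords <- rbind(via = via, as.matrix(targets[, c("x", "y")]))
  rownames(coords) <- c("via", targets$target)
  waypoints <- tibble(
    waypoint = seq_along(reach_sequence),
    id = reach_sequence,
    x = coords[reach_sequence, "x"],
    y = coords[reach_sequence, "y"]
  )

  structure(
    list(via = via, targets = targets, target_radius = target_radius,
         proximity_radius = proximity_radius,
         reach_sequence = reach_sequence, waypoints = waypoints),
    class = "reach_geometry"
  )
}

#' @export
print.reach_geometry <- function(x, ...) {
  cat("<reach_geometry>\n")
  cat(sprintf("  via at (%.1f, %.1f) cm; target radius %.2f cm; proximity %.1f cm\n",
              x$via[1], x$via[2], x$target_radius, x$proximity_radius))
  cat(sprintf("  sequence: %s (%d movements, %d transitions)\n",
              paste(x$reach_sequence, collapse = "-"),
              length(x$reach_sequence) - 1L, length(x$reach_sequence) - 2L))
  invisible(x)
}

# Matrix of the 9 ordered waypoint coordinates (rows).
waypoint_matrix <- function(geometry) {
  as.matrix(geometry$waypoints[, c("x", "y")])
}
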