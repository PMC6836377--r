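#' Describe an assay arena
#'
#' An \code{arena_spec} captures the geometry of a behavioral assay field:
#' either a circular Petri dish (default 90 mm diameter, the standard
#' food-localization arena) or a rectangular field (default 60 x 30 mm, the
#' photo-orientation container), together with the stimulus that defines the
#' target quadrant -- a food position for chemotactic assays or a light edge
#' for photo-orientation assays.
#'
#' Coordinates are in millimetres with the origin at the arena center, x
#' rightward and y upward. Exactly one of \code{food_xy_mm} and
#' \code{light_edge} must be set.
#'
#' The target quadrant is derived, not stored: for a circular arena it is the
#' quarter disc (bounded by two perpendicular diameters through the center)
#' whose angular bisector passes through the food; for a rectangular arena it
#' is the quarter of the long axis farthest from \code{light_edge}, across the
#' full short axis. Quadrant membership uses half-open boundaries so that no
#' sample is double counted on a dividing line.
#'
#' @param shape "circle" or "rectangle".
#' @param diameter_mm dish diameter in mm (circle only).
#' @param width_mm,height_mm field extent in mm (rectangle only).
#' @param food_xy_mm length-2 numeric, food position in mm, or \code{NULL}.
#'   Must lie strictly inside the arena and, for a circular arena, off-center
#'   (a centered food leaves the target quadrant undefined).
#' @param light_edge one of "left", "right", "top", "bottom", or \code{NULL}.
#' @param reach_radius_mm reach criterion: an animal within this Euclidean
#'   distance of the food counts as having reached it. Default 5 mm,
#'   comparable to the 5-mm food cube used in the assay.
#' @param start one of "opposite" (disc of radius \code{start_radius_mm}
#'   centered \code{start_offset_mm} from the food on the far side through the
#'   arena center; the usual release point drawn in assay schematics),
#'   "center", or "uniform" (uniform over the arena). Used by
#'   \code{\link{simulate_locomotion}}.
#' @param start_offset_mm distance from food to the start-region center
#'   (mode "opposite"), default 30 mm.
#' @param start_radius_mm radius of the start disc, default 5 mm.
#' @return an object of class \code{arena_spec}.
#' @examples
#' dish <- arena_spec("circle", food_xy_mm = c(22.5, 0))
#' field <- arena_spec("rectangle", light_edge = "left")
#' @export
arena_spec <- function(shape = c("circle", "rectangle"),
                       diameter_mm = 90, width_mm = 60, height_mm = 30,
                       food_xy_mm = NULL, light_edge = NULL,
                       reach_radius_mm = 5,
                       start = c("opposite", "center", "uniform"),
                       start_offset_mm = 30, start_radius_mm = 5) {
  shape <- match.arg(shape)
  start <- match.arg(start)
  if (is.null(food_xy_mm) == is.null(light_edge))
    stop("exactly one of 'food_xy_mm' and 'light_edge' must be set")
  if (!is.null(light_edge))
    light_edge <- match.arg(light_edge, c("left", "right", "top", "bottom"))
  stopifnot(is.numeric(reach_radius_mm), length(reach_radius_mm) == 1,
            is.finite(reach_radius_mm), reach_radius_mm > 0)
  a <- structure(list(shape = shape,
                      diameter_mm = if (shape == "circle") diameter_mm else NULL,
                      width_mm = if (shape == "rectangle") width_mm else NULL,
                      height_mm = if (shape == "rectangle") height_mm else NULL,
                      food_xy_mm = food_xy_mm, light_edge = light_edge,
                      reach_radius_mm = reach_radius_mm,
                      start = start, start_offset_mm = start_offset_mm,
                      start_radius_mm = start_radius_mm),
                 class = "arena_spec")
  half <- arena_half_extent(a)
  if (reach_radius_mm >= half)
    stop("'reach_radius_mm' must be smaller than the arena half-extent")
  if (!is.null(food_xy_mm)) {
    stopifnot(is.numeric(food_xy_mm), length(food_xy_mm) == 2,
              all(is.finite(food_xy_mm)))
    if (!in_arena(a, food_xy_mm[1], food_xy_mm[2], tol = -1e-9))
      stop("'food_xy_mm' must lie strictly inside the arena")
  }
  a
}

# Smallest half-extent of the arena (radius, or half the short side).
arena_half_extent <- function(arena) {
  if (arena$shape == "circle") arena$diameter_mm / 2
  else min(arena$width_mm, arena$height_mm) / 2
}

#' Test whether points lie inside an arena
#'
#' @param arena an \code{\link{arena_spec}}.
#' @param x,y numeric vectors of coordinates in mm (arena-centered).
#' @param tol boundary tolerance in mm (positive values admit points slightly
#'   outside; a negative value demands strict interiority).
#' @return logical vector.
#' @export
in_arena <- function(arena, x, y, tol = 0.1) {
  if (arena$shape == "circle") {
    sqrt(x^2 + y^2) <= arena$diameter_mm / 2 + tol
  } else {
    abs(x) <= arena$width_mm / 2 + tol & abs(y) <= arena$height_mm / 2 + tol
  }
}

#' Target-quadrant membership
#'
#' For a circular arena the target quadrant is the quarter disc whose angular
#' bisector points from the center toward the food; for a rectangular arena it
#' is the farthest quarter of the long axis from the light edge, full short
#' axis. Angular boundaries are half-open (counterclockwise lower edge
#' included) so dividing diameters are never double counted.
#'
#' @inheritParams in_arena
#' @return logical vector: is each point in the target quadrant.
#' @export
in_target_quadrant <- function(arena, x, y) {
  if (arena$shape == "circle") {
    f <- arena$food_xy_mm
    if (is.null(f)) stop("circular target quadrant requires 'food_xy_mm'")
    if (sqrt(sum(f^2)) < 1e-9)
      stop("target quadrant undefined: food at the exact arena center")
    bis <- atan2(f[2], f[1])
    rel <- (atan2(y, x) - bis + pi / 4) %% (2 * pi)
    rel >= 0 & rel < pi / 2
  } else {
    w <- arena$width_mm; h <- arena$height_mm
    edge <- arena$light_edge
    if (is.null(edge)) stop("rectangular target quadrant requires 'light_edge'")
    switch(edge,
      left   = x >= w / 4,
      right  = x < -w / 4,
      bottom = y >= h / 4,
      top    = y < -h / 4)
  }
}

# Unit goal direction for each position: toward the food, or away from the
# light edge. Returns the goal heading (radians) for vectors x, y.
goal_heading <- function(arena, x, y) {
  if (!is.null(arena$food_xy_mm)) {
    atan2(arena$food_xy_mm[2] - y, arena$food_xy_mm[1] - x)
  } else {
    switch(arena$light_edge,
      left = rep(0, length(x)), right = rep(pi, length(x)),
      bottom = rep(pi / 2, length(x)), top = rep(-pi / 2, length(x)))
  }
}

# Start-region center and radius used by the locomotion simulator.
start_region <- function(arena) {
  if (arena$start == "center")
    return(list(center = c(0, 0), radius = 0))
  if (arena$start == "uniform")
    return(list(center = c(0, 0), radius = NA_real_))
  # "opposite": offset disc on the far side of the food through the center
  if (!is.null(arena$food_xy_mm)) {
    f <- arena$food_xy_mm
    nf <- sqrt(sum(f^2))
    u <- if (nf < 1e-9) c(-1, 0) else -f / nf
    ctr <- f + u * arena$start_offset_mm
    # keep the start disc inside the arena
    if (!in_arena(arena, ctr[1], ctr[2], tol = -arena$start_radius_mm)) {
      half <- arena_half_extent(arena) - arena$start_radius_mm - 1
      ctr <- u * min(half, sqrt(sum(ctr^2)))
    }
    list(center = ctr, radius = arena$start_radius_mm)
  } else {
    # photo-orientation: release near the lit edge
    w2 <- if (arena$shape == "circle") arena$diameter_mm / 2 else arena$width_mm / 2
    h2 <- if (arena$shape == "circle") arena$diameter_mm / 2 else arena$height_mm / 2
    r <- arena$start_radius_mm
    ctr <- switch(arena$light_edge,
      left = c(-(w2 - r - 1), 0), right = c(w2 - r - 1, 0),
      bottom = c(0, -(h2 - r - 1)), top = c(0, h2 - r - 1))
    list(center = ctr, radius = r)
  }
}

#' @export
print.arena_spec <- function(x, ...) {
  dims <- if (x$shape == "circle") sprintf("diameter %g mm", x$diameter_mm)
          else sprintf("%g x %g mm", x$width_mm, x$height_mm)
  stim <- if (!is.null(x$food_xy_mm))
    sprintf("food at (%g, %g) mm, reach radius %g mm",
            x$food_xy_mm[1], x$food_xy_mm[2], x$reach_radius_mm)
  else sprintf("light at %s edge", x$light_edge)
  cat(sprintf("<arena_spec> %s arena, %s; %s; start: %s\n",
              x$shape, dims, stim, x$start))
  invisible(x)
}
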