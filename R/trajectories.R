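#' A single animal's trajectory
#'
#' Time-stamped planar positions of one animal in an arena, nominally sampled
#' every 0.2 s. Times must be strictly increasing and uniformly spaced within
#' 1%; positions must lie inside the arena within a 0.1-mm tolerance (when an
#' arena is attached).
#'
#' @param animal_id identifier.
#' @param times numeric vector of times, s.
#' @param x_mm,y_mm numeric position vectors, mm (arena-centered).
#' @param arena an \code{\link{arena_spec}} or \code{NULL}.
#' @param interpolated optional logical vector flagging gap-filled samples.
#' @return an object of class \code{trajectory}.
#' @export
trajectory <- function(animal_id, times, x_mm, y_mm, arena = NULL,
                       interpolated = NULL) {
  stopifnot(length(times) >= 2, length(x_mm) == length(times),
            length(y_mm) == length(times),
            all(is.finite(times)), all(is.finite(x_mm)), all(is.finite(y_mm)))
  dts <- diff(times)
  if (any(dts <= 0)) stop("'times' must be strictly increasing")
  if (max(dts) - min(dts) > 0.01 * stats::median(dts))
    stop("time spacing must be uniform within 1%")
  if (!is.null(arena)) {
    stopifnot(inherits(arena, "arena_spec"))
    if (!all(in_arena(arena, x_mm, y_mm, tol = 0.1)))
      stop("trajectory leaves the arena (tolerance 0.1 mm)")
  }
  structure(list(animal_id = as.character(animal_id), times = as.numeric(times),
                 x_mm = as.numeric(x_mm), y_mm = as.numeric(y_mm),
                 arena = arena,
                 interpolated = interpolated %||% rep(FALSE, length(times))),
            class = "trajectory")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' A set of trajectories sharing one arena
#'
#' @param trajectories a non-empty list of \code{\link{trajectory}} objects
#'   sharing one arena.
#' @param group_label optional condition name (e.g. a water type).
#' @return an object of class \code{track_set}.
#' @export
track_set <- function(trajectories, group_label = NULL) {
  stopifnot(is.list(trajectories), length(trajectories) >= 1,
            all(vapply(trajectories, inherits, logical(1), "trajectory")))
  arenas <- lapply(trajectories, `[[`, "arena")
  if (length(unique(vapply(arenas, function(a)
        paste(deparse(a), collapse = ""), character(1)))) > 1)
    stop("all trajectories in a track_set must share one arena")
  structure(list(trajectories = trajectories,
                 arena = arenas[[1]],
                 group_label = group_label),
            class = "track_set")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s: %d samples over %.1f s (dt %.3g s)\n",
              x$animal_id, length(x$times), diff(range(x$times)),
              stats::median(diff(x$times))))
  invisible(x)
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d animals%s\n", length(x$trajectories),
              if (is.null(x$group_label)) "" else paste0(" [", x$group_label, "]")))
  if (!is.null(x$arena)) print(x$arena)
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(animal_id = x$animal_id, time_s = x$times,
             x_mm = x$x_mm, y_mm = x$y_mm, stringsAsFactors = FALSE)
}

#' @export
as.data.frame.track_set <- function(x, ...) {
  do.call(rbind, lapply(x$trajectories, as.data.frame))
}

#' Median gliding speed of a trajectory
#'
#' The speed of an individual is the median of the per-interval speeds
#' \eqn{\lVert \Delta position \rVert / \Delta t} measured at the tracking
#' interval (nominally 0.2 s).
#'
#' @param traj a \code{\link{trajectory}}.
#' @return median speed in mm/s.
#' @examples
#' tr <- trajectory("a", times = seq(0, 0.6, 0.2),
#'                  x_mm = c(0, 0.1, 0.3, 1.2), y_mm = rep(0, 4))
#' median_speed(tr)  # median of 0.5, 1.0, 4.5 -> 1.0 mm/s
#' @export
median_speed <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  v <- step_speeds(traj)
  stats::median(v)
}

step_speeds <- function(traj) {
  sqrt(diff(traj$x_mm)^2 + diff(traj$y_mm)^2) / diff(traj$times)
}

#' Fraction of animals reaching the food
#'
#' An animal counts as having reached the food if any sample at time
#' \code{<= t_limit} lies within the arena's reach radius of the food
#' position (Euclidean distance).
#'
#' @param tracks a \code{\link{track_set}} whose arena has a food position.
#' @param t_limit time limit in seconds (e.g. 600, 1800, 3600 for the 10, 30
#'   and 60-min endpoints).
#' @return list with \code{percent} (0-100) and \code{reached}, a named
#'   logical per animal.
#' @export
fraction_reached <- function(tracks, t_limit) {
  stopifnot(inherits(tracks, "track_set"))
  arena <- tracks$arena
  if (is.null(arena) || is.null(arena$food_xy_mm))
    stop("fraction_reached requires an arena with a food position")
  f <- arena$food_xy_mm; rr <- arena$reach_radius_mm
  reached <- vapply(tracks$trajectories, function(tr) {
    sel <- tr$times <= t_limit
    any(sqrt((tr$x_mm[sel] - f[1])^2 + (tr$y_mm[sel] - f[2])^2) <= rr)
  }, logical(1))
  names(reached) <- vapply(tracks$trajectories, `[[`, character(1), "animal_id")
  list(percent = 100 * mean(reached), reached = reached)
}

#' Time spent in the target quadrant
#'
#' Each sample owns one sampling interval \code{dt}; the occupancy time is
#' \code{dt} summed over samples whose position lies in the target quadrant
#' (half-open boundaries), and the fraction divides by the full assay
#' duration \code{n * dt}.
#'
#' @param traj a \code{\link{trajectory}} whose arena defines a target
#'   quadrant.
#' @return list with \code{seconds} and \code{fraction} in [0, 1].
#' @export
quadrant_time <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(traj$arena)) stop("quadrant_time requires an arena")
  dt <- stats::median(diff(traj$times))
  inq <- in_target_quadrant(traj$arena, traj$x_mm, traj$y_mm)
  list(seconds = sum(inq) * dt, fraction = mean(inq))
}

#' Speed-compensated food-localization index
#'
#' Quadrant occupancy time adjusted so animals of different speeds are
#' comparable, as if every animal moved at a common reference median speed
#' \code{v_ref}: \code{index = quadrant_seconds * median_speed / v_ref}.
#' This equals the time the animal would have spent in the quadrant had its
#' path been replayed at constant \code{v_ref}, so the index is invariant
#' under a global retiming of a completed path (an animal twice as fast over
#' the same path halves its occupancy seconds but doubles its median speed).
#' Reference speeds used in the assays include 0.38, 0.51 and 0.60 mm/s (the
#' median speed of the respective control-deprived group).
#'
#' Immobile animals (median speed 0) have no defined index and return
#' \code{NA} with a warning; exclude them from group summaries.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param v_ref reference median speed in mm/s (> 0).
#' @return the index (seconds-equivalent), or \code{NA} for an immobile
#'   animal.
#' @export
localization_index <- function(traj, v_ref = 0.38) {
  stopifnot(is.numeric(v_ref), length(v_ref) == 1, is.finite(v_ref), v_ref > 0)
  qt <- quadrant_time(traj)
  ms <- median_speed(traj)
  if (ms == 0) {
    warning(sprintf("animal %s is immobile (median speed 0); index undefined",
                    traj$animal_id))
    return(NA_real_)
  }
  qt$seconds * ms / v_ref
}

#' Occupancy heat map of a track set
#'
#' Bins time-weighted positions of every animal on a regular grid, averages
#' the per-animal occupancy distributions, and normalizes so the unmasked
#' cells sum to 1. Cells whose center lies outside the arena are \code{NA}.
#'
#' @param tracks a \code{\link{track_set}}.
#' @param bin_mm bin side length in mm (> 0, smaller than the arena).
#' @return an object of class \code{occupancy_map}: list with \code{matrix}
#'   (rows = y bins, bottom row = lowest y; columns = x bins), \code{x_mid},
#'   \code{y_mid} bin centers, and \code{bin_mm}.
#' @export
occupancy_heatmap <- function(tracks, bin_mm = 3) {
  stopifnot(inherits(tracks, "track_set"), bin_mm > 0)
  arena <- tracks$arena
  if (is.null(arena)) stop("occupancy_heatmap requires an arena")
  if (arena$shape == "circle") {
    xr <- yr <- c(-1, 1) * arena$diameter_mm / 2
  } else {
    xr <- c(-1, 1) * arena$width_mm / 2; yr <- c(-1, 1) * arena$height_mm / 2
  }
  if (bin_mm > min(diff(xr), diff(yr)))
    stop("'bin_mm' is larger than the arena")
  xb <- seq(xr[1], xr[2] + bin_mm, by = bin_mm)
  yb <- seq(yr[1], yr[2] + bin_mm, by = bin_mm)
  nx <- length(xb) - 1L; ny <- length(yb) - 1L
  acc <- matrix(0, ny, nx)
  for (tr in tracks$trajectories) {
    ix <- pmin(pmax(findInterval(tr$x_mm, xb, rightmost.closed = TRUE), 1L), nx)
    iy <- pmin(pmax(findInterval(tr$y_mm, yb, rightmost.closed = TRUE), 1L), ny)
    h <- matrix(0, ny, nx)
    tab <- table(factor(iy, levels = seq_len(ny)), factor(ix, levels = seq_len(nx)))
    h[] <- as.numeric(tab)
    acc <- acc + h / length(tr$times)   # per-animal occupancy distribution
  }
  m <- acc / length(tracks$trajectories)
  xm <- (xb[-1] + xb[-length(xb)]) / 2
  ym <- (yb[-1] + yb[-length(yb)]) / 2
  outside <- outer(ym, xm, function(y, x) !in_arena(arena, x, y, tol = bin_mm / 2))
  m[outside & m == 0] <- NA
  m <- m / sum(m, na.rm = TRUE)
  structure(list(matrix = m, x_mid = xm, y_mid = ym, bin_mm = bin_mm,
                 arena = arena),
            class = "occupancy_map")
}

#' @export
print.occupancy_map <- function(x, ...) {
  cat(sprintf("<occupancy_map> %d x %d cells of %g mm; mass on %d cells\n",
              nrow(x$matrix), ncol(x$matrix), x$bin_mm,
              sum(!is.na(x$matrix) & x$matrix > 0)))
  invisible(x)
}

#' @export
plot.occupancy_map <- function(x, main = "Occupancy", ...) {
  graphics::image(x$x_mid, x$y_mid, t(x$matrix), asp = 1,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "x (mm)", ylab = "y (mm)", main = main, ...)
  if (!is.null(x$arena$food_xy_mm))
    graphics::points(x$arena$food_xy_mm[1], x$arena$food_xy_mm[2],
                     pch = 4, cex = 2, lwd = 2)
  invisible(x)
}

#' Per-animal trajectory metric table
#'
#' Computes every trajectory endpoint for each animal of a track set: median
#' speed, whether the animal reached the food within \code{t_limit}
#' (\code{NA} when the arena has no food), target-quadrant seconds and
#' fraction, and the speed-compensated food-localization index.
#'
#' @param tracks a \code{\link{track_set}}.
#' @param t_limit reach time limit, s.
#' @param v_ref reference speed for \code{\link{localization_index}}, mm/s.
#' @return a data.frame with one row per animal.
#' @export
track_metrics <- function(tracks, t_limit = 600, v_ref = 0.38) {
  stopifnot(inherits(tracks, "track_set"))
  has_food <- !is.null(tracks$arena$food_xy_mm)
  reached <- if (has_food) fraction_reached(tracks, t_limit)$reached else NULL
  rows <- lapply(seq_along(tracks$trajectories), function(i) {
    tr <- tracks$trajectories[[i]]
    qt <- quadrant_time(tr)
    ms <- median_speed(tr)
    li <- if (ms > 0) qt$seconds * ms / v_ref else NA_real_
    data.frame(animal_id = tr$animal_id,
               group = tracks$group_label %||% NA_character_,
               median_speed_mm_s = ms,
               reached = if (has_food) unname(reached[i]) else NA,
               quadrant_s = qt$seconds, quadrant_frac = qt$fraction,
               loc_index = li, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
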