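#' Parameters of the synthetic planarian walker
#'
#' The walker is a biased correlated random walk sampled at a fixed interval
#' \code{dt} (default 0.2 s, the tracking interval of the assays). At each
#' step the heading receives Gaussian noise of SD \code{turn_sigma} plus an
#' attraction term \code{sensitivity * kappa_food * sin(goal - heading)}
#' steering toward the food (or away from the light edge); the per-step speed
#' is gamma-distributed with mean \code{mean_speed} and coefficient of
#' variation \code{speed_cv}.
#'
#' \code{sensitivity} in [0, 1] scales the maximal bias gain
#' \code{kappa_food}; it is the model's stand-in for how strongly the
#' environment (notably free calcium in the water) lets the animal respond to
#' food cues. Use \code{\link{ca_sensitivity}} to map a calcium concentration
#' to this scale.
#'
#' Defaults are calibrated to the observable behavior of the assays: a mean
#' gliding speed of 0.5 mm/s (reported median speeds in these assays fall
#' around 0.38-0.60 mm/s), and a bias-to-noise ratio under which the 10-min
#' food-reaching endpoint is graded across the sensitivity range rather than
#' saturated, with nearly all biased walkers reaching the food within 60 min
#' -- the qualitative dose-response of the food-localization assay.
#'
#' @param mean_speed mean gliding speed, mm/s (> 0).
#' @param speed_cv coefficient of variation of per-step speed (>= 0; 0 gives
#'   constant speed).
#' @param turn_sigma heading noise SD per step, radians (>= 0).
#' @param kappa_food maximal food-bias gain per step (>= 0).
#' @param sensitivity environmental scaling of the bias, in [0, 1].
#' @param dt sampling interval, s (> 0; default 0.2).
#' @param stop_on_food if \code{TRUE} (default) an animal halts once within
#'   the arena's reach radius of the food, as fed animals remain at the food.
#' @return an object of class \code{locomotion_params}.
#' @export
locomotion_params <- function(mean_speed = 0.5, speed_cv = 0.3,
                              turn_sigma = 0.8, kappa_food = 0.1,
                              sensitivity = 1.0, dt = 0.2,
                              stop_on_food = TRUE) {
  num1 <- function(v, nm, lo = 0, strict = FALSE) {
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) ||
        (strict && v <= lo) || (!strict && v < lo))
      stop(sprintf("'%s' must be a finite number %s %g", nm,
                   if (strict) ">" else ">=", lo))
    v
  }
  num1(mean_speed, "mean_speed", strict = TRUE)
  num1(speed_cv, "speed_cv")
  num1(turn_sigma, "turn_sigma")
  num1(kappa_food, "kappa_food")
  num1(sensitivity, "sensitivity")
  if (sensitivity > 1) stop("'sensitivity' must lie in [0, 1]")
  num1(dt, "dt", strict = TRUE)
  structure(list(mean_speed = mean_speed, speed_cv = speed_cv,
                 turn_sigma = turn_sigma, kappa_food = kappa_food,
                 sensitivity = sensitivity, dt = dt,
                 stop_on_food = isTRUE(stop_on_food)),
            class = "locomotion_params")
}

#' Map environmental free-calcium concentration to walker sensitivity
#'
#' A Hill curve \eqn{c^n / (K^n + c^n)} mapping free Ca2+ (mM) onto the
#' [0, 1] sensitivity scale of \code{\link{locomotion_params}}. The default
#' half-saturation K = 0.77 mM equals the calcium concentration of the
#' standard defined planarian medium (Kanatani water), so sensitivity 0.5 at
#' that level; the Hill coefficient defaults to 2. This mapping is a modeling
#' convention for dose-response exploration, not a measured transfer function.
#'
#' @param ca_mM free calcium concentration, mM (>= 0; vectorized).
#' @param K half-saturation constant, mM.
#' @param n Hill coefficient.
#' @return numeric in [0, 1].
#' @examples
#' ca_sensitivity(c(0, 0.077, 0.77, 7.7))
#' @export
ca_sensitivity <- function(ca_mM, K = 0.77, n = 2) {
  stopifnot(all(ca_mM >= 0), K > 0, n > 0)
  ca_mM^n / (K^n + ca_mM^n)
}

#' Simulate planarian locomotion in an arena
#'
#' Runs \code{n_animals} independent biased correlated random walks for
#' \code{duration_s} seconds at the arena's stimulus. Walls reflect: a step
#' that would leave the arena is mirrored back in and the heading mirrored
#' across the wall tangent, so every sample satisfies the containment
#' predicate exactly. With \code{stop_on_food} the walk freezes once the
#' animal is within \code{reach_radius_mm} of the food. Fully reproducible
#' from \code{seed}.
#'
#' @param params a \code{\link{locomotion_params}}.
#' @param arena an \code{\link{arena_spec}} with a food position or a light
#'   edge.
#' @param n_animals number of animals (>= 1).
#' @param duration_s assay duration, s (>= \code{params$dt}).
#' @param seed integer seed.
#' @param group_label optional condition name attached to the result.
#' @return a \code{\link{track_set}} whose trajectories have
#'   \code{floor(duration_s / dt) + 1} samples at uniform \code{dt} (a
#'   warning is issued and the series truncated if \code{dt} does not divide
#'   \code{duration_s}).
#' @examples
#' arena <- arena_spec("circle", food_xy_mm = c(22.5, 0))
#' ts <- simulate_locomotion(locomotion_params(sensitivity = 1),
#'                           arena, n_animals = 5, duration_s = 60, seed = 1)
#' @export
simulate_locomotion <- function(params, arena, n_animals, duration_s, seed,
                                group_label = NULL) {
  stopifnot(inherits(params, "locomotion_params"), inherits(arena, "arena_spec"),
            n_animals >= 1, duration_s >= params$dt)
  dt <- params$dt
  n_exact <- duration_s / dt
  if (abs(n_exact - round(n_exact)) < 1e-9 * max(1, n_exact)) {
    n_steps <- round(n_exact)
  } else {
    n_steps <- floor(n_exact)
    warning(sprintf("dt = %g s does not divide duration %g s; truncating to %d steps",
                    dt, duration_s, n_steps))
  }
  set.seed(as.integer(seed))

  sr <- start_region(arena)
  if (is.na(sr$radius)) {             # uniform over the arena
    x <- y <- numeric(n_animals)
    for (i in seq_len(n_animals)) {
      repeat {
        if (arena$shape == "circle") {
          r2 <- arena$diameter_mm / 2
          p <- stats::runif(2, -r2, r2)
        } else {
          p <- c(stats::runif(1, -arena$width_mm / 2, arena$width_mm / 2),
                 stats::runif(1, -arena$height_mm / 2, arena$height_mm / 2))
        }
        if (in_arena(arena, p[1], p[2], tol = 0)) { x[i] <- p[1]; y[i] <- p[2]; break }
      }
    }
  } else if (sr$radius == 0) {
    x <- rep(sr$center[1], n_animals); y <- rep(sr$center[2], n_animals)
  } else {                            # uniform in the start disc
    rr <- sr$radius * sqrt(stats::runif(n_animals))
    aa <- stats::runif(n_animals, 0, 2 * pi)
    x <- sr$center[1] + rr * cos(aa); y <- sr$center[2] + rr * sin(aa)
  }

  theta <- stats::runif(n_animals, 0, 2 * pi)
  bias <- params$sensitivity * params$kappa_food
  cv <- params$speed_cv
  shape <- if (cv > 0) 1 / cv^2 else NA_real_

  X <- matrix(NA_real_, n_steps + 1L, n_animals)
  Y <- matrix(NA_real_, n_steps + 1L, n_animals)
  X[1L, ] <- x; Y[1L, ] <- y
  frozen <- if (params$stop_on_food && !is.null(arena$food_xy_mm)) {
    sqrt((x - arena$food_xy_mm[1])^2 + (y - arena$food_xy_mm[2])^2) <=
      arena$reach_radius_mm
  } else rep(FALSE, n_animals)

  for (t in seq_len(n_steps)) {
    act <- !frozen
    if (any(act)) {
      g <- goal_heading(arena, x[act], y[act])
      theta[act] <- theta[act] +
        stats::rnorm(sum(act), 0, params$turn_sigma) +
        bias * sin(g - theta[act])
      sp <- if (cv > 0) stats::rgamma(sum(act), shape = shape,
                                      scale = params$mean_speed / shape)
            else rep(params$mean_speed, sum(act))
      nx <- x[act] + sp * dt * cos(theta[act])
      ny <- y[act] + sp * dt * sin(theta[act])
      ref <- reflect_into(arena, nx, ny, theta[act])
      x[act] <- ref$x; y[act] <- ref$y; theta[act] <- ref$theta
      if (params$stop_on_food && !is.null(arena$food_xy_mm)) {
        d <- sqrt((x[act] - arena$food_xy_mm[1])^2 +
                  (y[act] - arena$food_xy_mm[2])^2)
        frozen[act] <- d <= arena$reach_radius_mm
      }
    }
    X[t + 1L, ] <- x; Y[t + 1L, ] <- y
  }

  times <- seq(0, by = dt, length.out = n_steps + 1L)
  trajs <- lapply(seq_len(n_animals), function(i)
    trajectory(animal_id = sprintf("animal_%02d", i), times = times,
               x_mm = X[, i], y_mm = Y[, i], arena = arena))
  ts <- track_set(trajs, group_label = group_label)
  attr(ts, "final_heading") <- theta %% (2 * pi)
  attr(ts, "params") <- params
  attr(ts, "seed") <- as.integer(seed)
  ts
}

# Mirror positions that left the arena back inside and reflect the heading
# across the wall. Steps are small relative to the arena, so one or two
# passes suffice; loop until contained.
reflect_into <- function(arena, x, y, theta) {
  if (arena$shape == "circle") {
    R <- arena$diameter_mm / 2
    for (k in 1:8) {
      r <- sqrt(x^2 + y^2)
      out <- r > R
      if (!any(out)) break
      nxn <- x[out] / r[out]; nyn <- y[out] / r[out]   # outward normal
      vx <- cos(theta[out]); vy <- sin(theta[out])
      dotp <- vx * nxn + vy * nyn
      theta[out] <- atan2(vy - 2 * dotp * nyn, vx - 2 * dotp * nxn)
      sc <- (2 * R - r[out]) / r[out]
      x[out] <- x[out] * sc; y[out] <- y[out] * sc
    }
    # numerical safety: clamp any residual excursion onto the boundary
    r <- sqrt(x^2 + y^2); bad <- r > R
    if (any(bad)) { x[bad] <- x[bad] * R / r[bad]; y[bad] <- y[bad] * R / r[bad] }
  } else {
    w2 <- arena$width_mm / 2; h2 <- arena$height_mm / 2
    for (k in 1:8) {
      outx <- abs(x) > w2; outy <- abs(y) > h2
      if (!any(outx) && !any(outy)) break
      x[outx] <- sign(x[outx]) * (2 * w2) - x[outx]
      theta[outx] <- pi - theta[outx]
      y[outy] <- sign(y[outy]) * (2 * h2) - y[outy]
      theta[outy] <- -theta[outy]
    }
    x <- pmin(pmax(x, -w2), w2); y <- pmin(pmax(y, -h2), h2)
  }
  list(x = x, y = y, theta = theta)
}

#' @export
print.locomotion_params <- function(x, ...) {
  cat(sprintf(paste0("<locomotion_params> mean speed %g mm/s (cv %g), ",
                     "turn sigma %g rad, bias %g x %g, dt %g s, stop_on_food %s\n"),
              x$mean_speed, x$speed_cv, x$turn_sigma, x$sensitivity,
              x$kappa_food, x$dt, x$stop_on_food))
  invisible(x)
}
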