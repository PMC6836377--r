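test_that("trajectory construction validates its invariants", {
  expect_error(trajectory("a", times = c(0, 0.2), x_mm = 1, y_mm = c(0, 0)))
  expect_error(trajectory("a", times = c(0.2, 0), x_mm = c(0, 0),
                          y_mm = c(0, 0)), "increasing")
  expect_error(trajectory("a", times = c(0, 0.2, 0.5), x_mm = rep(0, 3),
                          y_mm = rep(0, 3)), "uniform")
  expect_error(trajectory("a", times = c(0, 0.2), x_mm = c(0, 60),
                          y_mm = c(0, 0), arena = dish_arena()),
               "leaves the arena")
})

test_that("median speed follows the per-step definition", {
  # constant 1 mm per 0.2-s step
  tr <- path_traj(x = seq(0, 5, by = 1), y = rep(0, 6))
  expect_equal(median_speed(tr), 5.0)
  # static animal
  expect_equal(median_speed(path_traj(rep(2, 10), rep(3, 10))), 0)
  # steps of 0.1, 0.2, 0.9 mm at dt = 0.2 -> speeds 0.5, 1.0, 4.5
  tr3 <- path_traj(x = cumsum(c(0, 0.1, 0.2, 0.9)), y = rep(0, 4))
  expect_equal(median_speed(tr3), median(c(0.5, 1.0, 4.5)))
  expect_equal(median_speed(tr3), 1.0)
})

test_that("fraction_reached counts first arrivals within the limit", {
  arena <- dish_arena(food = c(20, 0))
  mk <- function(xs, id) path_traj(xs, rep(0, length(xs)), id = id,
                                   arena = arena)
  # 10 walkers: exactly 4 enter the 5-mm reach radius before t = 1 s
  trs <- c(lapply(1:4, function(i) mk(seq(10, 16, length.out = 6), paste0("r", i))),
           lapply(5:10, function(i) mk(seq(-10, -4, length.out = 6), paste0("n", i))))
  ts <- track_set(trs)
  fr <- fraction_reached(ts, t_limit = 1)
  expect_equal(fr$percent, 40)
  expect_equal(sum(fr$reached), 4L)
  # monotone non-decreasing in the time limit
  late <- track_set(list(mk(seq(0, 16, length.out = 9), "late")))
  p_early <- fraction_reached(late, 0.4)$percent
  p_late <- fraction_reached(late, 1.6)$percent
  expect_lte(p_early, p_late)
  expect_equal(p_late, 100)
  no_food <- photo_arena()
  tr <- path_traj(c(0, 1), c(0, 0), arena = no_food)
  expect_error(fraction_reached(track_set(list(tr)), 10), "food")
})

test_that("quadrant time integrates sample dwell at dt resolution", {
  arena <- dish_arena(food = c(22.5, 0))
  inside <- path_traj(rep(30, 10), rep(0, 10), arena = arena)
  qt <- quadrant_time(inside)
  expect_equal(qt$fraction, 1)
  expect_equal(qt$seconds, 10 * 0.2)
  # alternating in/out samples -> exactly half
  alt <- path_traj(rep(c(30, -30), 10), rep(0, 20), arena = arena)
  expect_equal(quadrant_time(alt)$fraction, 0.5)
  expect_error(quadrant_time(path_traj(c(0, 1), c(0, 0))), "arena")
})

test_that("unbiased center-start walkers occupy the target quadrant 25%", {
  arena <- dish_arena(start = "center")
  p <- locomotion_params(sensitivity = 0, stop_on_food = FALSE)
  ts <- simulate_locomotion(p, arena, 300, 90, seed = 17)
  fr <- mean(sapply(ts$trajectories, function(tr) quadrant_time(tr)$fraction))
  expect_lt(abs(fr - 0.25), 0.02)
})

test_that("localization index compensates speed exactly", {
  arena <- dish_arena(food = c(22.5, 0))
  x <- c(seq(-30, 30, by = 1), rep(30, 20))
  y <- rep(0, length(x))
  tr <- path_traj(x, y, dt = 0.2, arena = arena)
  # identity case: median speed equal to v_ref leaves quadrant time unchanged
  v <- median_speed(tr)
  expect_equal(localization_index(tr, v_ref = v), quadrant_time(tr)$seconds)
  # path-complete replay at speed factors 0.5, 2, 4: index invariant
  idx <- localization_index(tr, v_ref = 0.38)
  for (k in c(0.5, 2, 4)) {
    fast <- trajectory("f", times = tr$times / k, x_mm = x, y_mm = y,
                       arena = arena)
    expect_lt(abs(localization_index(fast, v_ref = 0.38) - idx), 1e-9)
  }
  # zero quadrant time -> zero index at any speed
  away <- path_traj(seq(-40, -30, by = 1), rep(0, 11), arena = arena)
  expect_equal(localization_index(away, v_ref = 0.38), 0)
  # immobile animals are flagged, not scored
  still <- path_traj(rep(0, 5), rep(0, 5), arena = arena)
  expect_warning(li <- localization_index(still, v_ref = 0.38), "immobile")
  expect_true(is.na(li))
})

test_that("occupancy heat maps are normalized occupancy distributions", {
  arena <- dish_arena(food = c(22.5, 0))
  still1 <- path_traj(rep(10, 10), rep(10, 10), arena = arena, id = "a")
  hm1 <- occupancy_heatmap(track_set(list(still1)), bin_mm = 3)
  expect_equal(sum(hm1$matrix > 0, na.rm = TRUE), 1L)
  expect_equal(max(hm1$matrix, na.rm = TRUE), 1)
  still2 <- path_traj(rep(-10, 10), rep(-10, 10), arena = arena, id = "b")
  hm2 <- occupancy_heatmap(track_set(list(still1, still2)), bin_mm = 3)
  vals <- hm2$matrix[!is.na(hm2$matrix) & hm2$matrix > 0]
  expect_equal(sort(vals), c(0.5, 0.5))
  expect_equal(sum(hm2$matrix, na.rm = TRUE), 1, tolerance = 1e-9)
  expect_error(occupancy_heatmap(track_set(list(still1)), bin_mm = 200),
               "larger than the arena")
})

test_that("hot spot of strongly biased walkers sits at the food", {
  arena <- dish_arena(food = c(22.5, 0))
  p <- locomotion_params(sensitivity = 1, kappa_food = 1.5, stop_on_food = TRUE)
  ts <- simulate_locomotion(p, arena, 10, 300, seed = 23)
  hm <- occupancy_heatmap(ts, bin_mm = 3)
  peak <- which(hm$matrix == max(hm$matrix, na.rm = TRUE), arr.ind = TRUE)[1, ]
  px <- hm$x_mid[peak[2]]; py <- hm$y_mid[peak[1]]
  d_food <- sqrt((px - 22.5)^2 + (py - 0)^2)
  expect_lt(d_food, arena$reach_radius_mm + hm$bin_mm)
})

test_that("track_metrics gathers every endpoint per animal", {
  arena <- dish_arena(food = c(22.5, 0))
  ts <- simulate_locomotion(locomotion_params(sensitivity = 0.8), arena,
                            5, 60, seed = 3)
  ts$group_label <- "kanatani"
  m <- track_metrics(ts, t_limit = 60, v_ref = 0.38)
  expect_equal(nrow(m), 5)
  expect_named(m, c("animal_id", "group", "median_speed_mm_s", "reached",
                    "quadrant_s", "quadrant_frac", "loc_index"))
  expect_true(all(m$group == "kanatani"))
  expect_true(all(m$quadrant_frac >= 0 & m$quadrant_frac <= 1))
  expect_true(all(is.finite(m$median_speed_mm_s)))
})
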