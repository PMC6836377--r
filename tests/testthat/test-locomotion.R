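test_that("parameter validation rejects out-of-range walkers", {
  expect_error(locomotion_params(mean_speed = 0), "mean_speed")
  expect_error(locomotion_params(speed_cv = -1), "speed_cv")
  expect_error(locomotion_params(sensitivity = 1.5), "sensitivity")
  expect_error(locomotion_params(dt = 0), "dt")
  expect_error(locomotion_params(turn_sigma = NaN), "turn_sigma")
})

test_that("simulation is reproducible and respects geometry and sampling", {
  arena <- dish_arena()
  p <- locomotion_params(sensitivity = 0.5)
  a <- simulate_locomotion(p, arena, 5, 30, seed = 7)
  b <- simulate_locomotion(p, arena, 5, 30, seed = 7)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- simulate_locomotion(p, arena, 5, 30, seed = 8)
  expect_false(identical(as.data.frame(a), as.data.frame(c2)))
  for (tr in a$trajectories) {
    expect_length(tr$times, 30 / 0.2 + 1)
    expect_equal(unique(round(diff(tr$times), 10)), 0.2)
    expect_true(all(in_arena(arena, tr$x_mm, tr$y_mm, tol = 0)))  # exact
  }
})

test_that("non-dividing dt truncates the series with a warning", {
  p <- locomotion_params(dt = 0.3)
  expect_warning(ts <- simulate_locomotion(p, dish_arena(), 2, 1.0, seed = 1),
                 "truncat")
  expect_length(ts$trajectories[[1]]$times, floor(1.0 / 0.3) + 1)
})

test_that("walls reflect in the rectangular arena too", {
  arena <- photo_arena()
  p <- locomotion_params(mean_speed = 3, turn_sigma = 0.8, sensitivity = 0,
                         stop_on_food = FALSE)
  ts <- simulate_locomotion(p, arena, 20, 60, seed = 3)
  for (tr in ts$trajectories)
    expect_true(all(in_arena(arena, tr$x_mm, tr$y_mm, tol = 0)))
})

test_that("unbiased walkers have uniform final headings", {
  arena <- dish_arena(start = "center")
  p <- locomotion_params(sensitivity = 0, kappa_food = 1.2,
                         stop_on_food = FALSE)
  ts <- simulate_locomotion(p, arena, 1000, 90, seed = 11)
  h <- attr(ts, "final_heading")
  counts <- table(cut(h, breaks = seq(0, 2 * pi, length.out = 9),
                      include.lowest = TRUE))
  expect_gt(chisq.test(as.numeric(counts))$p.value, 0.01)
})

test_that("generated speeds recover the requested median", {
  p <- locomotion_params(mean_speed = 1.0, speed_cv = 0.05, turn_sigma = 0.1,
                         sensitivity = 0, stop_on_food = FALSE)
  ts <- simulate_locomotion(p, dish_arena(), 20, 120, seed = 5)
  v <- unlist(lapply(ts$trajectories, function(tr)
    sqrt(diff(tr$x_mm)^2 + diff(tr$y_mm)^2) / diff(tr$times)))
  expect_lt(abs(median(v) - 1.0) / 1.0, 0.05)
})

test_that("food bias increases the fraction reaching the food", {
  arena <- dish_arena(food = c(22.5, 0))
  base <- locomotion_params(sensitivity = 0, kappa_food = 1.2, mean_speed = 1.0)
  bias <- locomotion_params(sensitivity = 1, kappa_food = 1.2, mean_speed = 1.0)
  t0 <- simulate_locomotion(base, arena, 50, 600, seed = 21)
  t1 <- simulate_locomotion(bias, arena, 50, 600, seed = 22)
  f0 <- fraction_reached(t0, 600)$percent
  f1 <- fraction_reached(t1, 600)$percent
  expect_gt(f1, f0)
})

test_that("calcium-to-sensitivity Hill mapping behaves as documented", {
  expect_equal(ca_sensitivity(0), 0)
  expect_equal(ca_sensitivity(0.77), 0.5)   # half-saturation at the default K
  s <- ca_sensitivity(c(0, 0.077, 0.77, 7.7))
  expect_true(all(diff(s) > 0))
  expect_true(all(s >= 0 & s <= 1))
})

test_that("start regions honor the configured arena geometry", {
  a_off <- dish_arena(food = c(22.5, 0))        # default: opposite disc
  ts <- simulate_locomotion(locomotion_params(), a_off, 30, 1, seed = 2)
  starts <- t(sapply(ts$trajectories, function(tr) c(tr$x_mm[1], tr$y_mm[1])))
  ctr <- c(22.5 - 30, 0)                        # 30 mm from food, through center
  d <- sqrt((starts[, 1] - ctr[1])^2 + (starts[, 2] - ctr[2])^2)
  expect_true(all(d <= a_off$start_radius_mm + 1e-9))
  a_ctr <- dish_arena(start = "center")
  ts2 <- simulate_locomotion(locomotion_params(), a_ctr, 3, 1, seed = 2)
  expect_true(all(sapply(ts2$trajectories, function(tr)
    tr$x_mm[1] == 0 && tr$y_mm[1] == 0)))
})
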