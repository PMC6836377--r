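test_that("arena validation enforces one stimulus and interior food", {
  expect_error(arena_spec("circle"), "exactly one")
  expect_error(arena_spec("circle", food_xy_mm = c(10, 0), light_edge = "left"),
               "exactly one")
  expect_error(arena_spec("circle", food_xy_mm = c(50, 0)),
               "strictly inside")
  expect_error(arena_spec("circle", food_xy_mm = c(10, 0),
                          reach_radius_mm = 60), "half-extent")
  expect_s3_class(dish_arena(), "arena_spec")
  expect_s3_class(photo_arena(), "arena_spec")
})

test_that("containment predicate matches geometry", {
  d <- dish_arena()
  expect_true(in_arena(d, 44.9, 0, tol = 0))
  expect_true(in_arena(d, 45, 0, tol = 0))     # boundary is inside
  expect_false(in_arena(d, 45.2, 0, tol = 0.1))
  r <- photo_arena()
  expect_true(all(in_arena(r, c(-30, 30, 0), c(0, 0, 15), tol = 0)))
  expect_false(in_arena(r, 30.2, 0, tol = 0.1))
})

test_that("circular target quadrant is the quarter disc bisected by the food", {
  d <- dish_arena(food = c(22.5, 0))
  expect_true(in_target_quadrant(d, 30, 0))       # on the bisector
  expect_true(in_target_quadrant(d, 20, 15))      # within +/- 45 degrees
  expect_false(in_target_quadrant(d, 0, 30))      # next quadrant over
  expect_false(in_target_quadrant(d, -30, 0))     # opposite
  # half-open boundaries: the two dividing diameters belong to one quadrant each
  on_upper <- in_target_quadrant(d, 10, 10)       # exactly +45 degrees
  on_lower <- in_target_quadrant(d, 10, -10)      # exactly -45 degrees
  expect_equal(sum(on_upper, on_lower), 1L)
  expect_error(in_target_quadrant(dish_arena(food = c(0, 1e-12)), 1, 1),
               "center")
})

test_that("rectangular target quadrant is the far quarter from the light", {
  r <- photo_arena()  # light at left edge, 60 mm long axis
  expect_true(in_target_quadrant(r, 20, 0))
  expect_true(in_target_quadrant(r, 15, 14))      # boundary x = w/4 included
  expect_false(in_target_quadrant(r, 14.9, 0))
  expect_false(in_target_quadrant(r, -20, 0))
  r2 <- arena_spec("rectangle", light_edge = "right")
  expect_true(in_target_quadrant(r2, -20, 0))
  expect_false(in_target_quadrant(r2, -15, 0))    # half-open: x < -w/4
})

test_that("quadrant membership partitions the circular arena evenly", {
  d <- dish_arena(food = c(17, 9))
  set.seed(42)
  ang <- runif(40000, 0, 2 * pi)
  rad <- 45 * sqrt(runif(40000))
  frac <- mean(in_target_quadrant(d, rad * cos(ang), rad * sin(ang)))
  expect_lt(abs(frac - 0.25), 0.01)
})
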