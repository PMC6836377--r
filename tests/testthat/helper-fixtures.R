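# Shared fixtures: small, fast synthetic objects built in code.

dish_arena <- function(..., food = c(22.5, 0)) {
  arena_spec("circle", diameter_mm = 90, food_xy_mm = food, ...)
}

photo_arena <- function(...) {
  arena_spec("rectangle", width_mm = 60, height_mm = 30, light_edge = "left", ...)
}

# A hand-built trajectory from explicit samples (no arena checks by default).
path_traj <- function(x, y, dt = 0.2, id = "t1", arena = NULL) {
  trajectory(id, times = seq(0, by = dt, length.out = length(x)),
             x_mm = x, y_mm = y, arena = arena)
}

# Independent Holm oracle: literal step-down definition.
holm_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 0
  for (i in seq_len(n)) {
    running <- max(running, (n - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, running)
  }
  adj
}
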