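test_that("Holm adjustment matches the step-down definition", {
  expect_equal(holm_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  set.seed(41)
  for (i in 1:10) {
    p <- runif(sample(2:8, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, holm_oracle(p))
    expect_true(all(adj >= p))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))   # monotone in rank order
  }
})

test_that("compare_groups validates its inputs", {
  expect_error(compare_groups(data.frame(group_label = "a", value = 1:5)),
               "at least 2 groups")
  expect_error(compare_groups(data.frame(group_label = rep(c("a", "b"), c(5, 2)),
                                         value = rnorm(7))),
               "at least 3 values")
  expect_error(compare_groups(data.frame(group_label = rep(c("a", "b"), each = 5),
                                         value = rep(1, 10))),
               "identical")
})

test_that("the normality gate routes to the expected branch", {
  set.seed(5)
  normal_tbl <- data.frame(group_label = rep(c("a", "b"), each = 25),
                           value = c(rnorm(25), rnorm(25, 1)))
  gc_n <- compare_groups(normal_tbl, design = "overall")
  expect_equal(gc_n$decision_path$branch_taken, "parametric")
  expect_match(gc_n$tests$test, "t$")
  skew_tbl <- data.frame(group_label = rep(c("a", "b"), each = 60),
                         value = c(rexp(60)^2, rexp(60)^2 + 1))
  gc_s <- compare_groups(skew_tbl, design = "overall")
  expect_equal(gc_s$decision_path$branch_taken, "rank")
  expect_equal(gc_s$tests$test, "Wilcoxon rank sum")
  # explicit override is honored and recorded
  gc_f <- compare_groups(normal_tbl, design = "overall", branch = "rank")
  expect_equal(gc_f$tests$test, "Wilcoxon rank sum")
  expect_equal(gc_f$decision_path$branch_requested, "rank")
})

test_that("a duplicated group compares as identical (p = 1)", {
  v <- c(1.2, 3.4, 2.2, 5.0, 0.7, 2.9)
  tbl <- data.frame(group_label = rep(c("a", "b"), each = 6), value = c(v, v))
  gc <- compare_groups(tbl, design = "overall", branch = "rank")
  expect_equal(gc$tests$p_raw, 1)
})

test_that("three-group designs produce omnibus and pairwise reports", {
  set.seed(8)
  tbl <- data.frame(group_label = rep(c("ctrl", "low", "high"), each = 12),
                    value = c(rnorm(12, 0), rnorm(12, 0.2), rnorm(12, 2)))
  ov <- compare_groups(tbl, design = "overall")
  expect_equal(nrow(ov$tests), 1)
  ap <- compare_groups(tbl, design = "all-pairs", branch = "rank")
  expect_equal(nrow(ap$tests), 3)
  expect_true(all(ap$tests$p_adjusted >= ap$tests$p_raw))
  expect_equal(ap$tests$p_adjusted, holm_oracle(ap$tests$p_raw))
  dn <- compare_groups(tbl, design = "pairwise-vs-control", control = "ctrl",
                       branch = "parametric")
  expect_equal(nrow(dn$tests), 2)
  expect_equal(dn$tests$test, rep("Dunnett", 2))
  kw <- compare_groups(tbl, design = "overall", branch = "rank")
  expect_equal(kw$tests$test, "Kruskal-Wallis")
})

test_that("null relabeling keeps the rank branch at its nominal level", {
  set.seed(77)
  reps <- 400
  rej <- logical(reps)
  for (i in seq_len(reps)) {
    tbl <- data.frame(group_label = rep(c("a", "b"), each = 15),
                      value = rnorm(30))
    gc <- compare_groups(tbl, design = "overall", branch = "rank")
    rej[i] <- gc$tests$p_raw < 0.05
  }
  expect_lt(abs(mean(rej) - 0.05), 0.03)  # Monte-Carlo error at 400 reps
})

test_that("OLS summaries are exact on constructed data", {
  r <- regression_r2(0:10, 2 * (0:10) + 1)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)
  expect_equal(r$r_squared, 1)
  # symmetric tent: slope 0, r^2 = 0 (hand OLS: Sxy = 0)
  r0 <- regression_r2(c(0, 1, 2), c(0, 1, 0))
  expect_equal(r0$r_squared, 0)
  expect_error(regression_r2(rep(1, 5), rnorm(5)), "degenerate")
  expect_error(regression_r2(1:2, 1:2), "at least 3")
})

test_that("r^2 vanishes for independent data and survives affine maps", {
  set.seed(19)
  x <- rnorm(500); y <- rnorm(500)
  expect_lt(regression_r2(x, y)$r_squared, 0.05)
  a <- regression_r2(x, 3 * y - 7)$r_squared
  b <- regression_r2(10 * x + 2, y)$r_squared
  expect_equal(a, regression_r2(x, y)$r_squared)
  expect_equal(b, regression_r2(x, y)$r_squared)
})

test_that("growth summaries locate the doubling crossing", {
  gs <- growth_summary(data.frame(batch = 1, week = 0:2,
                                  count = c(10, 14.14, 20)), n0 = 10)
  expect_equal(gs$doubling_time_weeks, 2.0, tolerance = 1e-9)
  flat <- growth_summary(data.frame(batch = rep(1:3, each = 3),
                                    week = rep(0:2, 3),
                                    count = rep(10, 9)))
  expect_false(flat$reached)
  expect_true(is.na(flat$doubling_time_weeks))
  expect_error(growth_summary(data.frame(batch = 1, week = 0:1,
                                         count = c(10, -2))),
               "non-negative")
  # t-based CI: hand-computed for 3 batches of known counts
  cts <- data.frame(batch = rep(1:3, each = 2), week = rep(0:1, 3),
                    count = c(10, 12, 10, 16, 10, 20))
  gs2 <- growth_summary(cts)
  expect_equal(gs2$trend, c(10, 16))
  expect_equal(gs2$ci_halfwidth[2], qt(0.975, 2) * sd(c(12, 16, 20)) / sqrt(3))
})

test_that("doubling time falls as the fission rate rises", {
  dts <- sapply(c(0.2, 0.414, 0.6), function(fp) {
    counts <- simulate_population(growth_params(fission_p = fp, weeks = 6,
                                                n_batches = 50), seed = 101)
    growth_summary(counts, n0 = 10)$doubling_time_weeks
  })
  expect_true(all(diff(dts) < 0))
})
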