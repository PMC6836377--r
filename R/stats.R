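#' Normality-gated group comparison workflow
#'
#' Reproduces the conventional decision path for behavioral metric tables:
#' per-group normality is screened with a Lilliefors-corrected
#' Kolmogorov-Smirnov test (alpha = 0.05); if every group passes, the
#' parametric branch is taken (one-way ANOVA for the overall design, Dunnett
#' contrasts against a control, or pairwise Welch t tests -- with an F test
#' choosing Student vs Welch for a two-group comparison); otherwise the
#' rank-based branch is taken (Kruskal-Wallis, or pairwise Wilcoxon rank-sum
#' tests). Families of pairwise p values are Holm-adjusted. Every decision is
#' recorded in the returned report, and significance is declared at
#' \code{p < alpha} (default 0.05).
#'
#' Groups with fewer than 4 values (below the Lilliefors minimum) or zero
#' variance send the workflow down the rank-based branch; \code{branch}
#' overrides the gate entirely.
#'
#' @param table data.frame with columns \code{group_label} and \code{value}
#'   (a \code{unit_id} column is carried through if present); at least 2
#'   groups with at least 3 finite values each.
#' @param design \code{"overall"} (one omnibus test),
#'   \code{"pairwise-vs-control"}, or \code{"all-pairs"}.
#' @param control control group label for \code{"pairwise-vs-control"};
#'   default the first group level.
#' @param alpha significance level (default 0.05).
#' @param branch \code{"auto"} (normality-gated), \code{"parametric"}, or
#'   \code{"rank"}.
#' @return an object of class \code{group_comparison}: \code{tests}
#'   (data.frame with test name, comparison, statistic, \code{p_raw},
#'   \code{p_adjusted}, significance), \code{decision_path} (normality and
#'   variance screening, branch taken), \code{alpha}.
#' @examples
#' tbl <- data.frame(group_label = rep(c("ctrl", "low", "high"), each = 8),
#'                   value = c(rnorm(8, 1), rnorm(8, 1), rnorm(8, 2)))
#' compare_groups(tbl, design = "pairwise-vs-control", control = "ctrl")
#' @export
compare_groups <- function(table, design = c("overall", "pairwise-vs-control",
                                             "all-pairs"),
                           control = NULL, alpha = 0.05,
                           branch = c("auto", "parametric", "rank")) {
  design <- match.arg(design)
  branch <- match.arg(branch)
  stopifnot(is.data.frame(table), all(c("group_label", "value") %in% names(table)))
  tbl <- table[is.finite(table$value), , drop = FALSE]
  tbl$group_label <- factor(as.character(tbl$group_label),
                            levels = unique(as.character(tbl$group_label)))
  ng <- nlevels(tbl$group_label)
  if (ng < 2) stop("at least 2 groups are required")
  sizes <- table(tbl$group_label)
  if (any(sizes < 3)) stop("every group needs at least 3 values")
  if (stats::sd(tbl$value) == 0)
    stop("all values identical: nothing to compare")
  groups <- split(tbl$value, tbl$group_label)

  # normality screen (Lilliefors-corrected KS, alpha = 0.05)
  norm_p <- vapply(groups, function(v) {
    if (length(v) < 4 || stats::sd(v) == 0) return(NA_real_)
    suppressWarnings(nortest::lillie.test(v)$p.value)
  }, numeric(1))
  all_normal <- all(!is.na(norm_p) & norm_p >= 0.05)
  use_parametric <- switch(branch, auto = all_normal,
                           parametric = TRUE, rank = FALSE)

  var_p <- NA_real_
  tests <- NULL
  if (design == "overall") {
    if (ng == 2) {
      a <- groups[[1]]; b <- groups[[2]]
      if (use_parametric) {
        var_p <- stats::var.test(a, b)$p.value
        eq <- var_p >= 0.05
        tt <- stats::t.test(a, b, var.equal = eq)
        tests <- test_row(if (eq) "Student t" else "Welch t",
                          paste(names(groups), collapse = " vs "),
                          unname(tt$statistic), tt$p.value)
      } else {
        wt <- suppressWarnings(stats::wilcox.test(a, b))
        tests <- test_row("Wilcoxon rank sum",
                          paste(names(groups), collapse = " vs "),
                          unname(wt$statistic), wt$p.value)
      }
    } else if (use_parametric) {
      fit <- stats::aov(value ~ group_label, data = tbl)
      sm <- summary(fit)[[1]]
      tests <- test_row("one-way ANOVA", "overall",
                        sm$`F value`[1], sm$`Pr(>F)`[1])
    } else {
      kw <- stats::kruskal.test(value ~ group_label, data = tbl)
      tests <- test_row("Kruskal-Wallis", "overall",
                        unname(kw$statistic), kw$p.value)
    }
  } else {
    if (design == "pairwise-vs-control") {
      control <- control %||% levels(tbl$group_label)[1]
      if (!control %in% levels(tbl$group_label))
        stop(sprintf("control group '%s' not present", control))
      others <- setdiff(levels(tbl$group_label), control)
      pairs <- lapply(others, function(g) c(control, g))
    } else {
      cmb <- utils::combn(levels(tbl$group_label), 2)
      pairs <- lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
    }
    if (use_parametric && design == "pairwise-vs-control") {
      # Dunnett many-to-one contrasts (joint multiplicity adjustment)
      tbl$group_label <- stats::relevel(tbl$group_label, ref = control)
      fit <- stats::aov(value ~ group_label, data = tbl)
      gl <- multcomp::glht(fit, linfct = multcomp::mcp(group_label = "Dunnett"))
      sgl <- summary(gl)
      tests <- do.call(rbind, lapply(seq_along(sgl$test$tstat), function(i)
        test_row("Dunnett", names(sgl$test$tstat)[i],
                 unname(sgl$test$tstat[i]), unname(sgl$test$pvalues[i]),
                 adjusted = TRUE)))
    } else {
      rows <- lapply(pairs, function(pr) {
        a <- groups[[pr[1]]]; b <- groups[[pr[2]]]
        if (use_parametric) {
          tt <- stats::t.test(a, b, var.equal = FALSE)
          test_row("Welch t", paste(pr, collapse = " vs "),
                   unname(tt$statistic), tt$p.value)
        } else {
          wt <- suppressWarnings(stats::wilcox.test(a, b))
          test_row("Wilcoxon rank sum", paste(pr, collapse = " vs "),
                   unname(wt$statistic), wt$p.value)
        }
      })
      tests <- do.call(rbind, rows)
      tests$p_adjusted <- holm_adjust(tests$p_raw)
    }
  }
  if (is.null(tests$p_adjusted) || all(is.na(tests$p_adjusted)))
    tests$p_adjusted <- tests$p_raw
  tests$significant <- tests$p_adjusted < alpha
  structure(list(tests = tests,
                 decision_path = list(
                   normality_p = norm_p,
                   all_groups_normal = all_normal,
                   variance_f_test_p = var_p,
                   branch_requested = branch,
                   branch_taken = if (use_parametric) "parametric" else "rank",
                   design = design),
                 alpha = alpha),
            class = "group_comparison")
}

test_row <- function(name, comparison, statistic, p, adjusted = NA) {
  data.frame(test = name, comparison = comparison,
             statistic = statistic, p_raw = p,
             p_adjusted = if (isTRUE(adjusted)) p else NA_real_,
             stringsAsFactors = FALSE)
}

#' Holm step-down adjustment
#'
#' Thin wrapper over \code{stats::p.adjust(method = "holm")}, kept as a named
#' step of the workflow: adjusted p values are monotone non-decreasing in the
#' rank order of the raw values and never smaller than them.
#'
#' @param p numeric vector of raw p values.
#' @return adjusted p values.
#' @examples
#' holm_adjust(c(0.01, 0.02, 0.04))  # 0.03, 0.04, 0.04
#' @export
holm_adjust <- function(p) stats::p.adjust(p, method = "holm")

#' @export
print.group_comparison <- function(x, ...) {
  dp <- x$decision_path
  cat(sprintf("<group_comparison> design: %s; branch: %s%s\n",
              dp$design, dp$branch_taken,
              if (dp$branch_requested != "auto") " (forced)" else ""))
  np <- dp$normality_p
  cat("  normality (Lilliefors KS) p per group:",
      paste(sprintf("%s=%.3g", names(np), np), collapse = ", "), "\n")
  if (!is.na(dp$variance_f_test_p))
    cat(sprintf("  F-test equal variances p = %.3g\n", dp$variance_f_test_p))
  print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Ordinary least-squares regression with r-squared
#'
#' Fits \code{y ~ x} by OLS and reports slope, intercept and
#' \code{r^2 = 1 - RSS/TSS}, the summary used for dose-response
#' correlations (e.g. ion concentration vs food-localization score).
#'
#' @param x,y paired numeric vectors, at least 3 finite pairs; \code{x} must
#'   vary.
#' @return list with \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{n}.
#' @examples
#' regression_r2(0:10, 2 * (0:10) + 1)
#' @export
regression_r2 <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("at least 3 finite paired points are required")
  if (stats::var(x) == 0) stop("'x' is degenerate (zero variance)")
  fit <- stats::lm(y ~ x)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = if (tss == 0) 0 else 1 - rss / tss,
       n = length(x))
}

#' Summarize weekly population counts
#'
#' Computes the per-week trend (mean across batches) with 95% t-based
#' confidence half-widths, and the doubling time: the earliest time at which
#' the trend crosses twice the starting count \code{n0}, located by linear
#' interpolation between weekly means ("not reached" if the trend never
#' crosses).
#'
#' @param counts data.frame with columns \code{batch}, \code{week},
#'   \code{count} (finite, non-negative), at least 2 weeks.
#' @param n0 starting count the doubling line refers to; default the mean
#'   count at the earliest week.
#' @return an object of class \code{growth_summary}: \code{weeks},
#'   \code{trend}, \code{ci_halfwidth} (NA with a single batch),
#'   \code{doubling_time_weeks} (NA if not reached), \code{reached},
#'   \code{n0}, \code{n_batches}.
#' @examples
#' gs <- growth_summary(simulate_population(growth_params(fission_p = 0.5),
#'                                          seed = 1))
#' @export
growth_summary <- function(counts, n0 = NULL) {
  stopifnot(is.data.frame(counts),
            all(c("batch", "week", "count") %in% names(counts)))
  if (any(!is.finite(counts$count)) || any(counts$count < 0))
    stop("counts must be finite and non-negative")
  weeks <- sort(unique(counts$week))
  if (length(weeks) < 2) stop("at least 2 weeks are required")
  by_week <- split(counts$count, factor(counts$week, levels = weeks))
  trend <- unname(vapply(by_week, mean, numeric(1)))
  nb <- vapply(by_week, length, integer(1))
  ci <- vapply(seq_along(by_week), function(i) {
    v <- by_week[[i]]
    if (length(v) < 2) return(NA_real_)
    stats::qt(0.975, length(v) - 1) * stats::sd(v) / sqrt(length(v))
  }, numeric(1))
  n0 <- n0 %||% trend[1]
  target <- 2 * n0
  dt_weeks <- NA_real_
  if (trend[1] >= target) {
    dt_weeks <- weeks[1]
  } else {
    for (i in seq_len(length(weeks) - 1)) {
      if (trend[i] < target && trend[i + 1] >= target) {
        dt_weeks <- weeks[i] + (target - trend[i]) /
          (trend[i + 1] - trend[i]) * (weeks[i + 1] - weeks[i])
        break
      }
    }
  }
  structure(list(weeks = weeks, trend = trend,
                 ci_halfwidth = unname(ci),
                 doubling_time_weeks = dt_weeks,
                 reached = !is.na(dt_weeks),
                 n0 = n0, n_batches = max(nb)),
            class = "growth_summary")
}

#' @export
print.growth_summary <- function(x, ...) {
  cat(sprintf("<growth_summary> %d batches, weeks %g..%g, n0 = %g\n",
              x$n_batches, min(x$weeks), max(x$weeks), x$n0))
  dtw <- if (x$reached) sprintf("%.2f weeks", x$doubling_time_weeks)
         else "not reached"
  cat(sprintf("  doubling time: %s\n", dtw))
  df <- data.frame(week = x$weeks, trend = round(x$trend, 2),
                   ci95 = round(x$ci_halfwidth, 2))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.growth_summary <- function(x, main = "Population growth", ...) {
  lo <- x$trend - ifelse(is.na(x$ci_halfwidth), 0, x$ci_halfwidth)
  hi <- x$trend + ifelse(is.na(x$ci_halfwidth), 0, x$ci_halfwidth)
  graphics::plot(x$weeks, x$trend, type = "n", ylim = range(0, hi, 2.2 * x$n0),
                 xlab = "week", ylab = "individuals", main = main, ...)
  graphics::polygon(c(x$weeks, rev(x$weeks)), c(lo, rev(hi)),
                    col = grDevices::grey(0.85), border = NA)
  graphics::lines(x$weeks, x$trend, lwd = 2)
  graphics::abline(h = 2 * x$n0, lty = 2)
  if (x$reached) graphics::abline(v = x$doubling_time_weeks, lty = 3)
  invisible(x)
}
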