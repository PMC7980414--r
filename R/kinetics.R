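#' Two-sample t test with degenerate-variance handling
#'
#' Thin wrapper over [stats::t.test()] defaulting to the pooled-variance
#' Student's test (the test used for all colocalization comparisons
#' against undamaged controls), with an unequal-variance Welch variant,
#' since unequal variances are expected across temporal series. Degenerate
#' inputs (zero variance in both groups) are flagged rather than erroring:
#' equal means give t = 0, p = 1; unequal means give an infinite t, p = 0.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param variant `"pooled"` (Student's, default) or `"welch"`.
#' @return Object of class `ttest_result`: `t`, `df`, `p`, `variant`,
#'   `degenerate` flag.
#' @export
t_test_two_sample <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stopf("two-sample t test needs n >= 2 per group (got %d and %d)",
          length(a), length(b))
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stopf("t test inputs must be finite")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(structure(list(t = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
                          df = length(a) + length(b) - 2,
                          p = if (eq) 1 else 0,
                          variant = variant, degenerate = TRUE),
                     class = "ttest_result"))
  }
  tt <- stats::t.test(a, b, var.equal = (variant == "pooled"))
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, variant = variant, degenerate = FALSE),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("<t test (%s): t = %.4g, df = %.4g, p = %.4g%s>\n",
              x$variant, x$t, x$df, x$p,
              if (x$degenerate) ", degenerate (zero variance)" else ""))
  invisible(x)
}

#' Aggregate per-nucleus colocalization ratios into a kinetic trace
#'
#' Groups labeled per-nucleus ratios by condition and recovery time,
#' computing mean, SE = sd/sqrt(n) and a two-sample t test of each group
#' against the control group (a single undamaged control group per
#' protein, not time-matched). Input order does not matter.
#'
#' @param results data frame with columns `nucleus_id`, `condition`,
#'   `time_h`, and the ratio column named by `metric` (`ratio_count` by
#'   default) — e.g. the output of [run_tier1()].
#' @param control_condition label of the control group (default
#'   `"control"`); all its rows are pooled as the reference.
#' @param metric column to aggregate.
#' @param variant t-test variant, `"pooled"` or `"welch"`.
#' @param alpha significance level recorded alongside each p (default
#'   0.05).
#' @return Data frame of class `kinetic_trace`: one row per
#'   (condition, time_h) with `mean`, `se`, `n`, `p_vs_control`,
#'   `significant`, `test_variant`.
#' @export
aggregate_timecourse <- function(results, control_condition = "control",
                                 metric = "ratio_count",
                                 variant = c("pooled", "welch"),
                                 alpha = 0.05) {
  variant <- match.arg(variant)
  need <- c("nucleus_id", "condition", "time_h", metric)
  miss <- setdiff(need, names(results))
  if (length(miss)) stopf("results missing column(s): %s",
                          paste(miss, collapse = ", "))
  bad <- which(is.na(results$condition) | is.na(results$time_h))
  if (length(bad))
    stopf("unlabeled result for nucleus '%s'", results$nucleus_id[bad[1L]])
  ctrl <- results[[metric]][results$condition == control_condition]
  groups <- split(results,
                  list(results$condition, results$time_h), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    v <- g[[metric]]
    is_ctrl <- g$condition[1L] == control_condition
    p <- if (!is_ctrl && length(v) >= 2L && length(ctrl) >= 2L)
      t_test_two_sample(v, ctrl, variant = variant)$p else NA_real_
    data.frame(condition = g$condition[1L], time_h = g$time_h[1L],
               metric = metric, mean = mean(v),
               se = stats::sd(v) / sqrt(length(v)), n = length(v),
               p_vs_control = p, significant = !is.na(p) & p < alpha,
               test_variant = variant)
  }))
  out <- out[order(out$condition, out$time_h), ]
  rownames(out) <- NULL
  class(out) <- c("kinetic_trace", "data.frame")
  out
}

#' @export
plot.kinetic_trace <- function(x, ...) {
  conds <- unique(x$condition)
  cols <- grDevices::hcl.colors(max(3L, length(conds)), "Dark 3")
  graphics::plot(NA, xlim = range(x$time_h),
                 ylim = range(c(x$mean - x$se, x$mean + x$se), na.rm = TRUE),
                 xlab = "recovery time (h)", ylab = unique(x$metric)[1L],
                 ...)
  for (k in seq_along(conds)) {
    g <- x[x$condition == conds[k], ]
    g <- g[order(g$time_h), ]
    graphics::lines(g$time_h, g$mean, col = cols[k], lwd = 2)
    graphics::arrows(g$time_h, g$mean - g$se, g$time_h, g$mean + g$se,
                     angle = 90, code = 3, length = 0.03, col = cols[k])
  }
  graphics::abline(h = 1, lty = 3)
  graphics::legend("topright", legend = conds, col = cols[seq_along(conds)],
                   lwd = 2, bty = "n")
  invisible(x)
}
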