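# Matched-pair and group-comparison statistics for explant summaries.
# All tests are authored from the formulas (base R supplies only the
# reference distributions) and are pure: same input (and seed for the
# Monte-Carlo Dunnett) gives identical output.

#' Matched paired t-test
#'
#' For paired columns `a` and `b` of a data frame, tests whether the mean of
#' `a - b` is zero: `t = mean_diff / (sd_diff / sqrt(n))`, `df = n - 1`,
#' two-sided p from the t distribution.
#'
#' @param data A data frame with one row per experimental unit.
#' @param a,b Unquoted column names of the paired measurements.
#' @return A `qus_paired_t` object; see [tidy()] / [glance()].
#' @export
#' @examples
#' d <- tibble::tibble(pre = c(1.0, 1.1, 1.2), post = c(1.09, 1.20, 1.31))
#' tidy(paired_t_test(d, post, pre))
paired_t_test <- function(data, a, b) {
  x <- eval_tidy(enquo(a), data)
  y <- eval_tidy(enquo(b), data)
  if (length(x) != length(y)) stop_cbi("paired columns differ in length.")
  if (anyNA(x) || anyNA(y)) stop_cbi("paired measurements contain NA.")
  n <- length(x)
  if (n < 2L) stop_cbi("need at least 2 pairs.")
  d <- x - y
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) stop_cbi("zero-variance differences: paired t-test undefined.")
  t_stat <- m / (s / sqrt(n))
  structure(
    list(statistic = t_stat, df = n - 1L,
         p.value = 2 * pt(-abs(t_stat), n - 1L),
         mean_diff = m, sd_diff = s, n = n),
    class = "qus_paired_t"
  )
}

#' One-way analysis of variance
#'
#' Standard between/within decomposition: `F = MS_between / MS_within` with
#' `k - 1` and `N - k` degrees of freedom. Requires at least two groups,
#' each with at least two observations and nonzero variance.
#'
#' @param data A data frame with one row per observation.
#' @param value Unquoted column of measurements.
#' @param group Unquoted column of group labels.
#' @return A `qus_anova` object; see [tidy()] / [glance()].
#' @export
one_way_anova <- function(data, value, group) {
  y <- eval_tidy(enquo(value), data)
  g <- as.factor(eval_tidy(enquo(group), data))
  if (anyNA(y) || anyNA(g)) stop_cbi("measurements or labels contain NA.")
  k <- nlevels(g)
  if (k < 2L) stop_cbi("need at least 2 groups.")
  n_i <- tabulate(g)
  if (any(n_i < 2L)) stop_cbi("every group needs at least 2 observations.")
  v_i <- tapply(y, g, stats::var)
  if (any(v_i == 0)) stop_cbi("a group has zero variance.")
  n <- length(y)
  grand <- mean(y)
  m_i <- tapply(y, g, mean)
  ss_between <- sum(n_i * (m_i - grand)^2)
  ss_within <- sum((y - m_i[as.integer(g)])^2)
  df_b <- k - 1L
  df_w <- n - k
  f_stat <- (ss_between / df_b) / (ss_within / df_w)
  structure(
    list(statistic = f_stat, df_between = df_b, df_within = df_w,
         p.value = pf(f_stat, df_b, df_w, lower.tail = FALSE),
         ss_between = ss_between, ss_within = ss_within, n = n, k = k),
    class = "qus_anova"
  )
}

#' Dunnett-type many-to-one comparisons by seeded Monte Carlo
#'
#' Compares every group mean to a designated control with the pooled-SE
#' statistic `t_i = (mean_i - mean_0) / (s_p sqrt(1/n_i + 1/n_0))`, and
#' adjusts for multiplicity with the distribution of the maximum absolute
#' statistic under the joint null: group means and the pooled variance are
#' drawn from their null sampling distributions (which reproduces the
#' correlation induced by the shared control), and the adjusted p for each
#' comparison is the tail probability of `max_j |T_j|` beyond the observed
#' `|t_i|`.
#'
#' @param data A data frame with one row per observation.
#' @param value Unquoted measurement column.
#' @param group Unquoted group-label column.
#' @param control Label of the reference group.
#' @param n_mc Monte-Carlo draws for the null of the max statistic.
#' @param seed Integer seed (recorded in the result).
#' @return A `qus_dunnett` object; [tidy()] gives one row per non-control
#'   group with estimate, statistic, unadjusted and adjusted p.
#' @export
dunnett_test <- function(data, value, group, control, n_mc = 200000L,
                         seed = 1L) {
  y <- eval_tidy(enquo(value), data)
  g <- as.factor(eval_tidy(enquo(group), data))
  if (!control %in% levels(g)) {
    stop_cbi("control group '%s' not present.", control)
  }
  g <- stats::relevel(g, ref = control)
  k <- nlevels(g)
  if (k < 2L) stop_cbi("need at least 2 groups.")
  n_i <- tabulate(g)
  if (any(n_i < 2L)) stop_cbi("every group needs at least 2 observations.")
  m_i <- tapply(y, g, mean)
  n <- length(y)
  df <- n - k
  s2 <- sum((y - m_i[as.integer(g)])^2) / df
  if (s2 == 0) stop_cbi("zero pooled variance.")
  se <- sqrt(s2 * (1 / n_i[-1] + 1 / n_i[1]))
  est <- m_i[-1] - m_i[1]
  t_obs <- est / se
  p_unadj <- 2 * pt(-abs(t_obs), df)

  max_t_null <- withr::with_seed(as.integer(seed), {
    z0 <- rnorm(n_mc, 0, sqrt(1 / n_i[1]))
    s_null <- sqrt(rchisq(n_mc, df) / df)
    mt <- rep(0, n_mc)
    for (j in 2:k) {
      zj <- rnorm(n_mc, 0, sqrt(1 / n_i[j]))
      tj <- (zj - z0) / (s_null * sqrt(1 / n_i[j] + 1 / n_i[1]))
      mt <- pmax(mt, abs(tj))
    }
    mt
  })
  p_adj <- vapply(abs(t_obs), function(t0) mean(max_t_null >= t0), numeric(1))

  structure(
    list(comparison = levels(g)[-1], control = control,
         estimate = unname(est), statistic = unname(t_obs), df = df,
         p.unadjusted = unname(p_unadj), p.adjusted = unname(p_adj),
         n_mc = n_mc, seed = as.integer(seed)),
    class = "qus_dunnett"
  )
}

#' Pearson correlation with least-squares line
#'
#' Product-moment correlation between two columns, the least-squares slope
#' and intercept of `y` on `x`, and the two-sided p-value from the
#' t-transform of `r` with `n - 2` degrees of freedom.
#'
#' @param data A data frame.
#' @param x,y Unquoted column names.
#' @return A `qus_pearson` object; see [tidy()] / [glance()].
#' @export
pearson_correlation <- function(data, x, y) {
  xv <- eval_tidy(enquo(x), data)
  yv <- eval_tidy(enquo(y), data)
  if (length(xv) != length(yv)) stop_cbi("columns differ in length.")
  n <- length(xv)
  if (n < 3L) stop_cbi("need at least 3 observations.")
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    stop_cbi("constant input: correlation undefined.")
  }
  r <- sum((xv - mean(xv)) * (yv - mean(yv))) /
    ((n - 1) * stats::sd(xv) * stats::sd(yv))
  slope <- r * stats::sd(yv) / stats::sd(xv)
  intercept <- mean(yv) - slope * mean(xv)
  p <- if (abs(r) >= 1) 0 else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(t_stat), n - 2)
  }
  structure(
    list(r = r, p.value = p, slope = slope, intercept = intercept, n = n),
    class = "qus_pearson"
  )
}

#' @export
tidy.qus_paired_t <- function(x, ...) {
  tibble(estimate = x$mean_diff, statistic = x$statistic,
         p.value = x$p.value, parameter = x$df, sd_diff = x$sd_diff)
}

#' @export
glance.qus_paired_t <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p.value, df = x$df, n = x$n)
}

#' @export
tidy.qus_anova <- function(x, ...) {
  tibble(
    term = c("between", "within"),
    df = c(x$df_between, x$df_within),
    sumsq = c(x$ss_between, x$ss_within),
    meansq = c(x$ss_between / x$df_between, x$ss_within / x$df_within),
    statistic = c(x$statistic, NA_real_),
    p.value = c(x$p.value, NA_real_)
  )
}

#' @export
glance.qus_anova <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p.value,
         df_between = x$df_between, df_within = x$df_within, n = x$n)
}

#' @export
tidy.qus_dunnett <- function(x, ...) {
  tibble(comparison = paste(x$comparison, "-", x$control),
         estimate = x$estimate, statistic = x$statistic, df = x$df,
         p.value = x$p.unadjusted, adj.p.value = x$p.adjusted)
}

#' @export
glance.qus_dunnett <- function(x, ...) {
  tibble(n_comparisons = length(x$comparison), df = x$df, n_mc = x$n_mc,
         seed = x$seed)
}

#' @export
tidy.qus_pearson <- function(x, ...) {
  tibble(estimate = x$r, p.value = x$p.value, slope = x$slope,
         intercept = x$intercept, n = x$n)
}

#' @export
glance.qus_pearson <- function(x, ...) {
  tibble(r = x$r, r.squared = x$r^2, p.value = x$p.value, n = x$n)
}

#' @export
print.qus_paired_t <- function(x, ...) {
  cat(sprintf("Matched paired t-test: t(%d) = %.3f, p = %.4g\n",
              x$df, x$statistic, x$p.value))
  cat(sprintf("  mean difference %.4g (sd %.4g), n = %d\n",
              x$mean_diff, x$sd_diff, x$n))
  invisible(x)
}

#' @export
print.qus_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df_between, x$df_within, x$statistic, x$p.value))
  invisible(x)
}

#' @export
print.qus_dunnett <- function(x, ...) {
  cat(sprintf("Dunnett-type comparisons vs '%s' (Monte Carlo, %d draws):\n",
              x$control, x$n_mc))
  print(tidy(x))
  invisible(x)
}

#' @export
print.qus_pearson <- function(x, ...) {
  cat(sprintf("Pearson correlation: r = %.3f (p = %.4g, n = %d)\n",
              x$r, x$p.value, x$n))
  cat(sprintf("  least squares: y = %.4g + %.4g x\n", x$intercept, x$slope))
  invisible(x)
}
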