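#' Weighted log-rank test for two fully observed cohorts
#'
#' Standard weighted log-rank test over the union of distinct death times,
#' for data without censoring (every fly followed to death). At each
#' distinct time the observed minus expected deaths in group `a` is
#' accumulated with weight 1 (`"mantel-cox"`) or the total number at risk
#' (`"gehan-wilcoxon"`); the squared weighted sum over its hypergeometric
#' variance is referred to a chi-square distribution with 1 df. Ties are
#' handled by grouping events at identical times (discrete-time
#' treatment).
#'
#' @param a,b [survival_cohort()] objects (or bare numeric vectors of
#'   death times).
#' @param weighting `"mantel-cox"` (weight 1) or `"gehan-wilcoxon"`
#'   (weight = number at risk).
#' @return A list with `statistic` (chi-square, 1 df), `p`, and
#'   `weighting`. When all death times are identical across both groups
#'   the statistic is 0 and p is 1.
#' @examples
#' a <- survival_cohort(c(24, 36, 48), 12)
#' b <- survival_cohort(c(48, 60, 72), 12)
#' logrank_test(a, b)
#' @export
logrank_test <- function(a, b, weighting = c("mantel-cox", "gehan-wilcoxon")) {
  weighting <- match.arg(weighting)
  ta <- cohort_times(a)
  tb <- cohort_times(b)
  times <- sort(unique(c(ta, tb)))
  oe <- 0
  v <- 0
  for (t in times) {
    n1 <- sum(ta >= t)         # at risk in a
    n <- n1 + sum(tb >= t)     # at risk total
    d1 <- sum(ta == t)         # deaths in a at t
    d <- d1 + sum(tb == t)     # deaths total at t
    w <- if (weighting == "mantel-cox") 1 else n
    oe <- oe + w * (d1 - d * n1 / n)
    if (n > 1) {
      v <- v + w^2 * d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  if (v <= 0) {
    return(list(statistic = 0, p = 1, weighting = weighting))
  }
  stat <- oe^2 / v
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE),
       weighting = weighting)
}

cohort_times <- function(x) {
  if (inherits(x, "survival_cohort")) return(x$death_times)
  if (is.numeric(x) && length(x) >= 1L) return(as.numeric(x))
  stop_param("expected a survival_cohort or a non-empty numeric vector")
}

#' Wang-Allison maximum-lifespan test
#'
#' Tests whether two cohorts differ in the upper tail of their death-time
#' distributions. The pooled `quantile` death time (step-function, grid
#' quantile) defines a threshold; flies are cross-classified as group
#' versus surviving beyond the threshold, and the 2x2 table is tested with
#' a two-sided Fisher exact test (sum of hypergeometric table
#' probabilities not exceeding the observed table's).
#'
#' @param a,b [survival_cohort()] objects or numeric death-time vectors.
#' @param quantile Pooled quantile defining "maximum" lifespan
#'   (default 0.9, the time of 90% mortality).
#' @return A list with `threshold`, `table` (2x2 matrix, rows = groups,
#'   columns = beyond/within threshold), `p`, and `degenerate` (`TRUE`,
#'   with a warning, when a table margin is zero; `p` is then 1).
#' @examples
#' wang_allison_test(1:10, 11:20)
#' @export
wang_allison_test <- function(a, b, quantile = 0.9) {
  if (quantile <= 0 || quantile >= 1) {
    stop_param("quantile must lie strictly between 0 and 1")
  }
  ta <- cohort_times(a)
  tb <- cohort_times(b)
  thr <- grid_quantile(c(ta, tb), quantile)
  tab <- matrix(c(sum(ta > thr), sum(ta <= thr),
                  sum(tb > thr), sum(tb <= thr)),
                nrow = 2, byrow = TRUE,
                dimnames = list(group = c("a", "b"),
                                survival = c("beyond", "within")))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    warning("degenerate 2x2 table (zero margin); p set to 1", call. = FALSE)
    p <- 1
  } else {
    p <- fisher.test(tab)$p.value
  }
  list(threshold = thr, table = tab, p = min(p, 1), degenerate = degenerate)
}

#' Compare median and maximum lifespan between two cohorts
#'
#' Produces the comparison reported in lifespan studies of this design:
#' the medians and times of 90% mortality of both cohorts, their percent
#' differences (denominated by the experimental-group value), a log-rank
#' p-value for the survival curves (Mantel-Cox, with
#' Gehan-Breslow-Wilcoxon reported alongside since both appear in this
#' literature), and the Wang-Allison p-value for maximum lifespan.
#'
#' @param ctrl,exp [survival_cohort()] objects in the same time unit.
#' @param quantile Quantile defining maximum lifespan (default 0.9).
#' @return An object of class `lifespan_comparison` with fields `m_ctrl`,
#'   `m_exp`, `d_m` (percent), `t90_ctrl`, `t90_exp`, `d_90` (percent),
#'   `p_median` (Mantel-Cox), `p_median_gehan`, `p_max` (Wang-Allison),
#'   `wang_table`, `n_ctrl`, `n_exp`.
#' @export
compare_lifespan <- function(ctrl, exp, quantile = 0.9) {
  stopifnot(inherits(ctrl, "survival_cohort"), inherits(exp, "survival_cohort"))
  if (ctrl$unit != exp$unit) {
    stop_param("cohorts use different time units (%s vs %s)",
               ctrl$unit, exp$unit)
  }
  s_c <- summarize_cohort(ctrl)
  s_e <- summarize_cohort(exp)
  d_m <- if (s_e$median > 0) 100 * (s_e$median - s_c$median) / s_e$median else NA_real_
  d_90 <- if (s_e$t90 > 0) 100 * (s_e$t90 - s_c$t90) / s_e$t90 else NA_real_
  lr <- logrank_test(ctrl, exp, "mantel-cox")
  gw <- logrank_test(ctrl, exp, "gehan-wilcoxon")
  wa <- wang_allison_test(ctrl, exp, quantile = quantile)
  structure(
    list(m_ctrl = s_c$median, m_exp = s_e$median, d_m = d_m,
         t90_ctrl = s_c$t90, t90_exp = s_e$t90, d_90 = d_90,
         p_median = lr$p, p_median_gehan = gw$p,
         p_max = wa$p, wang_table = wa$table,
         n_ctrl = s_c$n, n_exp = s_e$n, unit = ctrl$unit),
    class = "lifespan_comparison")
}

#' @export
print.lifespan_comparison <- function(x, ...) {
  cat(sprintf("<lifespan_comparison> (%s)\n", x$unit))
  cat(sprintf("  median:  %g vs %g (dM = %+.1f%%), Mantel-Cox p = %.3g, Gehan-Wilcoxon p = %.3g\n",
              x$m_ctrl, x$m_exp, x$d_m, x$p_median, x$p_median_gehan))
  cat(sprintf("  t90:     %g vs %g (d90 = %+.1f%%), Wang-Allison p = %.3g\n",
              x$t90_ctrl, x$t90_exp, x$d_90, x$p_max))
  invisible(x)
}
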