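#' Pearson correlation between assay age and mean stress survival
#'
#' Quantifies the age-dependent decline of stress resistance: each point
#' is one assay age paired with the cohort's mean survival time under a
#' stressor, and the association is measured by the sample Pearson
#' correlation, with a two-sided p-value from the t statistic
#' `r * sqrt((n - 2) / (1 - r^2))` on n - 2 df.
#'
#' @param age_days Strictly increasing vector of assay ages (days).
#' @param mean_survival Mean survival times (hours), same length.
#' @return An object of class `correlation_result` with fields `r`, `n`,
#'   `p`.
#' @examples
#' age_survival_correlation(c(7, 14, 21), c(76, 60, 45))
#' @export
age_survival_correlation <- function(age_days, mean_survival) {
  if (is.data.frame(age_days) && missing(mean_survival)) {
    mean_survival <- age_days$mean_survival
    age_days <- age_days$age_days
  }
  n <- length(age_days)
  if (n < 3 || length(mean_survival) != n) {
    stop_param("need at least 3 (age, mean survival) pairs of equal length")
  }
  if (any(diff(age_days) <= 0)) {
    stop_param("ages must be strictly increasing")
  }
  if (length(unique(mean_survival)) == 1L) {
    stop_param("mean survival is constant; correlation is undefined")
  }
  ct <- cor.test(age_days, mean_survival, method = "pearson")
  structure(list(r = unname(ct$estimate), n = n, p = ct$p.value),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r = %.3f, n = %d, p = %.3g\n",
              x$r, x$n, x$p))
  invisible(x)
}

#' Compare two Pearson correlation coefficients (Fisher z)
#'
#' Tests whether two independent correlations differ, using the Fisher
#' transform `z = atanh(r)` which is approximately normal with variance
#' `1/(n - 3)`. The standardized difference
#' `(z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3))` yields a one-sided p as the
#' upper-tail normal probability of its absolute value (so equal
#' correlations give exactly 0.5); the two-sided p doubles it, capped
#' at 1.
#'
#' @param r1,r2 Correlations, strictly inside (-1, 1).
#' @param n1,n2 Sample sizes (>= 4, so the standard error is finite).
#' @param sided `"one"` (default) or `"two"`.
#' @return An object of class `correlation_comparison` with fields `z1`,
#'   `z2`, `se`, `z_stat`, `p`, `sided`.
#' @examples
#' compare_correlations(-0.944, 9, -0.968, 10)
#' @export
compare_correlations <- function(r1, n1, r2, n2, sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (n1 < 4 || n2 < 4) {
    stop_param("both sample sizes must be >= 4 (got %g, %g)", n1, n2)
  }
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    stop_param("correlations must lie strictly inside (-1, 1)")
  }
  z1 <- atanh(r1)
  z2 <- atanh(r2)
  se <- sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  z_stat <- (z1 - z2) / se
  p <- pnorm(abs(z_stat), lower.tail = FALSE)
  if (sided == "two") p <- min(1, 2 * p)
  structure(list(z1 = z1, z2 = z2, se = se, z_stat = z_stat,
                 p = p, sided = sided),
            class = "correlation_comparison")
}

#' @export
print.correlation_comparison <- function(x, ...) {
  cat(sprintf("<correlation_comparison> z = %.3f, %s-sided p = %.3g\n",
              x$z_stat, x$sided, x$p))
  invisible(x)
}

#' Pearson chi-square test for a contingency table of counts
#'
#' Plain Pearson chi-square without continuity correction, as used to
#' compare fecundity/fertility counts between genotypes. Zero margins are
#' rejected (the test is undefined there).
#'
#' @param counts An R x C matrix (or coercible) of non-negative counts,
#'   at least 2 x 2.
#' @return A list with `statistic`, `df`, `p`.
#' @examples
#' chi_square_counts(matrix(c(10, 10, 20, 0), 2, byrow = TRUE))
#' @export
chi_square_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop_param("need at least a 2 x 2 table")
  }
  if (any(counts < 0) || anyNA(counts)) {
    stop_param("counts must be non-negative and complete")
  }
  rz <- which(rowSums(counts) == 0)
  cz <- which(colSums(counts) == 0)
  if (length(rz)) stop_param("row %d has a zero margin", rz[1L])
  if (length(cz)) stop_param("column %d has a zero margin", cz[1L])
  ht <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}
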