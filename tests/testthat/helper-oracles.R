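# Independent oracles, deliberately coded along different routes than the
# package implementations they check.

# Weighted log-rank chi-square via explicit risk sets and the
# product-form hypergeometric variance n1*n2*d*(n-d) / (n^2*(n-1)).
naive_weighted_logrank <- function(ta, tb, weighting) {
  all_t <- sort(unique(c(ta, tb)))
  num <- 0
  den <- 0
  for (t in all_t) {
    n1 <- length(ta[ta >= t])
    n2 <- length(tb[tb >= t])
    n <- n1 + n2
    d <- sum(ta == t) + sum(tb == t)
    w <- if (weighting == "mantel-cox") 1 else n
    num <- num + w * (sum(ta == t) - n1 * d / n)
    if (n > 1) den <- den + w^2 * n1 * n2 * d * (n - d) / (n^2 * (n - 1))
  }
  if (den <= 0) return(0)
  num^2 / den
}

# Two-sided Fisher exact p by full enumeration of hypergeometric tables
# with the observed margins.
enumerate_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ])
  r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  xs <- max(0, c1 - r2):min(c1, r1)
  probs <- dhyper(xs, r1, r2, c1)
  p_obs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Random census-grid cohort for property tests.
random_cohort <- function(n, census = 12, max_units = 12) {
  survival_cohort(census * sample.int(max_units, n, replace = TRUE),
                  census_interval = census)
}
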