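#' Generate stress-survival cohorts across assay ages
#'
#' Draws one cohort per assay age. Latent death times follow the
#' scenario's distribution (exponential by default) with mean
#' `baseline_mean_survival * genotype_effect^[overexpression] *
#' sex_effect^[female] * (1 - decline_rate)^(age - min(ages))`,
#' then are rounded UP to the next census-interval multiple (a death seen
#' at a census is known only to have occurred since the previous one) and
#' capped at the scenario's maximum duration.
#'
#' @param scenario A [stress_scenario()].
#' @param ages Strictly increasing assay ages in days (default the
#'   standard 7, 14, ..., 70 day series).
#' @param n_per_cohort Flies per age cohort (default 150, i.e. five vials
#'   of 30).
#' @param seed Integer seed; identical (scenario, seed) gives identical
#'   output.
#' @param genotype,sex Which experimental variant to generate; the
#'   scenario's genotype/sex effects apply to `"overexpression"` and
#'   `"female"` respectively.
#' @return A list of [survival_cohort()] objects, one per age, in hours.
#' @export
gen_stress_cohorts <- function(scenario,
                               ages = seq(7, 70, by = 7),
                               n_per_cohort = 150,
                               seed = 1L,
                               genotype = c("control", "overexpression"),
                               sex = c("male", "female")) {
  stopifnot(inherits(scenario, "stress_scenario"))
  genotype <- match.arg(genotype)
  sex <- match.arg(sex)
  if (length(ages) < 1L || any(diff(ages) <= 0)) {
    stop_param("ages must be a non-empty strictly increasing vector")
  }
  if (n_per_cohort < 1) stop_param("n_per_cohort must be >= 1")
  ci <- scenario$census_interval
  cap <- scenario$max_duration
  with_seed(seed, {
    lapply(ages, function(age) {
      scale <- scenario$baseline_mean_survival *
        (if (genotype == "overexpression") scenario$genotype_effect else 1) *
        (if (sex == "female") scenario$sex_effect else 1) *
        (1 - scenario$decline_rate)^(age - min(ages))
      x <- switch(scenario$distribution,
        exponential = rexp(n_per_cohort, rate = 1 / scale),
        weibull = {
          shape <- scenario$weibull_shape
          rweibull(n_per_cohort, shape = shape,
                   scale = scale / gamma(1 + 1 / shape))
        })
      t <- pmin(snap_up(x, ci), cap)
      survival_cohort(t, ci, stress = scenario$stress_name, sex = sex,
                      genotype = genotype, age_days = age, unit = "hours")
    })
  })
}

#' Generate a paired control/overexpression lifespan experiment
#'
#' Draws Gompertz death times by inverse-CDF sampling: with hazard
#' `a * exp(b * t)`, the survival function is
#' `S(t) = exp(-(a/b) (exp(b t) - 1))`, so `t = log1p(-(b/a) log U) / b`
#' for uniform U (reducing to exponential draws when b = 0). The second
#' group's baseline hazard is multiplied by the scenario's
#' `genotype_effect`. Times are rounded up to the daily census grid.
#'
#' @param scenario A [lifespan_scenario()].
#' @param seed Integer seed.
#' @return A list with elements `control` and `overexpression`, each a
#'   [survival_cohort()] in days.
#' @export
gen_lifespan_cohorts <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "lifespan_scenario"))
  a <- scenario$gompertz_a
  b <- scenario$gompertz_b
  n <- scenario$n_per_group
  ci <- scenario$census_interval
  draw <- function(haz_a) {
    u <- runif(n)
    t <- if (b == 0) -log(u) / haz_a else log1p(-(b / haz_a) * log(u)) / b
    snap_up(t, ci)
  }
  with_seed(seed, {
    ctrl <- draw(a)
    over <- draw(a * scenario$genotype_effect)
    list(
      control = survival_cohort(ctrl, ci, stress = "none", sex = "male",
                                genotype = "control", age_days = 0,
                                unit = "days"),
      overexpression = survival_cohort(over, ci, stress = "none",
                                       sex = "male",
                                       genotype = "overexpression",
                                       age_days = 0, unit = "days"))
  })
}
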