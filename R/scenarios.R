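#' Scenario describing an acute stress-survival assay
#'
#' Parameterizes the synthetic generator for stress-resistance cohorts:
#' flies of a given age are exposed to a stressor (paraquat, CuSO4, CdCl2,
#' NaCl, ...) and followed to death, with deaths recorded at twice-daily
#' censuses. Mean survival declines multiplicatively with the age at which
#' the assay starts.
#'
#' Defaults are calibrated to the scale of published paraquat assays in
#' this design: roughly 80 h mean survival at the youngest age, about a 3%
#' loss of survival scale per day of age, a modest survival advantage for
#' the overexpression genotype and slightly lower female survival, on a
#' 12-hour census grid.
#'
#' @param stress_name Label of the stressor.
#' @param baseline_mean_survival Mean survival (hours) at the youngest
#'   assayed age for control males.
#' @param decline_rate Proportional reduction of the survival scale per day
#'   of age (0 < rate < 1 gives decline; 0 means no ageing effect).
#' @param genotype_effect Multiplicative survival-scale factor applied to
#'   the overexpression genotype (> 1 means longer-surviving).
#' @param sex_effect Multiplicative survival-scale factor applied to
#'   females.
#' @param census_interval Census spacing in hours (default 12: deaths
#'   counted twice a day).
#' @param max_duration Longest recordable survival time (hours); must be a
#'   multiple of `census_interval`.
#' @param distribution Death-time distribution on the latent (continuous)
#'   scale: `"exponential"` (default) or `"weibull"`.
#' @param weibull_shape Shape parameter when `distribution = "weibull"`.
#' @return An object of class `stress_scenario`.
#' @seealso [gen_stress_cohorts()]
#' @export
stress_scenario <- function(stress_name = "paraquat",
                            baseline_mean_survival = 80,
                            decline_rate = 0.03,
                            genotype_effect = 1.1,
                            sex_effect = 0.9,
                            census_interval = 12,
                            max_duration = 240,
                            distribution = c("exponential", "weibull"),
                            weibull_shape = 2) {
  distribution <- match.arg(distribution)
  if (baseline_mean_survival <= 0) {
    stop_param("baseline_mean_survival must be > 0 (got %g)",
               baseline_mean_survival)
  }
  if (decline_rate < 0 || decline_rate >= 1) {
    stop_param("decline_rate must lie in [0, 1) (got %g)", decline_rate)
  }
  if (genotype_effect <= 0) stop_param("genotype_effect must be > 0")
  if (sex_effect <= 0) stop_param("sex_effect must be > 0")
  if (census_interval <= 0) stop_param("census_interval must be > 0")
  if (max_duration < census_interval ||
      !is_grid_multiple(max_duration, census_interval)) {
    stop_param("max_duration must be a positive multiple of census_interval")
  }
  if (weibull_shape <= 0) stop_param("weibull_shape must be > 0")
  structure(
    list(stress_name = stress_name,
         baseline_mean_survival = baseline_mean_survival,
         decline_rate = decline_rate,
         genotype_effect = genotype_effect,
         sex_effect = sex_effect,
         census_interval = census_interval,
         max_duration = max_duration,
         distribution = distribution,
         weibull_shape = weibull_shape),
    class = "stress_scenario")
}

#' Scenario describing a lifespan assay
#'
#' Parameterizes Gompertz lifespan cohorts for a control and an
#' overexpression group observed on a daily census grid. The Gompertz
#' hazard is `a * exp(b * t)`; the overexpression group's hazard is scaled
#' by `genotype_effect` (< 1 means protective, longer-lived).
#'
#' Defaults put the control median near 50 days and, with
#' `genotype_effect = 0.3`, the overexpression median near 65 days —
#' the magnitudes reported for neuronal Gclc overexpression — with about
#' 400 flies per group.
#'
#' @param gompertz_a Baseline hazard per day (> 0).
#' @param gompertz_b Hazard growth rate per day (>= 0; 0 gives exponential
#'   lifespans).
#' @param genotype_effect Multiplicative hazard factor for the second
#'   (overexpression) group.
#' @param n_per_group Flies per group (>= 2).
#' @param census_interval Census spacing in days (default 1: daily counts).
#' @return An object of class `lifespan_scenario`.
#' @seealso [gen_lifespan_cohorts()]
#' @export
lifespan_scenario <- function(gompertz_a = 0.00105,
                              gompertz_b = 0.08,
                              genotype_effect = 0.3,
                              n_per_group = 400,
                              census_interval = 1) {
  if (gompertz_a <= 0) stop_param("gompertz_a must be > 0")
  if (gompertz_b < 0) stop_param("gompertz_b must be >= 0")
  if (genotype_effect <= 0) stop_param("genotype_effect must be > 0")
  if (n_per_group < 2) stop_param("n_per_group must be >= 2")
  if (census_interval <= 0) stop_param("census_interval must be > 0")
  structure(
    list(gompertz_a = gompertz_a, gompertz_b = gompertz_b,
         genotype_effect = genotype_effect,
         n_per_group = as.integer(n_per_group),
         census_interval = census_interval),
    class = "lifespan_scenario")
}

#' Scenario describing a gene-level differential-expression table
#'
#' Stands in for the output of a differential-expression fit: per-gene log2
#' fold-changes with lognormal absolute-expression weights (CPM). A fixed
#' fraction of genes is exactly null (logFC 0); the allocation is exact,
#' not binomial.
#'
#' Defaults mirror the scale of a fly head transcriptome after low-count
#' filtering: 9400 genes, about 65% unaffected, unit spread of true
#' effects, and CPM weights spanning several orders of magnitude.
#'
#' @param n_genes Number of genes (>= 1).
#' @param logfc_effect_sd Standard deviation of non-null log2 fold-changes.
#' @param cpm_log_mean,cpm_log_sd Meanlog/sdlog of the lognormal CPM
#'   weights.
#' @param fraction_null Proportion of genes with logFC exactly 0.
#' @return An object of class `expression_scenario`.
#' @seealso [gen_gene_stats()]
#' @export
expression_scenario <- function(n_genes = 9400,
                                logfc_effect_sd = 1,
                                cpm_log_mean = 2,
                                cpm_log_sd = 1.5,
                                fraction_null = 0.65) {
  if (n_genes < 1) stop_param("n_genes must be >= 1 (got %g)", n_genes)
  if (logfc_effect_sd < 0) stop_param("logfc_effect_sd must be >= 0")
  if (cpm_log_sd < 0) stop_param("cpm_log_sd must be >= 0")
  if (fraction_null < 0 || fraction_null > 1) {
    stop_param("fraction_null must lie in [0, 1]")
  }
  structure(
    list(n_genes = as.integer(n_genes),
         logfc_effect_sd = logfc_effect_sd,
         cpm_log_mean = cpm_log_mean, cpm_log_sd = cpm_log_sd,
         fraction_null = fraction_null),
    class = "expression_scenario")
}

#' Scenario describing a Drosophila Activity Monitor recording
#'
#' Parameterizes synthetic DAM beam-break traces: `days_ld` days under a
#' 12:12 light-dark cycle followed by `days_dd` days of constant darkness,
#' with a sinusoidal expected activity
#' `mesor + amplitude * cos(2*pi*(ZT - peak_zt)/period)` counts per minute
#' and negative-binomial (or Poisson) count noise.
#'
#' The default regime (2 LD days then 6 DD days) matches the standard
#' circadian protocol for ageing flies; `peak_zt = 12` places the activity
#' peak at lights-off, where the evening peak of *D. melanogaster* falls.
#'
#' @param n_channels Number of occupied monitor channels (1-32).
#' @param days_ld,days_dd Days under light:dark cycling and constant
#'   darkness.
#' @param mesor Mean activity level, counts per minute.
#' @param amplitude Sinusoid amplitude, counts per minute; must not exceed
#'   `mesor` so expected counts stay non-negative.
#' @param peak_zt Zeitgeber time (hours) of peak expected activity.
#' @param period Rhythm period in hours (default 24).
#' @param noise_dispersion Negative-binomial overdispersion of per-minute
#'   counts (variance `mu + noise_dispersion * mu^2`); 0 gives Poisson.
#' @param acquisition_interval Minutes per reading (default 1).
#' @return An object of class `activity_scenario`.
#' @seealso [gen_dam_file()]
#' @export
activity_scenario <- function(n_channels = 10,
                              days_ld = 2,
                              days_dd = 6,
                              mesor = 1,
                              amplitude = 0.8,
                              peak_zt = 12,
                              period = 24,
                              noise_dispersion = 0.5,
                              acquisition_interval = 1) {
  if (n_channels < 1 || n_channels > 32) {
    stop_param("n_channels must lie in 1..32 (got %g)", n_channels)
  }
  if (days_ld < 0 || days_dd < 0 || days_ld + days_dd < 1) {
    stop_param("days_ld + days_dd must be >= 1")
  }
  if (mesor < 0) stop_param("mesor must be >= 0")
  if (amplitude < 0 || amplitude > mesor) {
    stop_param("amplitude must lie in [0, mesor] so counts are non-negative in expectation")
  }
  if (period <= 0) stop_param("period must be > 0")
  if (noise_dispersion < 0) stop_param("noise_dispersion must be >= 0")
  if (acquisition_interval <= 0 || 1440 %% acquisition_interval != 0) {
    stop_param("acquisition_interval must be a positive divisor of 1440 minutes")
  }
  structure(
    list(n_channels = as.integer(n_channels),
         days_ld = as.integer(days_ld), days_dd = as.integer(days_dd),
         mesor = mesor, amplitude = amplitude, peak_zt = peak_zt,
         period = period, noise_dispersion = noise_dispersion,
         acquisition_interval = as.integer(acquisition_interval)),
    class = "activity_scenario")
}
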