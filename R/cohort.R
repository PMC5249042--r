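#' Construct a survival cohort observed on a census grid
#'
#' A cohort is a set of flies of one experimental variant (stress, sex,
#' genotype, age at assay start) followed until death, with every death
#' time recorded at a census. Death times must therefore be positive
#' multiples of the census interval. No censoring is supported: the assay
#' protocol follows every fly to death, and censored inputs are rejected
#' rather than silently mishandled.
#'
#' @param death_times Numeric vector of death times (all on the census
#'   grid), in `unit`.
#' @param census_interval Census spacing, in `unit`.
#' @param stress Stressor label, or `"none"` for lifespan assays.
#' @param sex `"male"` or `"female"`.
#' @param genotype `"control"` or `"overexpression"`.
#' @param age_days Age (days) at assay start; 0 for lifespan assays.
#' @param unit Time unit of `death_times`: `"hours"` or `"days"`.
#' @return An object of class `survival_cohort`.
#' @examples
#' survival_cohort(c(12, 24, 24, 36), census_interval = 12)
#' @export
survival_cohort <- function(death_times,
                            census_interval,
                            stress = "none",
                            sex = c("male", "female"),
                            genotype = c("control", "overexpression"),
                            age_days = 0,
                            unit = c("hours", "days")) {
  sex <- match.arg(sex)
  genotype <- match.arg(genotype)
  unit <- match.arg(unit)
  if (length(death_times) < 1L) {
    stop_param("a survival cohort needs at least one death time")
  }
  if (anyNA(death_times)) {
    stop_param("death_times contain NA; censored or missing observations are not supported")
  }
  if (census_interval <= 0) stop_param("census_interval must be > 0")
  off <- !is_grid_multiple(death_times, census_interval)
  if (any(off)) {
    stop_param("death time %g is not a positive multiple of the census interval %g",
               death_times[which(off)[1L]], census_interval)
  }
  structure(
    list(stress = stress, sex = sex, genotype = genotype,
         age_days = age_days,
         death_times = as.numeric(death_times),
         census_interval = census_interval,
         unit = unit,
         n = length(death_times)),
    class = "survival_cohort")
}

#' @export
print.survival_cohort <- function(x, ...) {
  cat(sprintf(
    "<survival_cohort> %s / %s / %s, age %g d: n = %d, census every %g %s\n",
    x$stress, x$sex, x$genotype, x$age_days, x$n, x$census_interval, x$unit))
  invisible(x)
}

#' Summarize a survival cohort (mean, SEM, median, time of 90% mortality)
#'
#' Computes the census-grid summary used throughout this package: the
#' arithmetic mean with its standard error, the median survival time M,
#' and the time of 90% mortality ("maximum" survival). Quantiles are
#' step-function quantiles on the census grid — the smallest census time
#' at which the cumulative death fraction reaches the target — with no
#' interpolation, so both M and t90 are always grid multiples.
#'
#' @param cohort A [survival_cohort()].
#' @return An object of class `cohort_summary` with fields `mean`, `sem`,
#'   `median`, `t90`, `n` and `unit`.
#' @examples
#' co <- survival_cohort(c(12, 12, 24, 24, 24, 36, 36, 48, 48, 60), 12)
#' summarize_cohort(co)
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "survival_cohort"))
  x <- cohort$death_times
  n <- length(x)
  structure(
    list(mean = mean(x),
         sem = if (n > 1) sd(x) / sqrt(n) else NA_real_,
         median = grid_quantile(x, 0.5),
         t90 = grid_quantile(x, 0.9),
         n = n,
         unit = cohort$unit),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> X = %.1f +/- %.1f, M = %g, 90%% = %g (%s; n = %d)\n",
              x$mean, x$sem, x$median, x$t90, x$unit, x$n))
  invisible(x)
}

#' Write survival cohorts to a TSV file
#'
#' One row per fly with columns `stress`, `sex`, `genotype`, `age_days`,
#' `fly_id`, `death_time_h`. Times are always stored in hours; cohorts
#' recorded in days (lifespan assays) are converted on write.
#'
#' @param cohorts A `survival_cohort` or a list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_tsv <- function(cohorts, path) {
  if (inherits(cohorts, "survival_cohort")) cohorts <- list(cohorts)
  rows <- lapply(cohorts, function(co) {
    f <- if (co$unit == "days") 24 else 1
    data.frame(stress = co$stress, sex = co$sex, genotype = co$genotype,
               age_days = co$age_days,
               fly_id = seq_along(co$death_times),
               death_time_h = co$death_times * f)
  })
  tab <- do.call(rbind, rows)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read survival cohorts from a TSV file
#'
#' Inverse of [write_cohort_tsv()]: rows are grouped into one cohort per
#' (stress, sex, genotype, age) combination. All times are in hours.
#'
#' @param path Input TSV path with the columns written by
#'   [write_cohort_tsv()].
#' @param census_interval Census spacing in hours; if `NULL`, inferred as
#'   the greatest common divisor of all death times.
#' @return A list of [survival_cohort()] objects.
#' @export
read_cohort_tsv <- function(path, census_interval = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("stress", "sex", "genotype", "age_days", "fly_id", "death_time_h")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop_param("cohort TSV is missing required column(s): %s",
               paste(miss, collapse = ", "))
  }
  if (is.null(census_interval)) census_interval <- vec_gcd(tab$death_time_h)
  key <- interaction(tab$stress, tab$sex, tab$genotype, tab$age_days,
                     drop = TRUE, lex.order = TRUE)
  lapply(split(tab, key), function(g) {
    survival_cohort(g$death_time_h, census_interval,
                    stress = g$stress[1L], sex = g$sex[1L],
                    genotype = g$genotype[1L], age_days = g$age_days[1L],
                    unit = "hours")
  })
}
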