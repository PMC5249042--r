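# DAM monitor files use English month abbreviations; month.abb is
# locale-independent, so dates are formatted/parsed by hand rather than
# through strftime.
dam_format_date <- function(day_offset, origin = c(2024L, 1L, 1L)) {
  d <- as.Date(sprintf("%04d-%02d-%02d", origin[1], origin[2], origin[3])) +
    day_offset
  lt <- as.POSIXlt(d)
  sprintf("%02d %s %02d", lt$mday, month.abb[lt$mon + 1L],
          (lt$year + 1900L) %% 100L)
}

dam_parse_date <- function(s) {
  parts <- strsplit(s, " ", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 3L) return(NA_real_)
    mon <- match(p[2L], month.abb)
    if (is.na(mon)) return(NA_real_)
    yy <- as.integer(p[3L])
    as.numeric(as.Date(sprintf("%04d-%02d-%02d", 2000L + yy, mon,
                               as.integer(p[1L]))))
  }, numeric(1))
}

#' Write a synthetic Drosophila Activity Monitor file
#'
#' Emits a TriKinetics-dialect text file: one tab-separated line per
#' acquisition interval with a reading index, date (`DD Mon YY`), time
#' (`HH:MM:SS`), a status code (1 = valid data), six reserved fields and
#' 32 per-channel beam-break counts. Recording starts at lights-on
#' (08:00:00) and covers `days_ld + days_dd` full days. Expected activity
#' per minute follows
#' `mesor + amplitude * cos(2*pi*(ZT - peak_zt)/period)`; counts are
#' negative-binomial with the scenario's overdispersion (Poisson when 0).
#' Channels beyond `n_channels` read 0.
#'
#' @param scenario An [activity_scenario()].
#' @param seed Integer seed; identical (scenario, seed) yields a
#'   byte-identical file.
#' @param path Output file path.
#' @return Invisibly, a list with the written counts matrix (`counts`,
#'   readings x 32), `interval` (minutes) and `lights_on` (`"08:00:00"`).
#' @export
gen_dam_file <- function(scenario, seed = 1L, path) {
  stopifnot(inherits(scenario, "activity_scenario"))
  iv <- scenario$acquisition_interval
  n_days <- scenario$days_ld + scenario$days_dd
  n_read <- n_days * 1440L %/% iv
  # ZT hours at the midpoint-free start of each reading; recording starts
  # at ZT 0, so ZT just accumulates (DD continues the prior LD phase).
  zt_h <- (seq_len(n_read) - 1L) * iv / 60
  mu_min <- scenario$mesor + scenario$amplitude *
    cos(2 * pi * (zt_h - scenario$peak_zt) / scenario$period)
  mu <- pmax(mu_min, 0) * iv
  counts <- with_seed(seed, {
    m <- matrix(0L, nrow = n_read, ncol = 32L)
    for (ch in seq_len(scenario$n_channels)) {
      m[, ch] <- if (scenario$noise_dispersion > 0) {
        rnbinom(n_read, mu = mu, size = 1 / scenario$noise_dispersion)
      } else {
        rpois(n_read, lambda = mu)
      }
    }
    m
  })
  minute <- (seq_len(n_read) - 1L) * iv
  clock_min <- (8L * 60L + minute) %% 1440L
  day_off <- (8L * 60L + minute) %/% 1440L
  lines <- paste(
    seq_len(n_read),
    dam_format_date(day_off),
    sprintf("%02d:%02d:00", clock_min %/% 60L, clock_min %% 60L),
    1L,
    paste(rep("0", 6L), collapse = "\t"),
    apply(counts, 1L, paste, collapse = "\t"),
    sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(list(counts = counts, interval = iv, lights_on = "08:00:00"))
}
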