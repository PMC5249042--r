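# Global ZT minute of each reading (minute 0 = the lights-on at or before
# the first reading); day index and within-day position follow from it.
zt_minutes <- function(series) {
  offset <- (series$clock0_min - series$lights_on_min) %% 1440
  offset + (seq_along(series$values) - 1) * series$interval
}

#' Re-bin an activity series
#'
#' Aggregates consecutive readings into coarser bins by summation (beam
#' breaks are events, so bins add); total activity is conserved. A bin is
#' valid only if all member readings are.
#'
#' @param series An [activity_series()].
#' @param bin_minutes Target bin width; must be a multiple of the
#'   series interval and divide 1440.
#' @return An [activity_series()] at the new interval.
#' @export
bin_series <- function(series, bin_minutes) {
  stopifnot(inherits(series, "activity_series"))
  k <- bin_minutes / series$interval
  if (bin_minutes <= 0 || k != round(k) || 1440 %% bin_minutes != 0) {
    stop_param("bin_minutes (%g) must be a multiple of the interval (%d) and divide 1440",
               bin_minutes, series$interval)
  }
  k <- as.integer(k)
  n <- length(series$values)
  if (n %% k != 0) {
    stop_param("series length %d is not a whole number of %g-minute bins",
               n, bin_minutes)
  }
  g <- rep(seq_len(n %/% k), each = k)
  activity_series(
    values = as.numeric(tapply(series$values, g, sum)),
    interval = bin_minutes,
    channel_id = series$channel_id,
    clock0_min = series$clock0_min,
    lights_on_min = series$lights_on_min,
    valid = as.logical(tapply(series$valid, g, all)))
}

# Per-series matrix of complete, fully valid ZT days: rows = days,
# columns = bins of bin_minutes. Incomplete days and days containing an
# invalid reading are dropped.
complete_day_matrix <- function(series, bin_minutes) {
  gz <- zt_minutes(series)
  day <- gz %/% 1440
  within <- gz %% 1440
  per_day <- 1440 %/% series$interval
  keep_days <- Filter(function(d) {
    idx <- which(day == d)
    length(idx) == per_day && all(series$valid[idx])
  }, unique(day))
  if (length(keep_days) == 0L) return(NULL)
  bins_per_day <- 1440 %/% bin_minutes
  mat <- t(vapply(keep_days, function(d) {
    idx <- which(day == d)
    idx <- idx[order(within[idx])]
    v <- series$values[idx]
    as.numeric(tapply(v, rep(seq_len(bins_per_day),
                             each = bin_minutes %/% series$interval), sum))
  }, numeric(bins_per_day)))
  rownames(mat) <- paste0("day", keep_days + 1)
  mat
}

#' Average daily activity profile across flies (ZT-aligned)
#'
#' Builds the mean activity per bin over all complete days of all flies,
#' aligned to zeitgeber time (ZT 0 = lights-on; during constant darkness
#' circadian time simply continues the prior light-dark phase). Days with
#' any invalid reading, and incomplete days, are excluded. Also returns
#' per-fly, per-day total activity; totals equal the sum of the
#' underlying bins.
#'
#' @param group A list of [activity_series()] sharing interval and
#'   lights schedule (e.g. from [read_dam()]).
#' @param bin_minutes Profile bin width in minutes (default 10).
#' @return An object of class `activity_profile`: `bin_minutes`,
#'   `profile` (mean counts per bin, length `1440 / bin_minutes`, named
#'   by ZT bin start in hours), and `daily_totals` (data.frame with
#'   `channel_id`, `day`, `total`).
#' @export
daily_profile <- function(group, bin_minutes = 10) {
  if (inherits(group, "activity_series")) group <- list(group)
  if (length(group) == 0L) stop_param("empty group of activity series")
  iv <- unique(vapply(group, function(s) s$interval, numeric(1)))
  lo <- unique(vapply(group, function(s) s$lights_on_min, numeric(1)))
  if (length(iv) != 1L || length(lo) != 1L) {
    stop_param("all series must share acquisition interval and lights-on time")
  }
  mats <- list()
  totals <- list()
  for (s in group) {
    m <- complete_day_matrix(s, bin_minutes)
    if (is.null(m)) next
    mats[[length(mats) + 1L]] <- m
    totals[[length(totals) + 1L]] <- data.frame(
      channel_id = s$channel_id, day = rownames(m), total = rowSums(m))
  }
  if (length(mats) == 0L) {
    stop_param("no complete valid day in any series")
  }
  all_days <- do.call(rbind, mats)
  profile <- colMeans(all_days)
  names(profile) <- sprintf("ZT%g", (seq_along(profile) - 1) *
                              bin_minutes / 60)
  daily_totals <- do.call(rbind, totals)
  rownames(daily_totals) <- NULL
  structure(list(bin_minutes = bin_minutes, profile = profile,
                 daily_totals = daily_totals),
            class = "activity_profile")
}

#' @export
print.activity_profile <- function(x, ...) {
  cat(sprintf("<activity_profile> %d bins of %g min over %d fly-days; peak at %s\n",
              length(x$profile), x$bin_minutes, nrow(x$daily_totals),
              names(x$profile)[which.max(x$profile)]))
  invisible(x)
}

#' Actogram matrix of one fly's activity
#'
#' Rasterizes a series into a days-by-bins matrix of bin sums over
#' complete ZT days, the layout actogram plots draw. With
#' `double_plot = TRUE` each row shows day d followed by day d + 1 (the
#' conventional double-plotted actogram); the last row repeats the final
#' day.
#'
#' @param series An [activity_series()].
#' @param bin_minutes Bin width in minutes (default 10).
#' @param double_plot Concatenate consecutive days per row?
#' @return A numeric matrix, days x bins (days x 2*bins when
#'   double-plotted).
#' @export
actogram_matrix <- function(series, bin_minutes = 10, double_plot = FALSE) {
  stopifnot(inherits(series, "activity_series"))
  m <- complete_day_matrix(series, bin_minutes)
  if (is.null(m)) stop_param("series has no complete valid day")
  if (!double_plot) return(m)
  d <- nrow(m)
  nxt <- c(seq_len(d)[-1L], d)  # last row padded with the final day
  cbind(m, m[nxt, , drop = FALSE])
}
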