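#' A per-channel activity series
#'
#' Internal constructor for one monitor channel's beam-break counts at a
#' constant acquisition interval, together with the clock time of the
#' first reading and the lights-on time that anchors zeitgeber time
#' (ZT 0). `valid` flags readings whose monitor status was the valid-data
#' code; invalid readings are excluded from statistics, never silently
#' zeroed.
#'
#' @param values Non-negative counts per interval.
#' @param interval Minutes per reading; must divide 1440.
#' @param channel_id Channel label.
#' @param clock0_min Clock minutes (0-1439) of the first reading.
#' @param lights_on_min Clock minutes of lights-on (ZT 0).
#' @param valid Logical vector flagging valid readings.
#' @return An object of class `activity_series`.
#' @export
activity_series <- function(values, interval, channel_id = "ch01",
                            clock0_min = 480, lights_on_min = 480,
                            valid = rep(TRUE, length(values))) {
  if (any(values < 0, na.rm = TRUE)) stop_param("activity counts must be >= 0")
  if (interval <= 0 || 1440 %% interval != 0) {
    stop_param("interval must be a positive divisor of 1440 minutes")
  }
  if (length(valid) != length(values)) {
    stop_param("valid must have one flag per reading")
  }
  structure(list(channel_id = channel_id,
                 interval = as.integer(interval),
                 values = as.numeric(values),
                 clock0_min = clock0_min %% 1440,
                 lights_on_min = lights_on_min %% 1440,
                 valid = valid),
            class = "activity_series")
}

#' @export
print.activity_series <- function(x, ...) {
  cat(sprintf("<activity_series> %s: %d readings at %d min (%d invalid)\n",
              x$channel_id, length(x$values), x$interval, sum(!x$valid)))
  invisible(x)
}

parse_clock_min <- function(s) {
  p <- strsplit(s, ":", fixed = TRUE)
  vapply(p, function(h) as.numeric(h[1L]) * 60 + as.numeric(h[2L]) +
           as.numeric(h[3L]) / 60, numeric(1))
}

#' Read a Drosophila Activity Monitor text file
#'
#' Parses the TriKinetics-style dialect written by [gen_dam_file()]: 42
#' tab-separated fields per line (index, date, time, status, six reserved
#' fields, 32 counts) at a constant acquisition interval. Lines whose
#' status differs from `valid_status` are kept but flagged invalid, so
#' downstream statistics can exclude them explicitly.
#'
#' @param path Input file path.
#' @param lights_on Clock time of lights-on defining ZT 0
#'   (default `"08:00:00"`).
#' @param valid_status Monitor status code marking valid data
#'   (default 1).
#' @return A list of 32 [activity_series()], one per channel.
#' @export
read_dam <- function(path, lights_on = "08:00:00", valid_status = 1L) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop_param("empty DAM file: %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 42L)
  if (length(bad)) {
    stop_param("line %d has %d fields; expected 42 (index, date, time, status, 6 reserved, 32 counts)",
               bad[1L], nf[bad[1L]])
  }
  m <- do.call(rbind, fields)
  status <- as.integer(m[, 4L])
  day_num <- dam_parse_date(m[, 2L])
  if (anyNA(day_num)) {
    stop_param("unparseable date on line %d: '%s'",
               which(is.na(day_num))[1L], m[which(is.na(day_num))[1L], 2L])
  }
  clock <- parse_clock_min(m[, 3L])
  t_min <- day_num * 1440 + clock
  if (length(t_min) > 1L) {
    dt <- diff(t_min)
    if (any(dt <= 0)) {
      stop_param("timestamps are not strictly increasing at line %d",
                 which(dt <= 0)[1L] + 1L)
    }
    if (length(unique(round(dt, 6))) != 1L) {
      stop_param("acquisition interval is not constant (line %d)",
                 which(dt != dt[1L])[1L] + 1L)
    }
    interval <- dt[1L]
  } else {
    interval <- 1
  }
  counts <- matrix(as.numeric(m[, 11:42]), ncol = 32L)
  if (any(is.na(counts))) stop_param("non-numeric count field in DAM file")
  valid <- status == valid_status
  lights_on_min <- parse_clock_min(lights_on)
  stem <- tools::file_path_sans_ext(basename(path))
  lapply(seq_len(32L), function(ch) {
    activity_series(counts[, ch], interval = interval,
                    channel_id = sprintf("%s#%02d", stem, ch),
                    clock0_min = clock[1L], lights_on_min = lights_on_min,
                    valid = valid)
  })
}
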