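make_series <- function(values, interval = 10, clock0 = 480,
                        lights_on = 480, valid = rep(TRUE, length(values))) {
  activity_series(values, interval, clock0_min = clock0,
                  lights_on_min = lights_on, valid = valid)
}

test_that("DAM files have the documented shape and round-trip", {
  sc <- activity_scenario(n_channels = 2, days_ld = 1, days_dd = 0,
                          noise_dispersion = 0.2)
  path <- withr::local_tempfile(fileext = ".txt")
  gen <- gen_dam_file(sc, seed = 12, path = path)
  lines <- readLines(path)
  expect_length(lines, 1440L)
  expect_length(strsplit(lines[1], "\t")[[1]], 42L)

  series <- read_dam(path)
  expect_length(series, 32L)
  for (ch in 1:2) expect_equal(series[[ch]]$values, gen$counts[, ch])
  expect_true(all(series[[3]]$values == 0))  # unoccupied channel

  # identical scenario and seed give a byte-identical file
  path2 <- withr::local_tempfile(fileext = ".txt")
  gen_dam_file(sc, seed = 12, path = path2)
  expect_identical(unname(tools::md5sum(path)), unname(tools::md5sum(path2)))
})

test_that("the DAM reader rejects malformed input with line numbers", {
  sc <- activity_scenario(n_channels = 1, days_ld = 1, days_dd = 0)
  path <- withr::local_tempfile(fileext = ".txt")
  gen_dam_file(sc, seed = 3, path = path)
  lines <- readLines(path)

  ragged <- withr::local_tempfile()
  broken <- lines
  broken[7] <- paste(strsplit(lines[7], "\t")[[1]][1:41], collapse = "\t")
  writeLines(broken, ragged)
  expect_error(read_dam(ragged), "line 7")

  swapped <- withr::local_tempfile()
  writeLines(lines[c(1, 3, 2, 4:20)], swapped)
  expect_error(read_dam(swapped), "strictly increasing")
})

test_that("binning sums counts and conserves totals", {
  s <- make_series(rep(1, 1440), interval = 1)
  b <- bin_series(s, 10)
  expect_length(b$values, 144L)
  expect_true(all(b$values == 10))
  expect_equal(sum(b$values), sum(s$values))

  set.seed(5)
  r <- make_series(rpois(1440, 2), interval = 1)
  expect_equal(sum(bin_series(r, 30)$values), sum(r$values))
  expect_error(bin_series(r, 7), "divide 1440")
  expect_error(bin_series(make_series(rep(1, 30), interval = 10), 5),
               "multiple of the interval")
})

test_that("daily profiles average complete ZT days across flies", {
  set.seed(8)
  day <- rpois(1440, 1.5)
  one <- make_series(day, interval = 1)
  p1 <- daily_profile(one, bin_minutes = 10)
  expect_equal(as.numeric(p1$profile), bin_series(one, 10)$values)
  expect_equal(sum(p1$daily_totals$total), sum(day))

  # two identical flies: profile equals either one
  p2 <- daily_profile(list(one, one), bin_minutes = 10)
  expect_equal(p2$profile, p1$profile)
  expect_equal(nrow(p2$daily_totals), 2L)

  # totals conservation over complete days only
  extra <- make_series(c(day, day[1:720]), interval = 1)
  pe <- daily_profile(extra, bin_minutes = 10)
  expect_equal(sum(pe$daily_totals$total), sum(day))

  expect_error(daily_profile(list()), "empty group")
})

test_that("a day containing an invalid reading is dropped", {
  day <- rep(2, 1440)
  valid <- rep(TRUE, 2880)
  valid[200] <- FALSE
  s <- make_series(c(day, day * 3), interval = 1, valid = valid)
  p <- daily_profile(s, bin_minutes = 60)
  expect_equal(nrow(p$daily_totals), 1L)
  expect_true(all(p$profile == 6 * 60))
})

test_that("profiles are ZT-aligned and rotate with lights-on", {
  sc <- activity_scenario(n_channels = 1, days_ld = 2, days_dd = 2,
                          mesor = 5, amplitude = 4, noise_dispersion = 0)
  path <- withr::local_tempfile(fileext = ".txt")
  gen_dam_file(sc, seed = 77, path = path)
  s <- read_dam(path)[[1]]
  prof <- daily_profile(s, bin_minutes = 10)

  # phase recovery: circular mean of the profile within 1 h of peak_zt
  zt_h <- (seq_along(prof$profile) - 0.5) * prof$bin_minutes / 60
  ang <- 2 * pi * zt_h / 24
  phase <- atan2(sum(prof$profile * sin(ang)), sum(prof$profile * cos(ang)))
  phase_h <- (phase / (2 * pi) * 24) %% 24
  expect_lt(min(abs(phase_h - sc$peak_zt), 24 - abs(phase_h - sc$peak_zt)),
            1)

  # shifting lights-on by +3 h rotates a day-periodic profile by 18 bins
  pattern <- round(10 * (5 + 4 * cos(2 * pi * ((0:1439) / 60 - 12) / 24)))
  base <- make_series(rep(pattern, 4), interval = 1)
  shift3 <- make_series(rep(pattern, 4), interval = 1, lights_on = 660)
  pb <- unname(daily_profile(base, 10)$profile)
  ps <- unname(daily_profile(shift3, 10)$profile)
  expect_equal(ps, c(pb[-(1:18)], pb[1:18]), tolerance = 1e-9)
})

test_that("zero-amplitude traces yield flat profiles", {
  sc <- activity_scenario(n_channels = 4, days_ld = 2, days_dd = 2,
                          mesor = 2, amplitude = 0, noise_dispersion = 0)
  path <- withr::local_tempfile(fileext = ".txt")
  gen_dam_file(sc, seed = 9, path = path)
  prof <- daily_profile(read_dam(path)[1:4], bin_minutes = 60)
  # Poisson mean 2/min, 60-min bins averaged over 16 fly-days: SE ~ 2.7
  expect_lt(max(prof$profile) - min(prof$profile), 12)
})

test_that("actogram matrices have the documented layout", {
  set.seed(2)
  v <- rpois(2880, 1)
  s <- make_series(v, interval = 1)
  m <- actogram_matrix(s, bin_minutes = 10)
  expect_equal(dim(m), c(2L, 144L))
  expect_equal(unname(rowSums(m)),
               c(sum(v[1:1440]), sum(v[1441:2880])))

  d <- actogram_matrix(s, bin_minutes = 10, double_plot = TRUE)
  expect_equal(dim(d), c(2L, 288L))
  expect_equal(d[1, 145:288], m[2, ])  # row 1 continues into day 2
  expect_equal(d[2, 145:288], m[2, ])  # last row padded with final day
})
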