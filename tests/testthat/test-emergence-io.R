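test_that("series read/write round-trips bit-exactly, including NA tokens", {
  path <- withr::local_tempfile(fileext = ".csv")
  counts <- c(0, 5, NA, 3, 12, NA, NA, 0, 7, 1)
  s <- emergence_series(counts, bin_width = 24, start_index = 0,
                        label = "rep2020")
  write_series(list(rep2020 = s), path)
  back <- read_series(path, "daily")
  expect_identical(names(back), "rep2020")
  expect_identical(back$rep2020$counts, as.numeric(counts))
  expect_identical(back$rep2020$start_index, 0)
  expect_identical(back$rep2020$bin_width, 24)
  # second round trip is byte-identical
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_series(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("reader validates counts and indices and handles dialects", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("day,a", "0,1", "1,-1"), path)
  expect_error(read_series(path, "daily"), "negative")
  writeLines(c("day,a", "0,1", "2,4", "1,2"), path)
  expect_error(read_series(path, "daily"), "increasing")
  # tab dialect, NaN and empty cells as missing, gap days become NA
  writeLines(c("hour\tx", "1\t3", "2\tNaN", "3\t", "5\t2"), path)
  s <- read_series(path, "hourly")$x
  expect_identical(s$counts, c(3, NA, NA, NA, 2))
  expect_identical(s$bin_width, 1)
})

test_that("regime sidecar attaches light regimes to series columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  s <- emergence_series(c(1, 2, 3), 24, 0)
  write_series(list(a = s, b = s), path)
  write_regime_sidecar(list(a = light_regime(26), default = light_regime(24)),
                       path)
  back <- read_series(path, "daily")
  expect_equal(back$a$regime$cycle_length_T, 26)
  expect_equal(back$b$regime$cycle_length_T, 24)
})

test_that("events are credited to the solar day of the preceding lights-off", {
  # T = 24: one dark onset per day (hour 12, 36, 60, ...); the census
  # events just after each lights-off map to days identically
  ev <- data.frame(time = c(12.5, 36.9, 60.0), count = c(2L, 1L, 4L))
  s24 <- assign_to_solar_days(ev, light_regime(24), 4)
  expect_identical(s24$counts, c(2, 1, 4, 0))

  # T = 26, lights-on at 0: dark onsets at 13, 39, 65, 91, 117, 143, 169
  # fall on solar days 0,1,2,3,4,5,7 -> day 6 carries no information
  ev <- data.frame(time = c(13, 39, 65, 91, 117, 143, 169) + 0.5,
                   count = rep(1L, 7))
  s26 <- assign_to_solar_days(ev, light_regime(26), 8)
  expect_identical(which(is.na(s26$counts)), 7L)  # day 6 (1-based 7)
  expect_identical(s26$counts[-7], rep(1, 7))

  # T = 30: dark onsets 15, 45, 75, 105 -> days 0,1,3,4: day 2 masked
  s30 <- assign_to_solar_days(data.frame(time = numeric(), count = integer()),
                              light_regime(30), 5)
  expect_identical(which(is.na(s30$counts)), 3L)

  expect_error(assign_to_solar_days(ev, light_regime(mode = "LL"), 5),
               "unsupported")
})

test_that("day assignment conserves events and masks exactly the onset-free days", {
  set.seed(11)
  for (T in c(22, 26, 28, 30)) {
    reg <- light_regime(T)
    n_days <- 40
    # census events just after lights-off, like the counting protocol
    onsets <- seq(T / 2, n_days * 24 - 24, by = T)
    ev <- data.frame(time = sort(sample(onsets, 60, TRUE)) + runif(60, 0, 1),
                     count = sample(1:3, 60, TRUE))
    s <- assign_to_solar_days(ev, reg, n_days)
    expect_equal(sum(s$counts, na.rm = TRUE), sum(ev$count))
    all_onsets <- seq(T / 2, n_days * 24, by = T)
    expected_mask <- setdiff(0:(n_days - 1), floor(all_onsets / 24))
    expect_identical(which(is.na(s$counts)) - 1L, as.integer(expected_mask))
  }
})

test_that("the semilunar window is always exactly 82 days, padded when short", {
  s <- cosine_series(141, 15, start_index = 0)
  w <- window_semilunar(s)
  expect_length(w$counts, 82)
  expect_identical(w$start_index, 31)
  expect_identical(w$counts[1], s$counts[32])
  # 100-day input (days 0-99): days 100-112 masked
  s100 <- cosine_series(100, 15, start_index = 0)
  w100 <- window_semilunar(s100)
  expect_length(w100$counts, 82)
  expect_identical(which(is.na(w100$counts)), 70:82)
  expect_error(window_semilunar(cosine_series(60, 15, start_index = 40)),
               "starts after")
})

test_that("ZT alignment maps mid-dark to ZT 0 and conserves counts", {
  # LD 12:12, lights-on at 0: dark 12-24, mid-dark 18
  counts <- integer(48); counts[19] <- 7  # all emergence at absolute hour 18
  s <- emergence_series(counts, bin_width = 1, start_index = 0)
  z <- zt_align(s, light_regime(24))
  expect_equal(which(z$counts > 0), 1L)   # hour 18 -> ZT 0
  expect_equal(sum(z$counts), sum(s$counts))
  expect_identical(z$alignment, "zeitgeber_time")
  expect_identical(zt_align(z), z)        # already aligned: identity
  expect_error(zt_align(emergence_series(1:5, 24, 0), light_regime(24)),
               "hourly")
})

test_that("hourly profiles fold correctly and conserve the grand total", {
  # all emergence at ZT 18 -> single nonzero profile element at 18
  counts <- integer(30 * 24)
  counts[which((0:(30 * 24 - 1)) %% 24 == 18)] <- 5L
  s <- emergence_series(counts, bin_width = 1, start_index = 0)
  prof <- hourly_profile(s, 24)
  expect_equal(unname(which(prof > 0)), 19L)
  expect_equal(sum(prof), sum(counts))
  # uniform counts -> flat profile
  u <- emergence_series(rep(2L, 240), 1, 0)
  expect_true(all(hourly_profile(u, 24) == 20))
  # one nightly peak per 24 h: folding at 24 is unimodal, at 12 collapsed
  prof12 <- hourly_profile(s, 12)
  expect_equal(sum(prof12 > 0), 1L)  # 18 mod 12 = 6: peak collapses onto 6
  expect_equal(sum(prof12), sum(prof))
  expect_error(hourly_profile(s, 0), "positive")
})

test_that("series constructor enforces the count contract", {
  expect_error(emergence_series(c(1, -1, 2), 24, 0), "non-negative")
  expect_error(emergence_series(c(1, 2.5), 24, 0), "integers")
  expect_silent(emergence_series(rep(0, 82), 24, 0))  # all-zero is valid
})
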