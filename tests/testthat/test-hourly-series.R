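test_that("cleaning marks zero and negative values invalid and counts them", {
  raw <- series_from_values(c(0, -1.2, 5))
  cl <- clean_series(raw)
  expect_equal(cl$series$value[cl$series$valid], 5)
  expect_equal(cl$report$n_null_deleted, 1L)
  expect_equal(cl$report$n_negative_deleted, 1L)
  expect_equal(cl$report$n_missing, 2L)
  expect_equal(cl$report$n_valid, 1L)

  ok <- series_from_values(c(1.5, 2.5, 3.5))
  cl2 <- clean_series(ok)
  expect_equal(cl2$series$value, ok$value)
  expect_equal(cl2$report$n_null_deleted, 0L)
  expect_equal(cl2$report$n_negative_deleted, 0L)
})

test_that("cleaning removes 29 February and keeps the grid rectangular", {
  raw <- hourly_series(rep(10, 8784), start = "2020-01-01 00:00:00")
  cl <- clean_series(raw)
  expect_equal(length(cl$series), 8760L)
  cal <- series_calendar(cl$series)
  expect_false(any(cal$month == 2 & cal$day == 29))
  # invalid slots stay as slots, they are not removed
  raw2 <- series_from_values(c(3, 0, 4))
  expect_equal(length(clean_series(raw2)$series), 3L)
})

test_that("cleaning is idempotent", {
  spec <- series_spec(n_years = 1, start_year = 2020, seed = 2)
  raw <- generate_hourly_series(spec)
  raw$value[c(5, 100)] <- 0
  raw$value[300] <- -2
  once <- clean_series(raw)$series
  twice <- clean_series(once)
  expect_equal(twice$series, once)
  expect_equal(twice$report$n_null_deleted, 0L)
  expect_true(all(once$value[once$valid] > 0))
})

test_that("malformed calendar indexes are rejected", {
  expect_error(hourly_series(1:3, time = as.POSIXct(
    c("2019-01-01 00:00:00", "2019-01-01 00:30:00", "2019-01-01 01:00:00"),
    tz = "UTC")), "whole hours")
  expect_error(hourly_series(1:2, time = as.POSIXct(
    c("2019-01-01 01:00:00", "2019-01-01 01:00:00"), tz = "UTC")),
    "strictly increasing")
})

test_that("gap runs are maximal, ordered, and cover all invalid positions", {
  s <- series_from_values(c(1, NA, NA, 2, NA, 3))
  runs <- find_gap_runs(s)
  expect_equal(runs$start, c(2L, 5L))
  expect_equal(runs$length, c(2L, 1L))

  expect_equal(nrow(find_gap_runs(series_from_values(c(1, 2, 3)))), 0L)
  all_na <- series_from_values(rep(NA_real_, 7))
  expect_equal(find_gap_runs(all_na), data.frame(start = 1L, length = 7L))

  set.seed(31)
  for (i in 1:20) {
    v <- ifelse(runif(200) < 0.3, NA_real_, runif(200) + 1)
    if (all(is.na(v))) v[1] <- 1
    s <- series_from_values(v)
    runs <- find_gap_runs(s)
    expect_equal(sum(runs$length), sum(!s$valid))
    # runs are flanked by valid slots where in range
    for (j in seq_len(nrow(runs))) {
      a <- runs$start[j]; b <- a + runs$length[j] - 1L
      if (a > 1) expect_true(s$valid[a - 1])
      if (b < length(s)) expect_true(s$valid[b + 1])
    }
  }
})

test_that("grouping views partition the valid values", {
  arch <- test_archive()
  w <- group_view(arch, "two_hour_block")
  expect_length(w, 12L)
  expect_named(w, sprintf("W%d", 1:12))
  z <- group_view(arch, "weekday")
  expect_length(z, 7L)
  x <- group_view(arch, "year")
  expect_length(x, 6L)
  for (g in list(w, z, x))
    expect_equal(sum(lengths(g)), sum(arch$valid))

  one_year <- clean_series(generate_hourly_series(
    series_spec(n_years = 1, seed = 3)))$series
  expect_length(group_view(one_year, "year"), 1L)
  expect_error(group_view(arch, "fortnight"))
})

test_that("moving average is centered over valid values", {
  const <- series_from_values(rep(4.2, 100))
  expect_equal(moving_average(const, 10), rep(4.2, 100))

  s <- series_from_values(1:10 + 0)
  expect_equal(moving_average(s, 1), 1:10 + 0)
  ma3 <- moving_average(s, 3)
  # ends keep 2 of 3 window slots (>= 50% valid), so they are reported
  expect_equal(ma3, c(1.5, 2:9, 9.5))

  gappy <- series_from_values(c(1, NA, 3, 4, 5))
  ma <- moving_average(gappy, 3)
  expect_equal(ma[2], 2)          # mean of the two valid neighbours
  expect_error(moving_average(s, 0), "positive")
})

test_that("outlier rule is one-sided above Q3 + 1.5 IQR", {
  expect_equal(flag_outliers(c(1, 2, 3, 4, 100)),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_false(any(flag_outliers(rep(7, 10))))
  expect_false(any(flag_outliers(c(-100, 1, 2, 3, 4))))
  expect_error(flag_outliers(c(1, 2, 3)), "4")
})

test_that("pollution categories partition [0, Inf) as half-open bands", {
  expect_equal(as.character(classify_level(24.9)), "desirable")
  expect_equal(as.character(classify_level(25)), "acceptable")
  expect_equal(as.character(classify_level(350)), "emergency")
  expect_equal(as.character(classify_level(c(0, 49.99, 50, 149.9, 150,
                                             249.9, 250, 349.9))),
               c("desirable", "acceptable", "caution", "caution", "alert",
                 "alert", "alarm", "alarm"))
  set.seed(8)
  v <- c(runif(500, 0, 400), 0, 25, 50, 150, 250, 350, 1e6)
  lv <- classify_level(v)
  expect_false(anyNA(lv))         # exhaustive
  expect_error(classify_level(-1), "non-negative")
})

test_that("even/odd splitting is a bijection on positions", {
  x <- 0:8191 + 0
  subs <- split_subsequences(x)
  expect_named(subs, c("E1", "E2", "O1", "O2"))
  expect_true(all(lengths(subs) == 2048L))
  expect_equal(subs$E1[1:4], c(0, 2, 4, 6))
  expect_equal(subs$O1[1:4], c(1, 3, 5, 7))
  expect_equal(subs$E2[1], 4096)

  # round trip through the position map
  pos <- attr(subs, "positions")
  rebuilt <- numeric(8192)
  for (nm in names(subs)) rebuilt[pos[[nm]]] <- subs[[nm]]
  expect_identical(rebuilt, x)
  expect_equal(sort(unlist(subs)), sort(x), ignore_attr = TRUE)

  const <- split_subsequences(rep(2.5, 8192))
  expect_true(all(vapply(const, function(s) all(s == 2.5), logical(1))))
  expect_error(split_subsequences(1:100), "8192")
  bad <- 0:8191 + 0; bad[5] <- NA
  expect_error(split_subsequences(bad), "missing")
})

test_that("hourly CSV round-trips through files", {
  s <- series_from_values(c(1.5, NA, 3.25))
  f <- withr::local_tempfile(fileext = ".csv")
  write_hourly_csv(s, f)
  back <- read_hourly_csv(f)
  expect_equal(back$value, s$value)
  expect_equal(back$valid, s$valid)
  expect_equal(as.numeric(back$time), as.numeric(s$time))
})
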