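# Shared fixtures, built in code. The six-year archive mirrors the study
# layout: five donor years plus the year under analysis, cleaned to 8760
# slots per year.
.fixtures <- new.env(parent = emptyenv())

test_archive <- function(seed = 7) {
  key <- paste0("arch", seed)
  if (is.null(.fixtures[[key]])) {
    spec <- series_spec(n_years = 6, start_year = 2015, seed = seed)
    .fixtures[[key]] <- clean_series(generate_hourly_series(spec))$series
  }
  .fixtures[[key]]
}

# A smooth low-noise archive: pronounced diurnal cycle, almost no noise.
# Used where interpolation accuracy itself is under test.
smooth_archive <- function(seed = 11) {
  key <- paste0("smooth", seed)
  if (is.null(.fixtures[[key]])) {
    spec <- series_spec(n_years = 6, start_year = 2015, tail_sigma = 0.05,
                        outlier_rate = 0, seed = seed)
    .fixtures[[key]] <- clean_series(generate_hourly_series(spec))$series
  }
  .fixtures[[key]]
}

# Interior anchor hour in the last year, with 5 full prior years behind it.
interior_slot <- function(archive) {
  as.POSIXct("2020-06-15 12:00:00", tz = "UTC")
}

series_from_values <- function(values, start = "2019-03-01 00:00:00") {
  hourly_series(values, start = start)
}
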