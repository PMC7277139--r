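test_that("synthetic meteorology is reproducible bit-for-bit per seed", {
  a <- generate_synthetic_meteo(seed = 42, n_hours = 200)
  b <- generate_synthetic_meteo(seed = 42, n_hours = 200)
  expect_identical(a, b)
  c <- generate_synthetic_meteo(seed = 43, n_hours = 200)
  expect_false(identical(a$wind_direction, c$wind_direction))
})

test_that("generated series respects the record contract", {
  m <- generate_synthetic_meteo(seed = 3, n_hours = 500)
  expect_equal(nrow(m), 500)
  expect_true(all(m$wind_speed >= 0))
  expect_true(all(m$wind_direction >= 0 & m$wind_direction < 360))
  expect_true(all(m$stability_class %in% LETTERS[1:6]))
  expect_true(all(diff(as.numeric(m$timestamp)) == 3600))
  expect_no_error(validate_meteo(m))
})

test_that("zero direction spread pins every record to the prevailing wind", {
  m <- generate_synthetic_meteo(seed = 9, n_hours = 50,
                                prevailing_from_direction = 315,
                                direction_spread = 0)
  expect_true(all(m$wind_direction == 315))
})

test_that("circular mean of a long wrapped-normal draw recovers the prevailing direction", {
  m <- generate_synthetic_meteo(seed = 1, n_hours = 10000,
                                prevailing_from_direction = 315,
                                direction_spread = 30)
  mu <- circular_mean(m$wind_direction)
  delta <- abs(((mu - 315 + 180) %% 360) - 180)
  expect_lt(delta, 2)
})

test_that("degenerate generator arguments are rejected", {
  expect_error(generate_synthetic_meteo(seed = 1, n_hours = 0), "n_hours")
  expect_error(generate_synthetic_meteo(seed = 1, n_hours = 10,
                                        stability_weights = rep(0, 6)),
               "stability_weights")
  expect_error(generate_synthetic_meteo(seed = 1, n_hours = 10,
                                        speed_mean = 0), "speed_mean")
})

test_that("meteorology CSV round-trips every field", {
  m <- generate_synthetic_meteo(seed = 5, n_hours = 24)
  path <- withr::local_tempfile(fileext = ".csv")
  write_meteo_csv(m, path)
  m2 <- read_meteo_csv(path)
  expect_equal(m2$timestamp, m$timestamp)
  expect_equal(m2$wind_speed, m$wind_speed, tolerance = 1e-12)
  expect_equal(m2$wind_direction, m$wind_direction, tolerance = 1e-12)
  expect_identical(m2$stability_class, m$stability_class)
})

test_that("malformed meteorology files are rejected with the offending row", {
  m <- generate_synthetic_meteo(seed = 5, n_hours = 24)
  dup <- m; dup$timestamp[10] <- dup$timestamp[9]
  expect_error(validate_meteo(dup), "duplicated hour.*2017-01-01 08:00")
  gap <- m[-10, ]
  expect_error(validate_meteo(gap), "non-hourly gap.*row 9")
  bad <- m; bad$wind_direction[3] <- 360
  expect_error(validate_meteo(bad), "wind_direction.*row 3")
  expect_error(validate_meteo(m[, -2]), "missing column")
})

test_that("wind rose concentrates a constant wind into one sector", {
  m <- tibble::tibble(wind_direction = rep(315, 40))
  rose <- wind_rose(m, n_sectors = 16)
  expect_equal(sum(rose$frequency), 1)
  expect_equal(rose$frequency[rose$centre_deg == 315], 1)
  expect_equal(sum(rose$frequency > 0), 1)
})

test_that("wind rose of a uniform direction sweep is flat", {
  m <- tibble::tibble(wind_direction = 0:359)
  rose <- wind_rose(m, n_sectors = 8)
  expect_equal(rose$frequency, rep(0.125, 8))
})

test_that("wind-rose frequencies always form a probability distribution", {
  for (seed in 1:5) {
    m <- generate_synthetic_meteo(seed = seed, n_hours = 123,
                                  direction_spread = 120)
    rose <- wind_rose(m, n_sectors = 12)
    expect_true(all(rose$frequency >= 0))
    expect_equal(sum(rose$frequency), 1)
  }
})

test_that("wind rose rejects empty series and bad sector counts", {
  expect_error(wind_rose(tibble::tibble(wind_direction = numeric(0))), "empty")
  expect_error(wind_rose(tibble::tibble(wind_direction = 1), n_sectors = 7.5),
               "whole number")
  expect_error(wind_rose(tibble::tibble(wind_direction = 1), n_sectors = 2),
               ">= 4")
})
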