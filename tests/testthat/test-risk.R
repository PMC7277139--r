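test_that("LADD matches hand evaluation of the dose equation", {
  f <- default_exposure_factors()
  child <- f[f$group == "0-9", ]
  # 99 days at 1 mg/kg: 99 * 8e-5 / (13.3 * 30186)
  expect_equal(compute_ladd(rep(1, 120), 99, child),
               99 * 8e-5 / (13.3 * 30186), tolerance = 1e-12)
  expect_equal(compute_ladd(rep(1, 120), 99, child), 1.973e-8, tolerance = 1e-3)
  expect_equal(compute_ladd(rep(0, 50), 50, child), 0)
})

test_that("loop-summed dose equals the closed form on random series", {
  f <- default_exposure_factors()
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(5:60, 1)
    series <- rlnorm(n, 0, 1)
    ed <- sample(n, 1)
    row <- f[sample(4, 1), ]
    loop <- 0
    for (d in seq_len(ed)) {
      loop <- loop + series[d] * row$soil_intake_kg /
        (row$body_weight_kg * row$lifetime_days)
    }
    expect_equal(compute_ladd(series, ed, row), loop, tolerance = 1e-12)
  }
})

test_that("days beyond the endpoint never influence the dose", {
  f <- default_exposure_factors()[1, ]
  series <- runif(30)
  garbage <- c(series[1:20], rep(1e9, 10))
  expect_equal(compute_ladd(series, 20, f), compute_ladd(garbage, 20, f))
  expect_error(compute_ladd(series, 31, f), "exceeds the soil series length")
  expect_error(compute_ladd(series, 0, f), ">= 1")
})

test_that("ECR is the CSF-scaled dose", {
  expect_equal(compute_ecr(0, 0.17), 0)
  expect_equal(compute_ecr(2.5e-4, 1), 2.5e-4)
  # inverting the printed child maximum: 3.57e-5 / 0.17 gives the dose back
  expect_equal(compute_ecr(3.57e-5 / 0.17, 0.17), 3.57e-5)
  expect_error(compute_ecr(-1, 0.17), "non-negative")
})

test_that("zone classification honours the regulatory thresholds and ties", {
  expect_equal(classify_zone(c(2e-6, 5e-7, 5e-8, 0)),
               c("red", "orange", "green", "green"))
  expect_equal(classify_zone(1e-6), "red")      # tie at the limit is red
  expect_equal(classify_zone(1e-7), "orange")
  expect_error(classify_zone(-1e-9), "non-negative")
  expect_error(classify_zone(1e-6, red_threshold = 1e-8), "decreasing")
})

test_that("a four-cell toy grid partitions into the expected zone percentages", {
  soil <- array(0, c(2, 2, 1))
  soil[, , 1] <- matrix(c(2e-6, 5e-7, 5e-8, 0), 2, 2)
  h <- fake_history(soil = soil, nx = 2, ny = 2)
  a <- assess(h, 1, factors = identity_factors(), csf = 1)
  s <- a$maps[[1]]$summary
  expect_equal(s$pct_red, 25)
  expect_equal(s$pct_orange, 25)
  expect_equal(s$pct_green, 50)
})

test_that("zone percentages always partition exactly 100", {
  fx <- make_fixture(seed = 4, horizon_days = 3)
  h <- run_simulation(fx$scenario, fx$meteo)
  a <- assess(h, 2)
  for (m in a$maps) {
    expect_equal(m$summary$pct_red + m$summary$pct_orange +
                   m$summary$pct_green, 100, tolerance = 1e-12)
    expect_lte(m$summary$mean_ecr, m$summary$max_ecr)
  }
})

test_that("cross-group ECR fields differ by the exact intake/body-weight scalar", {
  fx <- make_fixture(seed = 5, horizon_days = 3)
  h <- run_simulation(fx$scenario, fx$meteo)
  a <- assess(h, 3)
  f <- default_exposure_factors()
  for (i in 1:3) for (j in (i + 1):4) {
    ratio <- (f$soil_intake_kg[i] / f$body_weight_kg[i]) /
      (f$soil_intake_kg[j] / f$body_weight_kg[j])
    expect_equal(a$maps[[i]]$ecr, a$maps[[j]]$ecr * ratio, tolerance = 1e-12)
    expect_equal(a$maps[[i]]$summary$max_ecr,
                 a$maps[[j]]$summary$max_ecr * ratio, tolerance = 1e-12)
  }
})

test_that("group maxima order by intake-per-body-weight as in the study table", {
  fx <- make_fixture(seed = 6, horizon_days = 2)
  h <- run_simulation(fx$scenario, fx$meteo)
  s <- tidy(assess(h, 2), digits = 6)
  expect_gt(s$max_ecr[s$group == "0-9"], s$max_ecr[s$group == "10-18"])
  expect_lt(s$max_ecr[s$group == "19-65"], s$max_ecr[s$group == ">65"])
  expect_gt(s$mean_ecr[s$group == "0-9"], max(s$mean_ecr[s$group != "0-9"]))
})

test_that("risk scales linearly with the soil history", {
  soil <- array(runif(3 * 3 * 4), c(3, 3, 4))
  h1 <- fake_history(soil = soil)
  h2 <- fake_history(soil = soil * 7)
  a1 <- assess(h1, 4, factors = identity_factors(), csf = 0.17)
  a2 <- assess(h2, 4, factors = identity_factors(), csf = 0.17)
  expect_equal(a2$maps[[1]]$ecr, 7 * a1$maps[[1]]$ecr, tolerance = 1e-12)
  expect_equal(a2$maps[[1]]$ladd, 7 * a1$maps[[1]]$ladd, tolerance = 1e-12)
})

test_that("an all-zero history yields zero risk everywhere and all-green maps", {
  h <- fake_history(soil = array(0, c(3, 3, 2)))
  a <- assess(h, 2)
  for (m in a$maps) {
    expect_equal(m$summary$max_ecr, 0)
    expect_equal(m$summary$mean_ecr, 0)
    expect_equal(m$summary$pct_green, 100)
  }
})

test_that("assess validates its inputs", {
  h <- fake_history(soil = array(0, c(3, 3, 2)))
  expect_error(assess(h, 5), "1..n_days")
  expect_error(assess(h, 1, factors = default_exposure_factors()[0, ]), "empty")
  expect_error(exposure_factors(character(0), numeric(0), numeric(0),
                                numeric(0)), "empty")
  expect_error(exposure_factors("a", -1, 10, 10), "positive")
})

test_that("the exposure-factor CSV shipped with the package matches the defaults", {
  path <- system.file("extdata", "exposure_factors.csv", package = "chemrisk")
  expect_equal(read_exposure_factors_csv(path), default_exposure_factors(),
               ignore_attr = TRUE)
})
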