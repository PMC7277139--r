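test_that("dispersion coefficients match the power-law table recomputed by hand", {
  # sigma_y(D, 1 km) = 68 * 1^0.894; sigma_z(D, 1 km) = 33.2 * 1^0.725 - 1.7
  s <- pg_sigmas("D", 1000)
  expect_equal(s$sigma_y, 68)
  expect_equal(s$sigma_z, 31.5)
  # far branch by hand: sigma_y(F, 2 km) = 34 * 2^0.894
  expect_equal(pg_sigmas("F", 2000)$sigma_y, 34 * 2^0.894)
})

test_that("dispersion coefficients order by stability and grow with distance", {
  x <- 1000
  expect_gt(pg_sigmas("A", x)$sigma_y, pg_sigmas("F", x)$sigma_y)
  expect_gt(pg_sigmas("A", x)$sigma_z, pg_sigmas("F", x)$sigma_z)
  for (cl in LETTERS[1:6]) {
    d <- c(100, 300, 1000, 2000, 8000)
    sy <- pg_sigmas(cl, d)$sigma_y
    sz <- pg_sigmas(cl, d)$sigma_z
    expect_true(all(diff(sy) > 0))
    expect_true(all(diff(sz) >= 0))
    expect_true(all(sy > 0) && all(sz > 0))
  }
  expect_error(pg_sigmas("G", 100), "unknown stability")
  expect_error(pg_sigmas("D", 0), "positive")
})

test_that("a single calm puff reproduces the closed-form kernel to 1e-9", {
  grid <- grid_spec(nx = 5, ny = 5, dx = 100, dy = 100, mixing_height = 10,
                    source_cell = c(3, 3))
  chem <- chemical_properties("inert", 100, deposition_velocity = 0)
  p <- new_puff(10, x = 250, y = 250, sigma0 = 80)
  st <- step_hour(list(p), list(wind_speed = 0, wind_direction = 0,
                                stability_class = "D"),
                  chem, grid, deposition = FALSE)
  # independent closed form at each cell centre
  cx <- (1:5 - 0.5) * 100
  expected <- outer(cx, cx, function(yy, xx) {
    r2 <- (xx - 250)^2 + (yy - 250)^2
    10 * 1e6 * exp(-r2 / (2 * 80^2)) / (2 * pi * 80^2 * 10)
  })
  expect_equal(st$air_field, expected, tolerance = 1e-9)
  # radial symmetry about the central cell and exact mass conservation
  expect_equal(st$air_field, t(st$air_field), tolerance = 1e-12)
  expect_equal(st$air_field[, 1], st$air_field[, 5], tolerance = 1e-12)
  expect_equal(st$puffs[[1]]$mass_kg, 10, tolerance = 1e-9)
  expect_equal(st$decayed_kg + st$deposited_kg + st$exported_kg, 0)
})

test_that("advection carries the plume toward direction + 180", {
  grid <- grid_spec(nx = 30, ny = 30, dx = 100, dy = 100,
                    source_cell = c(10, 20))
  chem <- chemical_properties("inert", 100, deposition_velocity = 0)
  p <- new_puff(5, x = 950, y = 1950, sigma0 = 30)
  st <- step_hour(list(p), list(wind_speed = 0.5, wind_direction = 315,
                                stability_class = "D"),
                  chem, grid, deposition = FALSE)
  ij <- which(st$air_field == max(st$air_field), arr.ind = TRUE)
  expect_gt(ij[1, "col"], 10)   # east of source
  expect_lt(ij[1, "row"], 20)   # south of source
})

test_that("puffs leaving the buffered domain are booked as exported", {
  grid <- grid_spec(nx = 5, ny = 5, dx = 100, dy = 100, source_cell = c(3, 3))
  chem <- chemical_properties("inert", 100, deposition_velocity = 0)
  p <- new_puff(7, x = 250, y = 250, sigma0 = 30)
  rec <- list(wind_speed = 3, wind_direction = 270, stability_class = "D")
  st <- step_hour(list(p), rec, chem, grid, buffer_m = 1000,
                  deposition = FALSE)
  expect_length(st$puffs, 0)
  expect_equal(st$exported_kg, 7)
})

test_that("deposition arithmetic matches the hand formula and conserves mass", {
  grid <- grid_spec(nx = 2, ny = 2, dx = 100, dy = 100, source_cell = c(1, 1))
  chem <- benzyl_chloride()
  sp <- soil_parameters(bulk_density = 1300, mixing_depth = 0.01)
  air <- matrix(0, 2, 2); air[1, 2] <- 3.5   # constant C for one hour
  soil0 <- matrix(1, 2, 2)
  soil1 <- deposit_hour(air, chem, sp, soil0)
  expect_equal(soil1[1, 2] - 1, 0.005 * 3.5 * 3600 / (1300 * 0.01))
  expect_equal(soil1[c(1, 2, 4)], soil0[c(1, 2, 4)])  # zero air -> unchanged
  expect_equal(deposit_hour(matrix(0, 2, 2), chem, sp, soil0), soil0)
  expect_error(deposit_hour(matrix(0, 3, 2), chem, sp, soil0), "congruent")
})

test_that("soil decay is exponential with the semigroup property", {
  soil <- matrix(runif(12), 3, 4)
  none <- chemical_properties("x", 1, soil_decay_rate = 0)
  expect_identical(decay_soil_day(soil, none), soil)
  half <- chemical_properties("x", 1, soil_decay_rate = log(2))
  expect_equal(decay_soil_day(soil, half), soil / 2)
  k <- chemical_properties("x", 1, soil_decay_rate = 0.13)
  ten <- soil
  for (i in 1:10) ten <- decay_soil_day(ten, k)
  expect_equal(ten, soil * exp(-10 * 0.13), tolerance = 1e-12)
})

test_that("simulation rejects meteorology shorter than the horizon", {
  fx <- make_fixture(seed = 1)
  expect_error(run_simulation(fx$scenario, fx$meteo[1:100, ]),
               "covers 100 hours")
})

test_that("a zero-mass release yields an all-zero history", {
  fx <- make_fixture(seed = 1, horizon_days = 2)
  sc <- fx$scenario
  sc$release_mass <- 0
  h <- run_simulation(sc, fx$meteo)
  expect_true(all(h$air_daily == 0))
  expect_true(all(h$soil_daily == 0))
})

test_that("the fate system is linear in released mass", {
  fx <- make_fixture(seed = 2, horizon_days = 3)
  h1 <- run_simulation(fx$scenario, fx$meteo)
  sc2 <- fx$scenario
  sc2$release_mass <- 2 * fx$scenario$release_mass
  h2 <- run_simulation(sc2, fx$meteo)
  expect_equal(h2$air_daily, 2 * h1$air_daily, tolerance = 1e-9)
  expect_equal(h2$soil_daily, 2 * h1$soil_daily, tolerance = 1e-9)
})

test_that("hourly mass balance closes to 1 percent on the fixture", {
  fx <- make_fixture(seed = 1)
  h <- run_simulation(fx$scenario, fx$meteo)
  rel <- abs(h$mass_balance$residual) / pmax(h$mass_balance$released, 1e-12)
  expect_true(all(rel < 0.01))
  expect_true(all(h$air_daily >= 0))
  expect_true(all(h$soil_daily >= 0))
})

test_that("with zero soil decay every cell's soil series is non-decreasing", {
  fx <- make_fixture(seed = 3, horizon_days = 3)
  sc <- fx$scenario
  sc$chemical$soil_decay_rate <- 0
  h <- run_simulation(sc, fx$meteo)
  flat <- matrix(h$soil_daily, ncol = dim(h$soil_daily)[3])
  expect_true(all(flat[, -1] - flat[, -ncol(flat)] >= -1e-12))
})

test_that("a calm no-loss run conserves airborne mass through many steps", {
  grid <- grid_spec(nx = 9, ny = 9, dx = 100, dy = 100, source_cell = c(5, 5))
  chem <- chemical_properties("inert", 100, deposition_velocity = 0)
  puffs <- list(new_puff(3, 450, 450, sigma0 = 60))
  for (i in 1:10) {
    st <- step_hour(puffs, list(wind_speed = 0, wind_direction = 0,
                                stability_class = "F"),
                    chem, grid, deposition = FALSE)
    puffs <- st$puffs
  }
  expect_equal(puffs[[1]]$mass_kg, 3, tolerance = 1e-9)
})
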