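# Build a concentration_history by hand from per-day grid-max values (the
# max is planted at a moving cell, everything else zero) or from explicit
# arrays. Used to probe the endpoint and risk engines independently of the
# fate model.
fake_history <- function(air_max = NULL, soil = NULL, nx = 3, ny = 3,
                         chemical = benzyl_chloride()) {
  n_days <- if (!is.null(air_max)) length(air_max) else dim(soil)[3]
  grid <- grid_spec(nx = nx, ny = ny, dx = 100, dy = 100,
                    mixing_height = 10, source_cell = c(1, 1))
  air <- array(0, c(ny, nx, n_days))
  if (!is.null(air_max)) {
    for (d in seq_len(n_days)) {
      cell <- 1 + (d - 1) %% (nx * ny)   # move the hot cell around
      air[, , d][cell] <- air_max[d]
    }
  }
  if (is.null(soil)) soil <- array(0, c(ny, nx, n_days))
  structure(
    list(air_daily = air, soil_daily = soil, n_days = n_days, grid = grid,
         chemical = chemical, soil_params = soil_parameters(),
         mass_balance = tibble::tibble()),
    class = "concentration_history"
  )
}

# Exposure factors that make ECR equal the cumulative soil concentration
# (IR = 1 kg/d, BW = 1 kg, LT = 1 d, use with csf = 1).
identity_factors <- function(label = "unit") {
  exposure_factors(label, soil_intake_mg = 1e6, body_weight_kg = 1,
                   lifetime_days = 1)
}

# calm meteorology: zero wind, fixed class, n hours
calm_meteo <- function(n_hours, stability = "D") {
  tibble::tibble(
    timestamp = as.POSIXct("2017-01-01 00:00:00", tz = "UTC") +
      3600 * (seq_len(n_hours) - 1),
    wind_speed = 0,
    wind_direction = 0,
    stability_class = stability
  )
}
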