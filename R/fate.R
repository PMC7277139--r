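# Gaussian-puff air dispersion with a vertically well-mixed layer, dry
# deposition to surface soil, first-order decay in both media, and an
# optional first-order soil-to-air re-volatilization return flux.

# Martin (1976) power-law fits to the Pasquill-Gifford curves, x in km.
.pg_sy_a <- c(A = 213, B = 156, C = 104, D = 68, E = 50.5, F = 34)
.pg_sz_near <- list( # x <= 1 km: c, d, f
  A = c(440.8, 1.941, 9.27), B = c(106.6, 1.149, 3.3),
  C = c(61.0, 0.911, 0),     D = c(33.2, 0.725, -1.7),
  E = c(22.8, 0.678, -1.3),  F = c(14.35, 0.740, -0.35)
)
.pg_sz_far <- list( # x > 1 km
  A = c(459.7, 2.094, -9.6), B = c(108.2, 1.098, 2.0),
  C = c(61.0, 0.911, 0),     D = c(44.5, 0.516, -13.0),
  E = c(55.4, 0.305, -34.0), F = c(62.6, 0.180, -48.6)
)

#' Pasquill-Gifford dispersion coefficients
#'
#' Horizontal and vertical Gaussian spread parameters as a power law of
#' downwind distance (Martin 1976 fits), by Pasquill stability class. Class
#' A (very unstable) spreads fastest, class F (very stable) slowest; both
#' sigmas grow monotonically with distance. The vertical sigma is floored
#' at 0.1 m where the far-field fit would turn non-positive very close to
#' the source.
#'
#' @param stability_class One of `"A"`..`"F"`.
#' @param distance_m Downwind travel distance(s), metres, > 0.
#' @return A list with numeric vectors `sigma_y` and `sigma_z` (metres).
#' @examples
#' pg_sigmas("D", 1000) # sigma_y = 68 m, sigma_z = 31.5 m
#' @export
pg_sigmas <- function(stability_class, distance_m) {
  if (!is.character(stability_class) || length(stability_class) != 1 ||
      !stability_class %in% LETTERS[1:6]) {
    stop("unknown stability class: ", paste(stability_class, collapse = ","),
         call. = FALSE)
  }
  if (any(distance_m <= 0)) stop("distance_m must be positive", call. = FALSE)
  x_km <- distance_m / 1000
  sigma_y <- .pg_sy_a[[stability_class]] * x_km^0.894
  near <- .pg_sz_near[[stability_class]]
  far <- .pg_sz_far[[stability_class]]
  sigma_z <- ifelse(x_km <= 1,
                    near[1] * x_km^near[2] + near[3],
                    far[1] * x_km^far[2] + far[3])
  list(sigma_y = unname(sigma_y), sigma_z = pmax(sigma_z, 0.1))
}

#' Create a puff
#'
#' A puff is a Gaussian parcel of released mass characterised by its centre,
#' cumulative travel distance (which sets its spread through [pg_sigmas()])
#' and an initial spread representing dilution over the release cell.
#'
#' @param mass_kg Mass carried by the puff, kg.
#' @param x,y Planar centre coordinates, metres.
#' @param sigma0 Initial horizontal spread, metres.
#' @return A list of class `puff`.
#' @export
new_puff <- function(mass_kg, x, y, sigma0 = 25) {
  stopifnot(mass_kg >= 0, sigma0 > 0)
  structure(list(mass_kg = mass_kg, x = x, y = y, travel_m = 0,
                 sigma0 = sigma0, sigma_y = sigma0, age_hours = 0),
            class = "puff")
}

# effective horizontal sigma: PG growth on top of the initial dilution
puff_sigma_y <- function(puff, stability_class) {
  if (puff$travel_m <= 0) return(puff$sigma0)
  sqrt(pg_sigmas(stability_class, puff$travel_m)$sigma_y^2 + puff$sigma0^2)
}

# cell-centre coordinate matrices (ny rows south->north, nx cols west->east)
grid_coord_matrices <- function(grid) {
  list(x = matrix(cell_centres_x(grid), grid$ny, grid$nx, byrow = TRUE),
       y = matrix(cell_centres_y(grid), grid$ny, grid$nx))
}

# vertically well-mixed Gaussian-puff field, mg/m^3 per cell.
# kernel "centre" evaluates the Gaussian at cell centres; "cell_mean"
# integrates it exactly over each cell (separable normal CDF products),
# which conserves deposited mass even when sigma_y is smaller than a cell.
puff_field <- function(mass_kg, x, y, sigma_y, grid,
                       coords = grid_coord_matrices(grid),
                       kernel = c("centre", "cell_mean")) {
  kernel <- match.arg(kernel)
  if (kernel == "centre") {
    r2 <- (coords$x - x)^2 + (coords$y - y)^2
    mass_kg * 1e6 * exp(-r2 / (2 * sigma_y^2)) /
      (2 * pi * sigma_y^2 * grid$mixing_height)
  } else {
    ex <- grid$origin[1] + (0:grid$nx) * grid$dx   # cell edges, west->east
    ey <- grid$origin[2] + (0:grid$ny) * grid$dy
    fx <- diff(stats::pnorm(ex, mean = x, sd = sigma_y))
    fy <- diff(stats::pnorm(ey, mean = y, sd = sigma_y))
    mass_kg * 1e6 * (fy %o% fx) /
      (grid$dx * grid$dy * grid$mixing_height)
  }
}

#' Advance the puff ensemble by one hour
#'
#' Advects every puff with the hour's wind (toward `wind_direction + 180`
#' degrees), grows its spread from cumulative travel distance via
#' [pg_sigmas()], applies first-order air decay and dry-deposition
#' depletion as exact exponentials, and evaluates the time-averaged hourly
#' air concentration field at cell centres with the vertically well-mixed
#' Gaussian-puff kernel. Puffs whose centre drifts beyond `buffer_m` past
#' the domain edge are dropped and their mass booked as exported. Optional
#' sub-hourly stepping (`n_substeps > 1`) refines the trajectory and the
#' time average without changing the ensemble contract.
#'
#' @param puffs List of [new_puff()] objects (may be empty).
#' @param meteo_record One-row slice of a `meteo_series` (or a list with
#'   `wind_speed`, `wind_direction`, `stability_class`).
#' @param chemical A [chemical_properties()].
#' @param grid A [grid_spec()].
#' @param n_substeps Sub-hourly integration steps.
#' @param buffer_m Export buffer beyond the domain edge, metres.
#' @param deposition Apply dry-deposition depletion (disable to study pure
#'   transport).
#' @param emit Optional emission this hour: a list with `mass_kg`, `x`, `y`,
#'   `sigma0` and optionally `n_puffs`; the mass is split into `n_puffs`
#'   puffs released at evenly spaced substeps through the hour.
#' @param coords Precomputed [grid] coordinate matrices (internal reuse).
#' @param kernel Field evaluation: `"centre"` (Gaussian evaluated at cell
#'   centres) or `"cell_mean"` (exact integral over each cell).
#' @return A list: `puffs` (updated ensemble), `air_field` (ny x nx matrix,
#'   mg/m^3, hourly mean), `exported_kg`, `decayed_kg`, `deposited_kg`
#'   (mass booked this hour).
#' @export
step_hour <- function(puffs, meteo_record, chemical, grid,
                      n_substeps = 1, buffer_m = 5000,
                      deposition = TRUE, emit = NULL,
                      coords = grid_coord_matrices(grid),
                      kernel = c("centre", "cell_mean")) {
  kernel <- match.arg(kernel)
  u <- meteo_record$wind_speed[1]
  dir_from <- meteo_record$wind_direction[1]
  stab <- meteo_record$stability_class[1]
  # transport is toward direction + 180 (meteorological "from" convention)
  theta <- (dir_from + 180) * pi / 180
  ux <- u * sin(theta)
  uy <- u * cos(theta)

  dt <- 3600 / n_substeps
  lam_air <- chemical$air_decay_rate / n_substeps            # per substep
  lam_dep <- if (deposition) {
    chemical$deposition_velocity * dt / grid$mixing_height   # per substep
  } else 0
  lam <- lam_air + lam_dep

  # emission schedule: which substep receives which new puff
  emit_at <- integer(0)
  emit_mass <- numeric(0)
  if (!is.null(emit) && emit$mass_kg > 0) {
    n_new <- emit$n_puffs %||% 1L
    emit_at <- floor(seq(0, n_substeps - 1e-9, length.out = n_new + 1))[seq_len(n_new)] + 1L
    emit_mass <- rep(emit$mass_kg / n_new, n_new)
  }

  xmin <- grid$origin[1] - buffer_m
  xmax <- grid$origin[1] + grid$nx * grid$dx + buffer_m
  ymin <- grid$origin[2] - buffer_m
  ymax <- grid$origin[2] + grid$ny * grid$dy + buffer_m

  air_sum <- matrix(0, grid$ny, grid$nx)
  exported <- 0; decayed <- 0; deposited <- 0

  for (s in seq_len(n_substeps)) {
    for (k in which(emit_at == s)) {
      puffs[[length(puffs) + 1]] <- new_puff(emit_mass[k], emit$x, emit$y,
                                             emit$sigma0 %||% 25)
    }
    keep <- logical(length(puffs))
    for (p in seq_along(puffs)) {
      pf <- puffs[[p]]
      pf$x <- pf$x + ux * dt
      pf$y <- pf$y + uy * dt
      pf$travel_m <- pf$travel_m + u * dt
      pf$age_hours <- pf$age_hours + 1 / n_substeps
      pf$sigma_y <- puff_sigma_y(pf, stab)
      if (pf$x < xmin || pf$x > xmax || pf$y < ymin || pf$y > ymax) {
        exported <- exported + pf$mass_kg
        keep[p] <- FALSE
        next
      }
      # time-averaged concentration over the substep under exponential loss
      psi <- if (lam > 0) (1 - exp(-lam)) / lam else 1
      air_sum <- air_sum + puff_field(pf$mass_kg * psi, pf$x, pf$y,
                                      pf$sigma_y, grid, coords,
                                      kernel = kernel) / n_substeps
      lost <- pf$mass_kg * (1 - exp(-lam))
      if (lam > 0) {
        decayed <- decayed + lost * lam_air / lam
        deposited <- deposited + lost * lam_dep / lam
      }
      pf$mass_kg <- pf$mass_kg - lost
      puffs[[p]] <- pf
      keep[p] <- TRUE
    }
    puffs <- puffs[keep]
  }

  list(puffs = puffs, air_field = air_sum,
       exported_kg = exported, decayed_kg = decayed, deposited_kg = deposited)
}

#' Soil parameters for converting deposited mass to soil concentration
#'
#' @param bulk_density Dry bulk density of the receiving soil layer, kg/m^3.
#' @param mixing_depth Depth over which deposition mixes, metres.
#' @return A list of class `soil_parameters`.
#' @export
soil_parameters <- function(bulk_density = 1300, mixing_depth = 0.01) {
  if (bulk_density <= 0 || mixing_depth <= 0) {
    stop("bulk_density and mixing_depth must be positive", call. = FALSE)
  }
  structure(list(bulk_density = bulk_density, mixing_depth = mixing_depth),
            class = "soil_parameters")
}

#' Deposit one hour of dry deposition into the soil field
#'
#' Per cell, the deposition flux is `deposition_velocity * C` (mg/m^2/s)
#' integrated over the hour, and the soil concentration increment is
#' `v_d * C * 3600 / (bulk_density * mixing_depth)` in mg/kg. The matching
#' mass has already been debited from the puff ensemble by [step_hour()]'s
#' depletion exponential, so air and soil stay in mass balance.
#'
#' @param air_field Hourly-mean air concentration matrix, mg/m^3.
#' @param chemical A [chemical_properties()].
#' @param soil_params A [soil_parameters()].
#' @param soil_field Soil concentration matrix, mg/kg (same shape).
#' @return The updated soil field, mg/kg.
#' @export
deposit_hour <- function(air_field, chemical, soil_params, soil_field) {
  if (!all(dim(air_field) == dim(soil_field))) {
    stop("air and soil fields are not congruent", call. = FALSE)
  }
  soil_field + chemical$deposition_velocity * air_field * 3600 /
    (soil_params$bulk_density * soil_params$mixing_depth)
}

#' Apply one day of first-order soil decay
#'
#' @param soil_field Soil concentration matrix, mg/kg.
#' @param chemical A [chemical_properties()]; uses `soil_decay_rate` (per day).
#' @return The decayed soil field.
#' @export
decay_soil_day <- function(soil_field, chemical) {
  soil_field * exp(-chemical$soil_decay_rate)
}

#' Simulate multimedia fate of an accidental release
#'
#' Runs the hourly Gaussian-puff air model over the scenario horizon,
#' deposits to surface soil each hour, applies first-order soil decay once
#' per simulated day, and (when the chemical's `revolatilization_rate` is
#' positive) returns a slow first-order soil-to-air flux that appears as a
#' ventilation-limited concentration in each cell's air column before being
#' carried out of the domain. Produces daily-average air fields (mean of
#' the day's 24 hourly fields) and end-of-day soil fields, plus an hourly
#' mass-balance ledger.
#'
#' @param scenario An [accident_scenario()].
#' @param meteo A `meteo_series` covering at least `horizon_days * 24` hours.
#' @param soil_params A [soil_parameters()].
#' @param n_substeps Sub-hourly integration steps for the puff model.
#' @param puffs_per_hour Number of puffs emitted per release hour.
#' @param buffer_m Export buffer beyond the domain edge, metres.
#' @param sigma0 Initial puff spread, metres.
#' @param kernel Field evaluation: `"cell_mean"` (default; exact Gaussian
#'   integral over each cell, conserves deposited mass for narrow puffs)
#'   or `"centre"` (point evaluation at cell centres).
#' @return An object of class `concentration_history`: 3-d arrays
#'   `air_daily` and `soil_daily` (`ny x nx x n_days`), `n_days`, the
#'   `grid`, and a `mass_balance` tibble with one row per simulated hour.
#' @examples
#' fx <- make_fixture(seed = 1)
#' hist <- run_simulation(fx$scenario, fx$meteo)
#' dim(hist$air_daily)
#' @export
run_simulation <- function(scenario, meteo, soil_params = soil_parameters(),
                           n_substeps = 30, puffs_per_hour = 6,
                           buffer_m = 5000, sigma0 = 10,
                           kernel = c("cell_mean", "centre")) {
  kernel <- match.arg(kernel)
  stopifnot(inherits(scenario, "accident_scenario"))
  validate_meteo(meteo)
  n_hours <- scenario$horizon_days * 24
  if (nrow(meteo) < n_hours) {
    stop("meteorology covers ", nrow(meteo), " hours but the horizon needs ",
         n_hours, call. = FALSE)
  }
  grid <- scenario$grid
  chem <- scenario$chemical
  coords <- grid_coord_matrices(grid)
  src <- source_xy(grid)
  cell_area <- grid$dx * grid$dy
  # kg of soil in one cell's mixing layer, for mg/kg <-> mass conversion
  cell_soil_kg <- soil_params$bulk_density * soil_params$mixing_depth * cell_area

  soil <- matrix(0, grid$ny, grid$nx)
  puffs <- list()
  air_daily <- array(0, c(grid$ny, grid$nx, scenario$horizon_days))
  soil_daily <- array(0, c(grid$ny, grid$nx, scenario$horizon_days))

  released <- 0; exported <- 0; decayed <- 0; deposited_outside <- 0
  mb <- vector("list", n_hours)
  day_air_sum <- matrix(0, grid$ny, grid$nx)

  # hourly emission plan over the release window
  rel_hours <- ceiling(scenario$release_duration)
  rate <- scenario$release_mass / scenario$release_duration
  k_rv_hour <- chem$revolatilization_rate / 24

  for (h in seq_len(n_hours)) {
    rec <- meteo[h, ]
    emit <- NULL
    if (h <= rel_hours) {
      frac_hr <- min(1, scenario$release_duration - (h - 1))
      emit <- list(mass_kg = rate * frac_hr, x = src[1], y = src[2],
                   sigma0 = sigma0, n_puffs = puffs_per_hour)
      released <- released + emit$mass_kg
    }
    st <- step_hour(puffs, rec, chem, grid, n_substeps = n_substeps,
                    buffer_m = buffer_m, emit = emit, coords = coords,
                    kernel = kernel)
    puffs <- st$puffs
    exported <- exported + st$exported_kg
    decayed <- decayed + st$decayed_kg

    # soil uptake from this hour's mean field; the off-grid share of the
    # depleted mass fell outside the mapped domain
    soil_new <- deposit_hour(st$air_field, chem, soil_params, soil)
    dep_in_grid <- sum(soil_new - soil) * cell_soil_kg / 1e6
    deposited_outside <- deposited_outside + max(0, st$deposited_kg - dep_in_grid)
    soil <- soil_new

    air_field <- st$air_field

    if (k_rv_hour > 0 && any(soil > 0)) {
      # first-order return flux; ventilation-limited column concentration,
      # then flushed out of the domain with the mean wind
      rv_frac <- 1 - exp(-k_rv_hour)
      rv_mass_mg <- soil * cell_soil_kg * rv_frac          # per cell
      u <- max(rec$wind_speed[1], 0.1)
      residence <- min(1, grid$dx / (u * 3600))
      air_field <- air_field + rv_mass_mg * residence /
        (cell_area * grid$mixing_height)
      soil <- soil * (1 - rv_frac)
      exported <- exported + sum(rv_mass_mg) / 1e6
    }

    day_air_sum <- day_air_sum + air_field
    airborne <- sum(vapply(puffs, function(p) p$mass_kg, numeric(1)))
    soil_kg <- sum(soil) * cell_soil_kg / 1e6

    if (h %% 24 == 0) {
      day <- h %/% 24
      air_daily[, , day] <- day_air_sum / 24
      day_air_sum <- matrix(0, grid$ny, grid$nx)
      decayed <- decayed + soil_kg * (1 - exp(-chem$soil_decay_rate))
      soil <- decay_soil_day(soil, chem)
      soil_kg <- sum(soil) * cell_soil_kg / 1e6
      soil_daily[, , day] <- soil
    }

    mb[[h]] <- c(hour = h, released = released, airborne = airborne,
                 soil = soil_kg, exported = exported, decayed = decayed,
                 deposited_outside = deposited_outside)
  }

  mass_balance <- tibble::as_tibble(do.call(rbind, mb))
  mass_balance$residual <- with(mass_balance,
    released - (airborne + soil + exported + decayed + deposited_outside))

  structure(
    list(air_daily = air_daily, soil_daily = soil_daily,
         n_days = scenario$horizon_days, grid = grid,
         chemical = chem, soil_params = soil_params,
         mass_balance = mass_balance),
    class = "concentration_history"
  )
}

#' @export
print.concentration_history <- function(x, ...) {
  cat(sprintf("<concentration_history> %d days on a %d x %d grid\n",
              x$n_days, x$grid$nx, x$grid$ny))
  amax <- apply(x$air_daily, 3, max)
  smax <- apply(x$soil_daily, 3, max)
  cat(sprintf("  air  daily max: %.3g .. %.3g mg/m^3\n", max(amax), min(amax)))
  cat(sprintf("  soil daily max: %.3g .. %.3g mg/kg\n", max(smax), min(smax)))
  invisible(x)
}

#' Daily grid-wide extrema of air and soil concentration
#'
#' A tabular view of a simulation: per day, the maximum and minimum air
#' (mg/m^3) and soil (mg/kg) concentration over all grid cells.
#'
#' @param history A `concentration_history`.
#' @return A tibble with columns `day`, `air_max`, `air_min`, `soil_max`,
#'   `soil_min`.
#' @export
daily_extrema <- function(history) {
  stopifnot(inherits(history, "concentration_history"))
  tibble::tibble(
    day = seq_len(history$n_days),
    air_max = apply(history$air_daily, 3, max),
    air_min = apply(history$air_daily, 3, min),
    soil_max = apply(history$soil_daily, 3, max),
    soil_min = apply(history$soil_daily, 3, min)
  )
}
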