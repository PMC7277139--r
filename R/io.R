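#' Write a concentration or risk field as an ESRI ASCII grid
#'
#' Standard six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value -9999`) followed by `ny` rows of `nx` values,
#' north row first, so any GIS can render the field.
#'
#' @param field `ny x nx` matrix (row 1 = southernmost row, as stored by
#'   [run_simulation()]).
#' @param grid A [grid_spec()] with `dx == dy`.
#' @param path Output path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @seealso [read_ascii_grid()]
#' @export
write_ascii_grid <- function(field, grid, path) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.matrix(field) || nrow(field) != grid$ny || ncol(field) != grid$nx) {
    stop("field shape does not match the grid (expected ", grid$ny, " x ",
         grid$nx, ")", call. = FALSE)
  }
  if (grid$dx != grid$dy) {
    stop("ESRI ASCII grids need square cells (dx == dy)", call. = FALSE)
  }
  header <- c(
    paste("ncols", grid$nx),
    paste("nrows", grid$ny),
    paste("xllcorner", format(grid$origin[1], scientific = FALSE)),
    paste("yllcorner", format(grid$origin[2], scientific = FALSE)),
    paste("cellsize", format(grid$dx, scientific = FALSE)),
    "NODATA_value -9999"
  )
  body <- apply(field[grid$ny:1, , drop = FALSE], 1,
                function(r) paste(formatC(r, format = "g", digits = 9),
                                  collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid written by [write_ascii_grid()]
#'
#' @param path Path to an `.asc` file.
#' @return A list: `field` (`ny x nx` matrix, row 1 = south) and `grid`
#'   (a [grid_spec()] with a placeholder source cell).
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("raster not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1))
  vals <- as.numeric(vapply(hdr, `[`, "", 2))
  names(vals) <- keys
  nx <- as.integer(vals[["ncols"]]); ny <- as.integer(vals[["nrows"]])
  body <- lapply(lines[7:(6 + ny)], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, body)          # north row first on disk
  field <- m[ny:1, , drop = FALSE]   # back to south-first storage
  grid <- grid_spec(nx = nx, ny = ny, dx = vals[["cellsize"]],
                    dy = vals[["cellsize"]],
                    origin = c(vals[["xllcorner"]], vals[["yllcorner"]]),
                    source_cell = c(1, 1))
  list(field = field, grid = grid)
}

#' Persist daily concentration fields as rasters plus an index
#'
#' Writes one ESRI ASCII raster per requested day and medium under `dir`
#' and an `index.csv` (`day`, `medium`, `path`) describing them.
#'
#' @param history A `concentration_history`.
#' @param dir Output directory (created if needed).
#' @param days Days to export; default all.
#' @return The index tibble, invisibly.
#' @export
write_history <- function(history, dir, days = seq_len(history$n_days)) {
  stopifnot(inherits(history, "concentration_history"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- purrr::list_rbind(purrr::map(days, function(d) {
    rows <- purrr::map(c("air", "soil"), function(med) {
      f <- if (med == "air") history$air_daily[, , d] else history$soil_daily[, , d]
      p <- file.path(dir, sprintf("%s_day%03d.asc", med, d))
      write_ascii_grid(f, history$grid, p)
      tibble::tibble(day = d, medium = med, path = p)
    })
    purrr::list_rbind(rows)
  }))
  readr::write_csv(idx, file.path(dir, "index.csv"))
  invisible(idx)
}

#' Build the small test scenario
#'
#' A deterministic, seconds-scale scenario used throughout the test suite
#' and examples: a one-hour 4-tonne release on a 20 x 15 grid of 100 m
#' cells over a 10-day horizon, with synthetic north-westerly meteorology.
#' The chemical is benzyl chloride with the soil-to-air return flux
#' switched off so that the extinction endpoint falls inside the short
#' horizon.
#'
#' @param seed Seed for the synthetic meteorology.
#' @param horizon_days Simulation horizon, days.
#' @return A list with `scenario` and `meteo`.
#' @examples
#' fx <- make_fixture(seed = 7)
#' fx$scenario
#' @export
make_fixture <- function(seed = 1, horizon_days = 10) {
  chem <- benzyl_chloride()
  chem$revolatilization_rate <- 0
  scenario <- accident_scenario(
    chemical = chem, release_mass = 4000, release_duration = 1,
    start_time = "2017-01-01 00:00:00",
    grid = grid_spec(nx = 20, ny = 15, dx = 100, dy = 100,
                     mixing_height = 10, source_cell = c(4, 11)),
    horizon_days = horizon_days
  )
  meteo <- generate_synthetic_meteo(seed = seed, n_hours = horizon_days * 24,
                                    prevailing_from_direction = 315,
                                    direction_spread = 20,
                                    speed_mean = 2, speed_sd = 1)
  list(scenario = scenario, meteo = meteo)
}

#' Run the full assessment pipeline
#'
#' Chains simulate -> endpoint -> assess -> report: runs the fate model,
#' determines the extinction endpoint, computes per-age-group LADD/ECR and
#' risk zones, and writes a report bundle to `out_dir`: per-group ECR and
#' zone rasters (zones coded 2 = red, 1 = orange, 0 = green),
#' `summary.csv` (Table-style per-group statistics), `endpoint.csv`
#' (daily exceedance profile), `windrose.csv`, selected daily
#' concentration rasters under `history/`, and `manifest.json` recording
#' every parameter, a configuration hash and stage timings. The run is
#' deterministic given the configuration (seed included). If a stage
#' fails, files already written are moved to `out_dir/failed/` and the
#' error names the stage.
#'
#' @param config A list (or path to a YAML file) with elements:
#'   `scenario` (an [accident_scenario()] or path to a scenario YAML),
#'   `meteo` (a `meteo_series`, a CSV path, or `NULL` to generate
#'   synthetically with `meteo_args`), `meteo_args` (passed to
#'   [generate_synthetic_meteo()]), `seed`, `fate` (arguments for
#'   [run_simulation()] plus optional `soil` list), `endpoint`
#'   (`background_ppb`, `molar_volume_l`), `risk` (`csf`, `factors` path,
#'   `red_threshold`, `orange_threshold`), `history_days` (days whose
#'   rasters to export; default day 1, the endpoint day and the final
#'   day), and `out_dir`.
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @return Invisibly, a list with `history`, `endpoint`, `assessment`,
#'   `summary` (tibble) and `manifest`.
#' @examples
#' fx <- make_fixture(seed = 1)
#' res <- run_pipeline(list(scenario = fx$scenario, meteo = fx$meteo,
#'                          out_dir = tempfile("run")))
#' res$summary
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- out_dir %||% config$out_dir %||% stop("out_dir is required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  quarantine <- function(stage, e) {
    made <- list.files(out_dir, full.names = TRUE, recursive = FALSE)
    made <- made[basename(made) != "failed"]
    if (length(made)) {
      qdir <- file.path(out_dir, "failed")
      dir.create(qdir, showWarnings = FALSE)
      file.rename(made, file.path(qdir, basename(made)))
    }
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  timings <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(force(expr), error = function(e) quarantine(name, e))
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    out
  }

  scenario <- stage("configure", {
    sc <- config$scenario
    if (is.character(sc)) sc <- read_scenario_yaml(sc)
    stopifnot(inherits(sc, "accident_scenario"))
    sc
  })

  meteo <- stage("meteorology", {
    m <- config$meteo
    if (is.null(m)) {
      args <- config$meteo_args %||% list()
      args$seed <- config$seed %||% args$seed %||% 1
      args$n_hours <- args$n_hours %||% (scenario$horizon_days * 24)
      args$start_time <- args$start_time %||% scenario$start_time
      do.call(generate_synthetic_meteo, args)
    } else if (is.character(m)) read_meteo_csv(m) else validate_meteo(m)
  })

  history <- stage("simulate", {
    fate <- config$fate %||% list()
    soil <- do.call(soil_parameters, fate$soil %||% list())
    run_simulation(scenario, meteo, soil_params = soil,
                   n_substeps = fate$n_substeps %||% 30,
                   puffs_per_hour = fate$puffs_per_hour %||% 6,
                   buffer_m = fate$buffer_m %||% 5000,
                   sigma0 = fate$sigma0 %||% 10)
  })

  ep <- stage("endpoint", {
    epc <- config$endpoint %||% list()
    bg <- if (!is.null(epc$background_ppb)) {
      ppb_to_mg_m3(epc$background_ppb, scenario$chemical$molecular_weight,
                   epc$molar_volume_l %||% 24.45)
    } else NULL
    determine_endpoint(history, background_mg_m3 = bg,
                       molar_volume_l = epc$molar_volume_l %||% 24.45)
  })

  assessment <- stage("assess", {
    rc <- config$risk %||% list()
    factors <- if (is.character(rc$factors)) {
      read_exposure_factors_csv(rc$factors)
    } else rc$factors %||% default_exposure_factors()
    assess(history, ep, factors = factors, csf = rc$csf,
           red_threshold = rc$red_threshold %||% 1e-6,
           orange_threshold = rc$orange_threshold %||% 1e-7)
  })

  summary_tbl <- stage("report", {
    smry <- tidy(assessment)
    readr::write_csv(smry, file.path(out_dir, "summary.csv"))
    readr::write_csv(tidy(ep), file.path(out_dir, "endpoint.csv"))
    readr::write_csv(wind_rose(meteo), file.path(out_dir, "windrose.csv"))
    zone_code <- c(green = 0, orange = 1, red = 2)
    for (m in assessment$maps) {
      slug <- gsub("[^0-9A-Za-z]+", "_", m$group)
      write_ascii_grid(m$ecr, history$grid,
                       file.path(out_dir, paste0("ecr_", slug, ".asc")))
      zc <- matrix(zone_code[m$zones], nrow(m$zones), ncol(m$zones))
      write_ascii_grid(zc, history$grid,
                       file.path(out_dir, paste0("zones_", slug, ".asc")))
    }
    days <- config$history_days %||%
      unique(pmin(history$n_days, c(1L, ep$endpoint_day, history$n_days)))
    write_history(history, file.path(out_dir, "history"), days = days)
    smry
  })

  manifest <- stage("manifest", {
    cfg_record <- list(
      scenario = unclass(scenario[c("release_mass", "release_duration", "horizon_days")]),
      chemical = unclass(scenario$chemical),
      grid = unclass(scenario$grid),
      seed = config$seed %||% NA,
      fate = config$fate %||% list(),
      endpoint = list(background_mg_m3 = ep$background_mg_m3),
      risk = list(csf = assessment$csf,
                  red_threshold = assessment$red_threshold,
                  orange_threshold = assessment$orange_threshold)
    )
    man <- list(
      package = "chemrisk",
      version = as.character(utils::packageVersion("chemrisk")),
      r_version = R.version.string,
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      config = cfg_record,
      config_hash = rlang::hash(cfg_record),
      endpoint_day = ep$endpoint_day,
      timings_s = timings
    )
    jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    man
  })

  invisible(list(history = history, endpoint = ep, assessment = assessment,
                 summary = summary_tbl, manifest = manifest))
}
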