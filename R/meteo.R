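#' Generate a synthetic hourly meteorology series
#'
#' Draws an hourly wind record emulating the kind of series a national
#' weather service archive would supply: wind direction from a wrapped
#' normal distribution around a prevailing direction, wind speed from a
#' normal truncated at zero, and a Pasquill stability class (A-F) drawn
#' from categorical weights. Directions follow the meteorological
#' convention: the direction the wind blows FROM, degrees clockwise from
#' north, so a 315 deg prevailing wind (from the north-west) transports the
#' plume toward the south-east.
#'
#' @param seed Integer seed; identical seed and parameters give an
#'   identical series.
#' @param n_hours Number of hourly records (>= 1).
#' @param prevailing_from_direction Prevailing wind origin, degrees.
#' @param direction_spread Standard deviation of the wrapped-normal
#'   direction, degrees. Zero gives a constant direction.
#' @param speed_mean,speed_sd Mean and sd of the (pre-truncation) normal
#'   wind-speed distribution, m/s.
#' @param stability_weights Non-negative weights for classes A-F;
#'   normalised internally. The default approximates a mid-latitude
#'   coastal class climatology in which the stable classes E-F occupy
#'   their nocturnal share of hours.
#' @param start_time First timestamp (POSIXct or string, UTC).
#' @return A tibble of class `meteo_series` with columns `timestamp`,
#'   `wind_speed`, `wind_direction`, `stability_class`.
#' @examples
#' m <- generate_synthetic_meteo(seed = 1, n_hours = 48)
#' head(m)
#' @export
generate_synthetic_meteo <- function(seed = 1, n_hours = 24 * 100,
                                     prevailing_from_direction = 315,
                                     direction_spread = 30,
                                     speed_mean = 2, speed_sd = 1,
                                     stability_weights = c(0.03, 0.07, 0.15, 0.35, 0.20, 0.20),
                                     start_time = "2017-01-01 00:00:00") {
  n_hours <- as.integer(n_hours)
  if (is.na(n_hours) || n_hours < 1) stop("n_hours must be >= 1", call. = FALSE)
  if (speed_mean <= 0) stop("speed_mean must be positive", call. = FALSE)
  if (length(stability_weights) != 6 || any(stability_weights < 0) ||
      sum(stability_weights) == 0) {
    stop("stability_weights must be six non-negative weights, not all zero",
         call. = FALSE)
  }
  if (is.character(start_time)) start_time <- as.POSIXct(start_time, tz = "UTC")

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)

  direction <- (prevailing_from_direction +
                  stats::rnorm(n_hours, 0, direction_spread)) %% 360
  # normal truncated at zero via inverse-CDF so no probability mass piles at 0
  p0 <- stats::pnorm(0, speed_mean, speed_sd)
  speed <- stats::qnorm(p0 + stats::runif(n_hours) * (1 - p0), speed_mean, speed_sd)
  stability <- sample(LETTERS[1:6], n_hours, replace = TRUE,
                      prob = stability_weights / sum(stability_weights))

  out <- tibble::tibble(
    timestamp = start_time + 3600 * (seq_len(n_hours) - 1),
    wind_speed = speed,
    wind_direction = direction,
    stability_class = stability
  )
  class(out) <- c("meteo_series", class(out))
  out
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# shared column contract for meteorology tables
meteo_columns <- c("timestamp", "wind_speed", "wind_direction", "stability_class")

#' Validate an hourly meteorology table
#'
#' Checks the column contract, hourly gap-free continuity, direction range
#' `[0, 360)`, non-negative speeds and known stability classes. Called by
#' [read_meteo_csv()] and by [run_simulation()] on entry.
#'
#' @param meteo A data frame with the [generate_synthetic_meteo()] columns.
#' @return The input, invisibly classed as `meteo_series`.
#' @export
validate_meteo <- function(meteo) {
  miss <- setdiff(meteo_columns, names(meteo))
  if (length(miss)) stop("meteorology is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(meteo) == 0) stop("meteorology series is empty", call. = FALSE)
  ts <- meteo$timestamp
  if (anyDuplicated(ts)) {
    stop("duplicated hour in meteorology at ",
         format(ts[duplicated(ts)][1], "%Y-%m-%d %H:%M", tz = "UTC"),
         call. = FALSE)
  }
  dt <- as.numeric(difftime(ts[-1], ts[-length(ts)], units = "secs"))
  if (length(dt) && any(dt != 3600)) {
    i <- which(dt != 3600)[1]
    stop("non-hourly gap in meteorology after row ", i, " (",
         format(ts[i], "%Y-%m-%d %H:%M", tz = "UTC"), ")", call. = FALSE)
  }
  bad_dir <- which(meteo$wind_direction < 0 | meteo$wind_direction >= 360)
  if (length(bad_dir)) stop("wind_direction out of [0, 360) at row ", bad_dir[1],
                            call. = FALSE)
  bad_spd <- which(meteo$wind_speed < 0)
  if (length(bad_spd)) stop("negative wind_speed at row ", bad_spd[1], call. = FALSE)
  bad_cls <- which(!meteo$stability_class %in% LETTERS[1:6])
  if (length(bad_cls)) stop("unknown stability_class at row ", bad_cls[1],
                            call. = FALSE)
  if (!inherits(meteo, "meteo_series")) class(meteo) <- c("meteo_series", class(meteo))
  invisible(meteo)
}

#' Read an hourly meteorology series from CSV
#'
#' Expects the header `timestamp,wind_speed,wind_direction,stability_class`
#' with ISO-8601 timestamps and one row per hour; continuity and value
#' ranges are enforced, and violations are reported with the offending row.
#'
#' @param path Path to a CSV file.
#' @return A validated `meteo_series` tibble.
#' @seealso [write_meteo_csv()]
#' @export
read_meteo_csv <- function(path) {
  if (!file.exists(path)) stop("meteorology file not found: ", path, call. = FALSE)
  meteo <- readr::read_csv(
    path,
    col_types = readr::cols(
      timestamp = readr::col_datetime(),
      wind_speed = readr::col_double(),
      wind_direction = readr::col_double(),
      stability_class = readr::col_character()
    )
  )
  validate_meteo(meteo)
  meteo
}

#' Write an hourly meteorology series to CSV
#'
#' @param meteo A `meteo_series` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meteo_csv <- function(meteo, path) {
  validate_meteo(meteo)
  out <- tibble::as_tibble(meteo[meteo_columns])
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  readr::write_csv(out, path)
  invisible(path)
}

#' Wind-rose sector frequencies
#'
#' Bins wind directions into `n_sectors` equal sectors centred on
#' 0, 360/n, 2*360/n, ... degrees (sector 1 is centred on north) and
#' returns the relative frequency of each sector; frequencies sum to one.
#'
#' @param meteo A `meteo_series` (or any data frame with `wind_direction`).
#' @param n_sectors Number of sectors (whole number >= 4); 16 is the
#'   conventional rose.
#' @return A tibble with columns `sector`, `centre_deg`, `count`, `frequency`.
#' @examples
#' rose <- wind_rose(generate_synthetic_meteo(seed = 1, n_hours = 240))
#' sum(rose$frequency)
#' @export
wind_rose <- function(meteo, n_sectors = 16) {
  if (!"wind_direction" %in% names(meteo)) {
    stop("input has no wind_direction column", call. = FALSE)
  }
  if (nrow(meteo) == 0) stop("cannot build a wind rose from an empty series",
                             call. = FALSE)
  if (length(n_sectors) != 1 || n_sectors != round(n_sectors) || n_sectors < 4) {
    stop("n_sectors must be a whole number >= 4", call. = FALSE)
  }
  width <- 360 / n_sectors
  idx <- floor(((meteo$wind_direction + width / 2) %% 360) / width) + 1L
  counts <- tabulate(idx, nbins = n_sectors)
  out <- tibble::tibble(
    sector = seq_len(n_sectors),
    centre_deg = (seq_len(n_sectors) - 1) * width,
    count = counts,
    frequency = counts / sum(counts)
  )
  class(out) <- c("wind_rose", class(out))
  out
}

#' Circular mean of wind directions
#'
#' @param degrees Directions in degrees.
#' @return Mean direction in `[0, 360)`.
#' @export
circular_mean <- function(degrees) {
  rad <- degrees * pi / 180
  (atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi) %% 360
}
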