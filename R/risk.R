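#' Age-group exposure factors for soil ingestion
#'
#' Builds the tabular exposure-factor set used by the dose model: soil
#' intake rate (stored in kg/d), body weight (kg) and lifetime (days) per
#' age group. The default table carries the Korean regulatory screening
#' values used by the packaged benzyl chloride scenario: soil intake
#' 80 mg/d for ages 0-18 and 40 mg/d for adults, age-group body weights
#' 13.3 / 53.6 / 63.3 / 60.7 kg, and a shared life expectancy of 30,186
#' days.
#'
#' @param group Character vector of group labels.
#' @param soil_intake_mg Soil intake rate per group, mg/d.
#' @param body_weight_kg Body weight per group, kg.
#' @param lifetime_days Lifetime per group, days (recycled if length 1).
#' @return A tibble of class `exposure_factors` with columns `group`,
#'   `soil_intake_kg` (kg/d), `body_weight_kg`, `lifetime_days`.
#' @examples
#' default_exposure_factors()
#' @export
exposure_factors <- function(group, soil_intake_mg, body_weight_kg,
                             lifetime_days) {
  if (length(group) == 0) stop("exposure-factor table is empty", call. = FALSE)
  lifetime_days <- rep_len(lifetime_days, length(group))
  if (any(soil_intake_mg <= 0) || any(body_weight_kg <= 0) ||
      any(lifetime_days <= 0)) {
    stop("exposure factors must all be positive", call. = FALSE)
  }
  out <- tibble::tibble(
    group = as.character(group),
    soil_intake_kg = soil_intake_mg / 1e6,
    body_weight_kg = body_weight_kg,
    lifetime_days = lifetime_days
  )
  class(out) <- c("exposure_factors", class(out))
  out
}

#' @rdname exposure_factors
#' @export
default_exposure_factors <- function() {
  exposure_factors(
    group = c("0-9", "10-18", "19-65", ">65"),
    soil_intake_mg = c(80, 80, 40, 40),
    body_weight_kg = c(13.3, 53.6, 63.3, 60.7),
    lifetime_days = 30186
  )
}

#' Read an exposure-factor table from CSV
#'
#' Columns: `group, soil_intake_mg, body_weight_kg, lifetime_days`.
#'
#' @param path CSV path.
#' @return An `exposure_factors` tibble.
#' @export
read_exposure_factors_csv <- function(path) {
  if (!file.exists(path)) stop("exposure-factor file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, col_types = readr::cols(
    group = readr::col_character(), .default = readr::col_double()))
  miss <- setdiff(c("group", "soil_intake_mg", "body_weight_kg", "lifetime_days"),
                  names(df))
  if (length(miss)) stop("exposure-factor file missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  exposure_factors(df$group, df$soil_intake_mg, df$body_weight_kg,
                   df$lifetime_days)
}

#' Lifetime average daily dose from a daily soil-concentration series
#'
#' Accumulates dose over the exposure window closed by the extinction
#' endpoint:
#' `LADD = sum(n = 1..endpoint_day) C_soil[n] * IR_soil / (BW * LT)`,
#' in mg/kg/d. Days after the endpoint never contribute.
#'
#' @param soil_series Daily soil concentration at one location, mg/kg.
#' @param endpoint_day Last day of the accumulation window (1-based).
#' @param factors One row of an [exposure_factors()] table.
#' @return LADD in mg/kg/d.
#' @examples
#' f <- default_exposure_factors()[1, ]
#' compute_ladd(rep(1, 99), 99, f)
#' @export
compute_ladd <- function(soil_series, endpoint_day, factors) {
  endpoint_day <- as.integer(endpoint_day)
  if (endpoint_day < 1) stop("endpoint_day must be >= 1", call. = FALSE)
  if (endpoint_day > length(soil_series)) {
    stop("endpoint_day (", endpoint_day, ") exceeds the soil series length (",
         length(soil_series), ")", call. = FALSE)
  }
  if (nrow(factors) != 1) stop("factors must be a single group row", call. = FALSE)
  sum(soil_series[seq_len(endpoint_day)]) * factors$soil_intake_kg /
    (factors$body_weight_kg * factors$lifetime_days)
}

#' Excess cancer risk from a lifetime average daily dose
#'
#' `ECR = LADD * CSF` (both non-negative); dimensionless excess
#' probability.
#'
#' @param ladd LADD, mg/kg/d (vectorised).
#' @param csf Cancer slope factor, per mg/kg-day.
#' @return ECR, same shape as `ladd`.
#' @export
compute_ecr <- function(ladd, csf) {
  if (any(ladd < 0) || any(csf < 0)) {
    stop("ladd and csf must be non-negative", call. = FALSE)
  }
  ladd * csf
}

#' Classify excess cancer risk into mapped zones
#'
#' Red marks cells at or above the acceptable-risk limit of 1e-6, orange
#' the 1e-7 to 1e-6 band, green below 1e-7. A tie at exactly 1e-6 is red
#' (the safety-conservative reading of "at the limit or higher").
#'
#' @param ecr Excess cancer risk (vectorised, >= 0).
#' @param red_threshold,orange_threshold Zone boundaries (strictly
#'   decreasing).
#' @return Character vector in `c("red", "orange", "green")`.
#' @examples
#' classify_zone(c(2e-6, 5e-7, 5e-8, 0))
#' @export
classify_zone <- function(ecr, red_threshold = 1e-6, orange_threshold = 1e-7) {
  if (any(ecr < 0)) stop("ecr must be non-negative", call. = FALSE)
  if (!(red_threshold > orange_threshold)) {
    stop("zone thresholds must be strictly decreasing", call. = FALSE)
  }
  ifelse(ecr >= red_threshold, "red",
         ifelse(ecr >= orange_threshold, "orange", "green"))
}

#' Per-age-group chronic risk assessment over the endpoint window
#'
#' For each age group, accumulates each grid cell's daily soil
#' concentration up to the endpoint day into a lifetime average daily dose
#' (LADD), multiplies by the cancer slope factor to get the excess cancer
#' risk (ECR), classifies cells into red/orange/green zones, and summarises
#' with the whole-domain maximum and mean ECR and the percentage of domain
#' area in each zone (one exact partition of the cell set, so the three
#' percentages always sum to 100).
#'
#' @param history A `concentration_history`.
#' @param endpoint An `endpoint_result` (or an integer endpoint day).
#' @param factors An [exposure_factors()] table; defaults to the packaged
#'   age groups.
#' @param csf Cancer slope factor, per mg/kg-day; defaults to the history
#'   chemical's `csf_oral`.
#' @param red_threshold,orange_threshold Zone boundaries passed to
#'   [classify_zone()].
#' @return An object of class `risk_assessment`: a list with `maps` (one
#'   `risk_map` per group, each holding `ladd`, `ecr` and `zones`
#'   matrices plus its unrounded summary), the shared `grid`,
#'   `endpoint_day` and `csf`. Use [tidy()] for the per-group summary
#'   table and [glance()] for run-level metadata.
#' @examples
#' fx <- make_fixture(seed = 1)
#' hist <- run_simulation(fx$scenario, fx$meteo)
#' ep <- determine_endpoint(hist)
#' tidy(assess(hist, ep))
#' @export
assess <- function(history, endpoint, factors = default_exposure_factors(),
                   csf = NULL, red_threshold = 1e-6, orange_threshold = 1e-7) {
  stopifnot(inherits(history, "concentration_history"))
  if (inherits(endpoint, "endpoint_result")) {
    endpoint_day <- endpoint$endpoint_day
  } else {
    endpoint_day <- as.integer(endpoint)
  }
  if (endpoint_day < 1 || endpoint_day > history$n_days) {
    stop("endpoint_day must lie in 1..n_days", call. = FALSE)
  }
  if (nrow(factors) == 0) stop("exposure-factor table is empty", call. = FALSE)
  if (is.null(csf)) csf <- history$chemical$csf_oral

  # per-cell cumulative soil concentration over the exposure window
  cum_soil <- apply(history$soil_daily[, , seq_len(endpoint_day), drop = FALSE],
                    c(1, 2), sum)
  n_cells <- length(cum_soil)

  maps <- purrr::map(seq_len(nrow(factors)), function(g) {
    f <- factors[g, ]
    ladd <- cum_soil * f$soil_intake_kg / (f$body_weight_kg * f$lifetime_days)
    ecr <- compute_ecr(ladd, csf)
    zones <- matrix(classify_zone(ecr, red_threshold, orange_threshold),
                    nrow(ecr), ncol(ecr))
    structure(
      list(group = f$group, factors = f, ladd = ladd, ecr = ecr,
           zones = zones,
           summary = tibble::tibble(
             group = f$group,
             max_ecr = max(ecr),
             mean_ecr = mean(ecr),
             pct_red = 100 * sum(zones == "red") / n_cells,
             pct_orange = 100 * sum(zones == "orange") / n_cells,
             # exact complement: the three percentages partition 100
             pct_green = 100 - 100 * sum(zones == "red") / n_cells -
               100 * sum(zones == "orange") / n_cells)),
      class = "risk_map")
  })
  names(maps) <- factors$group

  structure(
    list(maps = maps, grid = history$grid, endpoint_day = endpoint_day,
         csf = csf, red_threshold = red_threshold,
         orange_threshold = orange_threshold),
    class = "risk_assessment"
  )
}

#' @export
print.risk_map <- function(x, ...) {
  cat(sprintf("<risk_map> group %s: max ECR %.3g, mean %.3g; red %.2f%%, orange %.2f%%, green %.2f%%\n",
              x$group, x$summary$max_ecr, x$summary$mean_ecr,
              x$summary$pct_red, x$summary$pct_orange, x$summary$pct_green))
  invisible(x)
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat(sprintf("<risk_assessment> %d age group(s), endpoint day %d, CSF %.3g\n",
              length(x$maps), x$endpoint_day, x$csf))
  print(tidy(x))
  invisible(x)
}

#' Tidy summary of a risk assessment
#'
#' One row per age group with the whole-domain maximum and mean ECR and
#' the red/orange/green area percentages, rounded half-up to two decimals
#' at this reporting step (internal values are unrounded).
#'
#' @param x A `risk_assessment`.
#' @param digits Decimal places for the zone percentages.
#' @param ... Unused.
#' @return A tibble with columns `group`, `max_ecr`, `mean_ecr`,
#'   `pct_red`, `pct_orange`, `pct_green`.
#' @method tidy risk_assessment
#' @export
tidy.risk_assessment <- function(x, digits = 2, ...) {
  out <- purrr::list_rbind(purrr::map(x$maps, "summary"))
  round_half_up <- function(v) floor(v * 10^digits + 0.5) / 10^digits
  out$pct_red <- round_half_up(out$pct_red)
  out$pct_orange <- round_half_up(out$pct_orange)
  out$pct_green <- round_half_up(out$pct_green)
  out
}

#' @method glance risk_assessment
#' @export
glance.risk_assessment <- function(x, ...) {
  tibble::tibble(
    n_groups = length(x$maps),
    endpoint_day = x$endpoint_day,
    csf = x$csf,
    n_cells = x$grid$nx * x$grid$ny,
    red_threshold = x$red_threshold,
    orange_threshold = x$orange_threshold
  )
}
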