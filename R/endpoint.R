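#' Convert a mixing ratio in ppb to a mass concentration in mg/m^3
#'
#' Uses the ideal-gas molar volume (24.45 L/mol at 25 degrees C and 1 atm
#' by default): `mg/m^3 = ppb * MW / molar_volume / 1000`.
#'
#' @param ppb Mixing ratio, parts per billion by volume (>= 0).
#' @param molecular_weight Molar mass, g/mol (> 0).
#' @param molar_volume_l Molar volume, litres per mole.
#' @return Concentration in mg/m^3.
#' @examples
#' ppb_to_mg_m3(0.01, 126.58) # ~5.18e-5 mg/m^3
#' @export
ppb_to_mg_m3 <- function(ppb, molecular_weight, molar_volume_l = 24.45) {
  if (molecular_weight <= 0) stop("molecular_weight must be positive", call. = FALSE)
  if (molar_volume_l <= 0) stop("molar_volume_l must be positive", call. = FALSE)
  if (any(ppb < 0)) stop("ppb must be non-negative", call. = FALSE)
  ppb * molecular_weight / molar_volume_l / 1000
}

#' Determine the extinction endpoint of a simulated release
#'
#' The endpoint is the last day on which any grid cell's daily-average air
#' concentration exceeds the atmospheric background; from the following
#' day onward the chemical is considered extinct everywhere, and the
#' endpoint day closes the dose-accumulation window. A last-exceedance
#' (rather than first-crossing) rule is used because secondary
#' soil-to-air return can push the air concentration back above background
#' after an early dip. Exceedance is strict: a cell exactly at background
#' counts as extinct. If no day ever exceeds background the endpoint is
#' day 1 by convention.
#'
#' @param history A `concentration_history` from [run_simulation()].
#' @param background_mg_m3 Background threshold in mg/m^3; if `NULL`,
#'   derived from the history's chemical (`background_air_ppb` via
#'   [ppb_to_mg_m3()] with `molar_volume_l`).
#' @param molar_volume_l Molar volume used when deriving the threshold.
#' @return An object of class `endpoint_result`: `endpoint_day`,
#'   `background_mg_m3`, and `exceedance_profile`, a tibble with one row
#'   per day (`day`, `air_max`, `exceeds`).
#' @section Errors:
#' If the final simulated day still exceeds background the horizon was too
#' short to observe extinction; an error of class `chemrisk_horizon_error`
#' is raised rather than returning a truncated window.
#' @examples
#' fx <- make_fixture(seed = 1)
#' hist <- run_simulation(fx$scenario, fx$meteo)
#' determine_endpoint(hist)
#' @export
determine_endpoint <- function(history, background_mg_m3 = NULL,
                               molar_volume_l = 24.45) {
  stopifnot(inherits(history, "concentration_history"))
  if (history$n_days < 1) stop("history is empty", call. = FALSE)
  if (is.null(background_mg_m3)) {
    background_mg_m3 <- ppb_to_mg_m3(history$chemical$background_air_ppb,
                                     history$chemical$molecular_weight,
                                     molar_volume_l)
  }
  if (background_mg_m3 <= 0) stop("background must be positive", call. = FALSE)

  air_max <- apply(history$air_daily, 3, max)
  exceeds <- air_max > background_mg_m3
  if (exceeds[history$n_days]) {
    stop(structure(
      class = c("chemrisk_horizon_error", "error", "condition"),
      list(message = sprintf(
        "air still exceeds background (%.3g mg/m^3) on the final simulated day %d; extend the horizon",
        background_mg_m3, history$n_days),
        call = NULL)))
  }
  endpoint_day <- if (any(exceeds)) max(which(exceeds)) else 1L

  structure(
    list(endpoint_day = as.integer(endpoint_day),
         background_mg_m3 = background_mg_m3,
         exceedance_profile = tibble::tibble(
           day = seq_len(history$n_days),
           air_max = air_max,
           exceeds = exceeds)),
    class = "endpoint_result"
  )
}

#' @export
print.endpoint_result <- function(x, ...) {
  cat(sprintf("<endpoint_result> endpoint day %d (background %.3g mg/m^3)\n",
              x$endpoint_day, x$background_mg_m3))
  cat(sprintf("  %d of %d days exceed background\n",
              sum(x$exceedance_profile$exceeds), nrow(x$exceedance_profile)))
  invisible(x)
}

#' @method tidy endpoint_result
#' @export
tidy.endpoint_result <- function(x, ...) x$exceedance_profile

#' @method glance endpoint_result
#' @export
glance.endpoint_result <- function(x, ...) {
  tibble::tibble(
    endpoint_day = x$endpoint_day,
    background_mg_m3 = x$background_mg_m3,
    n_days = nrow(x$exceedance_profile),
    n_exceeding = sum(x$exceedance_profile$exceeds)
  )
}
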