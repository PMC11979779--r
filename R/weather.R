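#' PAR from shortwave radiation
#'
#' Linear conversion of solar radiation to photosynthetically active photon
#' flux, 1000 W m-2 ~ 2300 umol m-2 s-1.
#'
#' @param w_m2 Solar radiation (W m-2), >= 0.
#' @return PAR photon flux (umol m-2 s-1).
#' @export
#' @examples
#' par_from_solar(1000) # 2300
par_from_solar <- function(w_m2) {
  stopifnot(all(w_m2 >= 0, na.rm = TRUE))
  2.3 * w_m2
}

#' Saturated vapor pressure (Tetens/Magnus form)
#'
#' e_sat(T) = 610.78 exp(17.27 T / (T + 237.3)) Pa, over liquid water.
#'
#' @param temp Air temperature (degC), in (-40, 60).
#' @return Saturation vapor pressure (Pa), strictly increasing.
#' @export
saturated_vapor_pressure <- function(temp) {
  stopifnot(all(temp > -40 & temp < 60, na.rm = TRUE))
  610.78 * exp(17.27 * temp / (temp + 237.3))
}

#' Astronomical day length (CBM form)
#'
#' Solar-declination + hour-angle day length with the sun-center daylength
#' coefficient (p = 0, no twilight), saturating at 0/24 h in polar
#' night/day.
#'
#' @param latitude Degrees, in `[-90, 90]`.
#' @param day_of_year Integer day of year (1-366); vectorized (either
#'   argument may be length > 1).
#' @return Daylight hours.
#' @export
#' @examples
#' day_length(64.17, 172) # midsummer at the boreal site, ~20 h or more
day_length <- function(latitude, day_of_year) {
  stopifnot(all(abs(latitude) <= 90))
  theta <- 0.2163108 + 2 * atan(0.9671396 * tan(0.00860 * (day_of_year - 186)))
  phi <- asin(0.39795 * cos(theta)) # solar declination (rad)
  latr <- latitude * pi / 180
  x <- (sin(0 * pi / 180) + sin(latr) * sin(phi)) / (cos(latr) * cos(phi))
  x <- pmin(pmax(x, -1), 1)
  24 - 24 / pi * acos(x)
}

#' Growing season boundaries
#'
#' The season starts on the first day of the first run of 5 successive days
#' with mean temperature >= 5 degC, and ends on the day before the first
#' subsequent run of 5 successive days below 5 degC.
#'
#' @param tmean Daily mean temperature series (degC), length >= 10.
#' @param threshold Temperature threshold (degC). Default 5.
#' @param run_length Run length in days. Default 5.
#' @return A one-row tibble with `start` and `end` indices, or NA in both if
#'   no season is found (an explicit no-season value, not an error).
#' @export
growing_season <- function(tmean, threshold = 5, run_length = 5) {
  stopifnot(length(tmean) >= 2 * run_length)
  n <- length(tmean)
  warm <- tmean >= threshold
  runs_from <- function(flag) {
    # first index i such that flag[i..i+run_length-1] all TRUE
    ok <- stats::filter(as.numeric(flag), rep(1, run_length), sides = 1)
    which(ok == run_length) - run_length + 1
  }
  starts <- runs_from(warm)
  if (length(starts) == 0) {
    return(tibble::tibble(start = NA_integer_, end = NA_integer_))
  }
  start <- starts[1]
  cold_starts <- runs_from(!warm)
  cold_starts <- cold_starts[cold_starts > start]
  end <- if (length(cold_starts) == 0) n else cold_starts[1] - 1L
  tibble::tibble(start = as.integer(start), end = as.integer(end))
}

#' Gap-fill a CO2 series from a companion level
#'
#' Fills missing values of the primary series by a linear map of the
#' companion series (default coefficients as recorded for the paired
#' instrument levels: primary = 0.783 x companion + 781, in as-recorded
#' instrument units).  Non-gap values are untouched.
#'
#' @param level1 Primary series with gaps (NA).
#' @param level2 Companion series, same length.
#' @param slope,intercept Linear map coefficients.
#' @param refit Re-estimate the coefficients by least squares on the overlap
#'   (both series present) before filling. Default FALSE.
#' @return The filled series; attribute `"coefficients"` carries the map used.
#' @export
gapfill_co2 <- function(level1, level2, slope = 0.783, intercept = 781,
                        refit = FALSE) {
  stopifnot(length(level1) == length(level2))
  gaps <- is.na(level1)
  if (any(gaps & is.na(level2))) {
    rlang::abort("gap in the primary series with no companion value",
                 class = "canopyoptim_gapfill_error")
  }
  if (refit) {
    overlap <- !is.na(level1) & !is.na(level2)
    if (sum(overlap) < 2) {
      rlang::abort("not enough overlap to refit the gap-fill map",
                   class = "canopyoptim_gapfill_error")
    }
    fit <- stats::lm(level1[overlap] ~ level2[overlap])
    intercept <- unname(stats::coef(fit)[1])
    slope <- unname(stats::coef(fit)[2])
  }
  out <- level1
  out[gaps] <- slope * level2[gaps] + intercept
  attr(out, "coefficients") <- c(slope = slope, intercept = intercept)
  out
}

#' Read / write a daily weather table
#'
#' CSV schema: ISO `date`, `t_min`, `t_mean`, `t_max` (degC), `i0`
#' (mol m-2 day-1 PAR), `ca` (Pa), `vpd` (Pa), `theta` (fraction), `dt_g`
#' (h).  A `theta_percent` column, if present instead of `theta`, is divided
#' by 100 at ingest.  Round-trips losslessly at full double precision.
#'
#' @param path File path.
#' @return `read_weather()`: a weather tibble.
#' @export
read_weather <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  if ("theta_percent" %in% names(out) && !"theta" %in% names(out)) {
    out$theta <- out$theta_percent / 100
    out$theta_percent <- NULL
  }
  if ("date" %in% names(out)) out$date <- as.Date(out$date)
  out
}

#' @rdname read_weather
#' @param weather Weather data frame.
#' @return `write_weather()`: the path, invisibly.
#' @export
write_weather <- function(weather, path) {
  readr::write_csv(weather, path)
  invisible(path)
}

#' Interpolate short weather gaps
#'
#' Linear interpolation of interior NA runs no longer than `max_gap` days,
#' per numeric column.  Never applied silently by any other function: the
#' simulation requires gap-free input.
#'
#' @param weather Weather data frame.
#' @param max_gap Longest NA run to fill (days). Default 2.
#' @return The weather data frame with short gaps filled.
#' @export
interpolate_gaps <- function(weather, max_gap = 2) {
  num <- vapply(weather, is.numeric, logical(1))
  for (col in names(weather)[num]) {
    x <- weather[[col]]
    if (!anyNA(x)) next
    r <- rle(is.na(x))
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1
    for (k in seq_along(r$values)) {
      if (!r$values[k] || r$lengths[k] > max_gap) next
      i0 <- idx_start[k] - 1; i1 <- idx_end[k] + 1
      if (i0 < 1 || i1 > length(x)) next # edge gaps stay
      gap <- seq(idx_start[k], idx_end[k])
      x[gap] <- x[i0] + (x[i1] - x[i0]) * (gap - i0) / (i1 - i0)
    }
    weather[[col]] <- x
  }
  weather
}
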