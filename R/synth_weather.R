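#' Synthetic daily weather generator
#'
#' Seeded generator of a boreal growing-season driver series with realistic
#' seasonal structure and cross-correlations: temperature as a seasonal
#' sinusoid plus AR(1) anomalies; daily PAR as a clear-sky envelope tied to
#' day length times an autocorrelated cloudiness fraction; VPD from the
#' saturation curve and an AR(1) relative humidity that drops on sunny days
#' (so sunny days carry higher VPD); soil water as a slow AR(1) around a
#' regime mean with an optional scheduled drought spike; CO2 partial pressure
#' a slow ramp with small noise; day length from solar geometry.  All series
#' are clamped to configurable physical bounds defaulting to the observed
#' driver ranges of the study site.
#'
#' @param n_days Number of days. Default 150 (one growing season).
#' @param seed Integer seed; the same seed reproduces the series exactly.
#' @param latitude Site latitude (degrees). Default 64.17.
#' @param start_date First day. Default `"2015-05-01"`.
#' @param theta_mean Soil water regime mean (fraction). Default 0.17.
#' @param theta_persistence AR(1) coefficient of soil water. Default 0.95.
#' @param theta_sd Innovation SD of soil water. Default 0.006.
#' @param drought Optional `list(start =, length =, depth =)` (day index,
#'   days, fraction of theta) scheduling a soil-drying spell with elevated
#'   VPD.
#' @param t_seasonal_mean,t_seasonal_amp Annual temperature cycle mean and
#'   amplitude (degC). Defaults 2 and 14 (boreal).
#' @param t_ar,t_sd AR(1) coefficient and innovation SD of the temperature
#'   anomaly. Defaults 0.75 and 2.2.
#' @param bounds Named list of `c(min, max)` bounds per driver; defaults to
#'   the observed site ranges (`t` -5.1..30.8 degC, `i0` 1.8..63.5
#'   mol m-2 day-1, `vpd` 45.5..1420 Pa, `theta` 0.067..0.298, `ca`
#'   38.5..40.9 Pa).
#' @return A weather tibble with columns `date`, `doy`, `t_min`, `t_mean`,
#'   `t_max`, `i0`, `ca`, `vpd`, `theta`, `dt_g`.
#' @export
#' @examples
#' w <- synthesize_weather(n_days = 30, seed = 1)
#' range(w$vpd)
synthesize_weather <- function(n_days = 150, seed = 1, latitude = 64.17,
                               start_date = as.Date("2015-05-01"),
                               theta_mean = 0.17, theta_persistence = 0.95,
                               theta_sd = 0.006, drought = NULL,
                               t_seasonal_mean = 2, t_seasonal_amp = 14,
                               t_ar = 0.75, t_sd = 2.2,
                               bounds = list(t = c(-5.1, 30.8),
                                             i0 = c(1.8, 63.5),
                                             vpd = c(45.5, 1420),
                                             theta = c(0.067, 0.298),
                                             ca = c(38.5, 40.9))) {
  stopifnot(n_days >= 1, theta_persistence >= 0, theta_persistence < 1)
  if (theta_mean < bounds$theta[1] || theta_mean > bounds$theta[2]) {
    rlang::abort("theta_mean outside the configured bounds",
                 class = "canopyoptim_bad_config")
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))

  date <- as.Date(start_date) + seq_len(n_days) - 1
  doy <- as.integer(strftime(date, "%j"))
  dt_g <- day_length(latitude, doy)

  ar1 <- function(n, phi, sd) {
    x <- numeric(n)
    x[1] <- stats::rnorm(1, 0, sd / sqrt(1 - phi^2))
    for (i in seq_len(n - 1)) x[i + 1] <- phi * x[i] + stats::rnorm(1, 0, sd)
    x
  }
  clamp <- function(x, b) pmin(pmax(x, b[1]), b[2])

  # temperature: seasonal cycle peaking mid-July + AR(1) anomaly
  t_seas <- t_seasonal_mean + t_seasonal_amp * cos(2 * pi * (doy - 197) / 365)
  t_mean <- clamp(t_seas + ar1(n_days, t_ar, t_sd), bounds$t)

  # cloudiness: AR(1) latent -> clearness fraction in [0.25, 1], skewed clear
  z <- ar1(n_days, 0.5, 1)
  u <- stats::pnorm(z / sqrt(1 / (1 - 0.5^2)))
  clearness <- 0.25 + 0.75 * u^0.7

  # diurnal range widens on clear days
  dtr <- 4 + 7 * clearness
  t_min <- clamp(t_mean - 0.45 * dtr, bounds$t)
  t_max <- clamp(t_mean + 0.55 * dtr, bounds$t)
  t_min <- pmin(t_min, t_mean)
  t_max <- pmax(t_max, t_mean)

  # PAR: clear-sky envelope linked to day length, times clearness
  i0 <- clamp(3.1 * dt_g * clearness, bounds$i0)

  # relative humidity: wetter on cloudy days, AR(1) day-to-day memory
  rh <- pmin(pmax(0.88 - 0.38 * (clearness - 0.25) + 0.05 * ar1(n_days, 0.6, 1),
                  0.3), 0.98)

  # drought spell: dries the soil and the air over a scheduled window
  dry_mult <- rep(1, n_days)
  if (!is.null(drought)) {
    win <- seq(drought$start, min(drought$start + drought$length - 1, n_days))
    ramp <- sin(pi * seq_along(win) / length(win)) # smooth in/out
    dry_mult[win] <- 1 - drought$depth * ramp
    rh[win] <- pmax(rh[win] - 0.25 * ramp, 0.25)
  }

  vpd <- clamp((1 - rh) * saturated_vapor_pressure(t_mean), bounds$vpd)

  theta <- clamp(theta_mean * dry_mult +
                   ar1(n_days, theta_persistence, theta_sd), bounds$theta)

  ca <- clamp(39.2 + 1.0 * (seq_len(n_days) - 1) / max(n_days - 1, 1) +
                stats::rnorm(n_days, 0, 0.08), bounds$ca)

  tibble::tibble(date = date, doy = doy, t_min = t_min, t_mean = t_mean,
                 t_max = t_max, i0 = i0, ca = ca, vpd = vpd, theta = theta,
                 dt_g = dt_g)
}

# save/restore the RNG state so generation is side-effect free
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
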