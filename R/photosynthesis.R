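#' CO2 compensation point
#'
#' Arrhenius temperature response of the photorespiratory CO2 compensation
#' point Gamma*.
#'
#' @param temp Air temperature (degC); vectorized.
#' @param params [photo_params()].
#' @return Compensation point (Pa), strictly increasing in `temp` and equal
#'   to `gamma_star_ref` at the reference temperature.
#' @export
#' @examples
#' gamma_star(24.85) # reference value 4.17 Pa at 298 K
gamma_star <- function(temp, params = photo_params()) {
  stopifnot(all(temp > -273.15))
  cpp_gamma_star(as.numeric(temp), unclass(params))
}

#' Short-term temperature response of Jmax
#'
#' Peaked (Arrhenius x deactivation) response, normalized to 1 at the optimal
#' temperature.
#'
#' @inheritParams gamma_star
#' @return Dimensionless multiplier f_Jmax(T).
#' @export
f_jmax_temp <- function(temp, params = photo_params()) {
  stopifnot(all(temp > -273.15))
  out <- cpp_f_jmax_temp(as.numeric(temp), unclass(params))
  if (anyNA(out)) {
    rlang::abort("denominator of the Jmax temperature response crossed zero",
                 class = "canopyoptim_invalid_parameter")
  }
  out
}

#' Delayed temperature acclimation
#'
#' First-order delay dynamics of the effective (acclimated) temperature S_t
#' and the resulting activation factor X_t in `[0, 1]`.  The activation ramps
#' linearly from 0 at `s_min` to 1 at `s_min + delta_s` (closed intervals at
#' both ends).
#'
#' `acclimation()` advances the whole series with `S_0 = T_0` (the first
#' observed mean temperature) unless `s0` is given; `update_acclimation()`
#' performs one step.
#'
#' @param tmean Daily mean air temperatures (degC).
#' @param params [photo_params()] (uses `tau`, `s_min`, `delta_s`).
#' @param s0 Initial delayed temperature (degC). Defaults to `tmean[1]`.
#' @return A tibble with columns `s_t` and `x_t`, one row per input day.
#' @export
#' @examples
#' acclimation(c(5, 6, 8, 10, 12))
acclimation <- function(tmean, params = photo_params(), s0 = tmean[1]) {
  stopifnot(length(tmean) >= 1)
  out <- cpp_acclimation(as.numeric(tmean), as.numeric(s0), unclass(params))
  tibble::tibble(s_t = out$s_t, x_t = out$x_t)
}

#' @rdname acclimation
#' @param s_prev Previous delayed temperature (degC).
#' @param t_t Current mean temperature (degC).
#' @return For `update_acclimation()`: a list with `s_t` and `x_t`.
#' @export
update_acclimation <- function(s_prev, t_t, params = photo_params()) {
  out <- cpp_acclimation(as.numeric(t_t), as.numeric(s_prev), unclass(params))
  list(s_t = out$s_t[length(out$s_t)], x_t = out$x_t[length(out$x_t)])
}

#' Potential electron transport capacity
#'
#' Instantaneous Jmax: the product of the activation factor, the N-Jmax
#' proportionality, the leaf N mass concentration and the short-term
#' temperature response.  Linear in `n_mf`.
#'
#' @param n_mf Leaf N mass concentration (kg N kg-1 leaf).
#' @param temp Air temperature (degC).
#' @param x_t Seasonal activation factor in `[0, 1]`.
#' @param params [photo_params()].
#' @return Jmax (mol m-2 s-1).
#' @export
jmax <- function(n_mf, temp, x_t = 1, params = photo_params()) {
  stopifnot(all(n_mf >= 0))
  x_t * params$a_jmax * n_mf * f_jmax_temp(temp, params)
}

#' Electron transport rate
#'
#' Smaller root of the non-rectangular hyperbola in irradiance, with the
#' quantum yield and the seasonal Jmax both scaled by the activation factor.
#'
#' @param i_inc Irradiance incident on the leaf (mol m-2 s-1).
#' @param jmax_season Seasonal-apex Jmax, already carrying the N and
#'   short-term temperature dependence (mol m-2 s-1).
#' @param x_t Activation factor in `[0, 1]`.
#' @param params [photo_params()].
#' @return Electron transport rate J (mol m-2 s-1), bounded by
#'   `min(x_t * alpha_season * i_inc, x_t * jmax_season)`.
#' @export
electron_transport <- function(i_inc, jmax_season, x_t = 1,
                               params = photo_params()) {
  stopifnot(all(i_inc >= 0), all(jmax_season >= 0))
  cpp_electron_transport(as.numeric(i_inc), as.numeric(jmax_season),
                         as.numeric(x_t), unclass(params))
}

#' Intercellular CO2 partial pressure
#'
#' Greater root of the supply/demand quadratic, with the lumped
#' stomatal+mesophyll conductance `g = g_ratio * gs`.
#'
#' @param gs Stomatal conductance (mol m-2 s-1), > 0.
#' @param ca Ambient CO2 partial pressure (Pa), > 0.
#' @param gamma CO2 compensation point (Pa).
#' @param j Electron transport rate (mol m-2 s-1).
#' @param params [photo_params()] (uses `g_ratio`).
#' @param p_atm Atmospheric pressure (Pa).
#' @return ci (Pa), with `gamma <= ci <= ca` whenever `ca > gamma`.
#' @export
solve_ci <- function(gs, ca, gamma, j, params = photo_params(),
                     p_atm = 101325) {
  if (any(ca <= 0)) {
    rlang::abort("ambient CO2 partial pressure must be positive",
                 class = "canopyoptim_degenerate_input")
  }
  stopifnot(all(gs > 0))
  cpp_solve_ci(as.numeric(gs), as.numeric(ca), as.numeric(gamma),
               as.numeric(j), unclass(params), p_atm)
}

#' Leaf carbon assimilation
#'
#' Co-limited assimilation: the electron-transport-limited demand evaluated at
#' the intercellular CO2 that balances it against Fick's-law supply through
#' the lumped conductance.
#'
#' @param gs Stomatal conductance (mol m-2 s-1), > 0.
#' @param i_inc Irradiance incident on the leaf (mol m-2 s-1).
#' @param temp Air temperature (degC).
#' @param ca Ambient CO2 partial pressure (Pa).
#' @param n_mf Leaf N mass concentration (kg N kg-1 leaf).
#' @param x_t Activation factor in `[0, 1]`.
#' @param params [photo_params()].
#' @param p_atm Atmospheric pressure (Pa).
#' @return A tibble with columns `a` (assimilation, mol m-2 s-1), `ci` (Pa),
#'   `j` and `jmax` (mol m-2 s-1); one row per input.
#' @export
#' @examples
#' assimilation(gs = 0.1, i_inc = 5e-4, temp = 18, ca = 40, n_mf = 0.02)
assimilation <- function(gs, i_inc, temp, ca, n_mf, x_t = 1,
                         params = photo_params(), p_atm = 101325) {
  stopifnot(all(gs > 0), all(i_inc >= 0), all(ca > 0), all(n_mf >= 0))
  out <- cpp_assimilation(as.numeric(gs), as.numeric(i_inc), as.numeric(temp),
                          as.numeric(ca), as.numeric(n_mf), as.numeric(x_t),
                          unclass(params), p_atm)
  tibble::as_tibble(out)
}
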