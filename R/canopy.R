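#' Big-leaf canopy scale factor
#'
#' Integral of the exponential irradiance-acclimation profile over the
#' canopy: (1 - exp(-k LAI)) / k.  Tends to LAI as k -> 0 and saturates at
#' 1/k for deep canopies.
#'
#' @param lai Projected leaf area index (m2 m-2).
#' @param k_ext Light extinction coefficient (-).
#' @return Leaf-area-equivalent scale factor (m2 m-2).
#' @export
canopy_scale_factor <- function(lai, k_ext = 0.52) {
  stopifnot(all(lai >= 0), k_ext >= 0)
  if (k_ext == 0) return(lai)
  (1 - exp(-k_ext * lai)) / k_ext
}

#' Ecosystem GPP from canopy GPP
#'
#' GPP_e = zeta * GPP_c, where the upscale factor zeta accounts for
#' understory vegetation under equal light-use efficiency.  The understory
#' share of ecosystem GPP is (zeta - 1) / zeta.
#'
#' @param gpp_c Canopy (tree) GPP (g C m-2 ground day-1).
#' @param zeta Upscale factor, >= 1 (1.2 fertilized, 1.13 control).
#' @return Ecosystem GPP in the same units.
#' @export
ecosystem_gpp <- function(gpp_c, zeta = 1.2) {
  stopifnot(zeta >= 1)
  zeta * gpp_c
}

#' Daily canopy transpiration
#'
#' Canopy conductance g_C = 1.6 gs_top (1 - exp(-k LAI)) / k applied to the
#' segment VPD, summed over the two daylight segments and converted to
#' liquid water depth (1 kg m-2 = 1 mm).
#'
#' @param gs_am,gs_pm Morning/afternoon top-leaf stomatal conductance
#'   (mol m-2 s-1).
#' @param day One-row weather data frame.
#' @param stand [stand_params()].
#' @param p_atm Atmospheric pressure (Pa).
#' @return Canopy transpiration (mm day-1).
#' @export
canopy_transpiration_day <- function(gs_am, gs_pm, day, stand = stand_params(),
                                     p_atm = 101325) {
  day <- day[1, , drop = FALSE]
  lam <- canopy_scale_factor(stand$lai, stand$k_ext)
  dd <- diurnal_drivers(day, c(0.25, 0.75) * day$dt_g)
  dur <- day$dt_g / 2 * 3600
  sum(1.6 * c(gs_am, gs_pm) * lam * dd$vpd / p_atm * dur) * 18.015e-3
}

#' Run a full growing-season simulation
#'
#' Advances the temperature acclimation state day by day, optimizes leaf N
#' weekly and the stomatal conductance pair daily in 7-day blocks, and
#' upscales leaf-level rates to stand-level daily GPP and canopy
#' transpiration.  Deterministic given inputs.  Days where even closed
#' stomata would violate the cavitation threshold are clamped to the lower
#' conductance bound and flagged, never aborted.
#'
#' @param weather Weather data frame restricted to a growing season, with
#'   columns `date` (optional), `i0` (mol m-2 day-1 PAR), `t_min`, `t_mean`,
#'   `t_max` (degC), `vpd` (Pa), `ca` (Pa), `theta` (fraction), `dt_g` (h).
#' @param params [model_params()]; use [default_params()] for a calibrated
#'   treatment bundle.
#' @param opts [optim_opts()].
#' @param fixed_nmf Optional fixed leaf N concentration; when given, the
#'   weekly N optimization is bypassed (ablation runs).
#' @return A tibble of class `canopy_simulation`, one row per day: `date`,
#'   `week`, `s_t`, `x_t`, `n_mf`, `gs_am`, `gs_pm`, `gpp_c`, `gpp_e`
#'   (g C m-2 ground day-1), `e_c` (mm day-1), `wue` (g C per kg H2O,
#'   GPP_c / E_c), `psi_c_min` (MPa), `k_cost_min`, `flag`.
#' @export
#' @examples
#' w <- synthesize_weather(n_days = 21, seed = 7)
#' sim <- run_simulation(w)
#' head(sim)
run_simulation <- function(weather, params = default_params(),
                           opts = optim_opts(), fixed_nmf = NULL) {
  stopifnot(nrow(weather) >= 1)
  op <- opts
  if (!is.null(fixed_nmf)) {
    stopifnot(fixed_nmf > 0)
    op$nmf_min <- fixed_nmf
    op$nmf_max <- fixed_nmf
    op$grid_n <- 1L
  }
  res <- cpp_run_season(weather_matrix(weather), params_for_kernel(params),
                        unclass(op), s0 = weather$t_mean[1])
  out <- tibble::as_tibble(res)
  out$gpp_e <- ecosystem_gpp(out$gpp_c, params$stand$zeta)
  out$wue <- ifelse(out$e_c > 0, out$gpp_c / out$e_c, NA_real_)
  if ("date" %in% names(weather)) {
    out <- dplyr::bind_cols(tibble::tibble(date = weather$date), out)
  }
  out <- dplyr::relocate(out, dplyr::any_of("date"), "week", "s_t", "x_t",
                         "n_mf", "gs_am", "gs_pm", "gpp_c", "gpp_e", "e_c",
                         "wue", "psi_c_min", "k_cost_min", "flag")
  class(out) <- c("canopy_simulation", class(out))
  out
}

#' Trait-weather correlations
#'
#' Pearson correlations (with two-sided p-values) between the optimized
#' plant variables (daily mean stomatal conductance, leaf N concentration,
#' water-use efficiency) and the weather drivers (I0, mean temperature, VPD,
#' soil water content).
#'
#' @param sim A [run_simulation()] result.
#' @param weather The weather data frame the simulation was run on.
#' @return A tibble with columns `trait`, `driver`, `r`, `p`, `n`, `flag`
#'   (`"undefined"` for constant series, otherwise `"ok"`).
#' @export
trait_weather_correlations <- function(sim, weather) {
  stopifnot(nrow(sim) == nrow(weather), nrow(sim) >= 3)
  traits <- list(gs = (sim$gs_am + sim$gs_pm) / 2, n_mf = sim$n_mf,
                 wue = sim$wue)
  drivers <- list(i0 = weather$i0, t_a = weather$t_mean, vpd = weather$vpd,
                  theta = weather$theta)
  purrr::map_dfr(names(traits), function(tr) {
    purrr::map_dfr(names(drivers), function(dv) {
      x <- traits[[tr]]; y <- drivers[[dv]]
      keep <- stats::complete.cases(x, y)
      x <- x[keep]; y <- y[keep]
      if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
        return(tibble::tibble(trait = tr, driver = dv, r = NA_real_,
                              p = NA_real_, n = length(x), flag = "undefined"))
      }
      ct <- stats::cor.test(x, y, method = "pearson")
      tibble::tibble(trait = tr, driver = dv, r = unname(ct$estimate),
                     p = ct$p.value, n = length(x), flag = "ok")
    })
  })
}
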