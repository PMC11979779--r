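#' Leaf-level transpiration
#'
#' @param gs Stomatal conductance (mol m-2 s-1).
#' @param vpd Vapor pressure deficit (Pa), >= 0.
#' @param p_atm Atmospheric pressure (Pa).
#' @return Transpiration per leaf area E = 1.6 gs VPD / P (mol m-2 s-1).
#' @export
leaf_transpiration <- function(gs, vpd, p_atm = 101325) {
  stopifnot(all(vpd >= 0))
  1.6 * gs * vpd / p_atm
}

#' Soil water potential (Brooks-Corey retention)
#'
#' psi_s = psi_a * Se^(-1/lambda) with effective saturation
#' Se = (theta - theta_r) / (theta_s - theta_r).
#'
#' @param theta Volumetric soil water content (fraction, not percent).
#' @param params [hydraulic_params()].
#' @return Soil water potential (MPa), <= psi_a, strictly increasing in theta.
#' @export
#' @examples
#' soil_water_potential(0.211) # -0.193 MPa with the default soil constants
soil_water_potential <- function(theta, params = hydraulic_params()) {
  if (any(theta <= params$theta_r | theta > params$theta_s)) {
    rlang::abort(
      "theta outside (theta_r, theta_s]: retention curve undefined",
      class = "canopyoptim_out_of_range")
  }
  cpp_soil_water_potential(as.numeric(theta), unclass(params))
}

#' Xylem vulnerability curve
#'
#' Fraction of maximum soil-canopy conductance remaining at water potential
#' psi: P(psi) = (1/2)^((psi/psi50)^b).  Evaluated on the |psi/psi50| ratio,
#' so signs cancel; P(0) = 1 and P(psi50) = 0.5.
#'
#' @param psi Water potential (MPa, <= 0).
#' @param params [hydraulic_params()].
#' @return Remaining conductance fraction in `(0, 1]`.
#' @export
#' @examples
#' vulnerability(-2.7) # 0.5 at psi50
vulnerability <- function(psi, params = hydraulic_params()) {
  cpp_vulnerability(as.numeric(psi), unclass(params))
}

#' Hydraulic cost factor
#'
#' Linear discount from 1 at maximal conductance to 0 at the critical
#' conductance `f_crit * k_sc_max` (88% conductivity loss with the default
#' `f_crit = 0.12`).  May be negative below the critical conductance; the
#' trait optimizer never accepts such states.
#'
#' @param k_sc Soil-canopy conductance (mol m-2 leaf s-1 MPa-1).
#' @param params [hydraulic_params()].
#' @return Dimensionless cost factor.
#' @export
k_cost <- function(k_sc, params = hydraulic_params()) {
  stopifnot(all(k_sc <= params$k_sc_max * (1 + 1e-12), na.rm = TRUE))
  kcrit <- params$f_crit * params$k_sc_max
  (k_sc - kcrit) / (params$k_sc_max - kcrit)
}

#' Coupled canopy water state
#'
#' Solves the Darcy drawdown and the integral-mean conductance
#' simultaneously: psi_c = psi_c,pd - E / k_sc with
#' k_sc = k_sc,max * mean of the vulnerability curve over
#' `[psi_c, psi_c,pd]` (Simpson's 1/3 rule), by damped fixed-point iteration.
#' The pre-dawn potential is psi_c,pd = psi_s - H rho g 1e-6.
#'
#' @param gs Stomatal conductance (mol m-2 s-1); vectorized.
#' @param vpd Vapor pressure deficit (Pa).
#' @param theta Soil water content (fraction).
#' @param height Canopy height (m).
#' @param params [hydraulic_params()].
#' @param p_atm Atmospheric pressure (Pa).
#' @param panels,tol,maxit Simpson panel count, relative fixed-point
#'   tolerance, iteration cap.
#' @return A tibble with columns `psi_c`, `psi_c_pd` (MPa), `k_sc`
#'   (mol m-2 leaf s-1 MPa-1), `e_leaf` (mol m-2 s-1), `k_cost`, `converged`
#'   and `iterations`.  Rows where runaway embolism prevents a solution carry
#'   `converged = FALSE` and NA state.
#' @export
#' @examples
#' solve_canopy_state(gs = 0.05, vpd = 800, theta = 0.15, height = 21)
solve_canopy_state <- function(gs, vpd, theta, height,
                               params = hydraulic_params(), p_atm = 101325,
                               panels = 50, tol = 1e-9, maxit = 200) {
  stopifnot(all(gs >= 0), all(vpd >= 0), height >= 0)
  out <- cpp_canopy_state(as.numeric(gs), as.numeric(vpd), as.numeric(theta),
                          height, unclass(params), p_atm,
                          as.integer(panels), tol, as.integer(maxit))
  res <- tibble::as_tibble(out)
  res$k_cost <- k_cost(pmin(res$k_sc, params$k_sc_max), params)
  res
}

#' Critical stomatal conductance
#'
#' The stomatal conductance at which the solved canopy water potential
#' reaches the runaway threshold P(psi_c) = f_crit.  Computed in closed form
#' from the supply integral between the critical potential and the pre-dawn
#' potential, using the same Simpson discretization as the canopy solver, so
#' the two are mutually consistent.  Decreasing in VPD and in soil dryness.
#'
#' @inheritParams solve_canopy_state
#' @param gs_max Upper search bound returned as VPD approaches 0.
#' @param on_beyond What to do when even closed stomata violate the threshold
#'   (`P(psi_c_pd) <= f_crit`): `"error"` (default) or `"na"`.
#' @return g_s,crit (mol m-2 s-1), capped at `gs_max`.
#' @export
critical_gs <- function(vpd, theta, height, params = hydraulic_params(),
                        p_atm = 101325, panels = 50, gs_max = 1,
                        on_beyond = c("error", "na")) {
  on_beyond <- match.arg(on_beyond)
  out <- cpp_critical_gs(as.numeric(vpd), as.numeric(theta), height,
                         unclass(params), p_atm, as.integer(panels), gs_max)
  if (anyNA(out) && on_beyond == "error") {
    rlang::abort("pre-dawn water potential already beyond the critical threshold",
                 class = "canopyoptim_beyond_critical")
  }
  out
}
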