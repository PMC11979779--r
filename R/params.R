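#' Photosynthesis parameters
#'
#' Parameters of the co-limited leaf photosynthesis model: the Arrhenius
#' temperature response of the CO2 compensation point, the peaked short-term
#' temperature response of Jmax, the non-rectangular hyperbola light response,
#' the delayed seasonal acclimation of photosynthetic capacity, and the linear
#' leaf-nitrogen to Jmax coordination.
#'
#' Temperatures are handed to every user-facing function in degrees Celsius;
#' the conversion to Kelvin happens inside the temperature-response functions.
#' `t_ref` and `t_opt` are stored in Kelvin (reference values 298 K and 305 K).
#'
#' @param gamma_star_ref CO2 compensation point at the reference temperature
#'   (Pa). Default 4.17.
#' @param e_a_gamma Activation energy of the compensation point (J mol-1).
#'   Default 23420.
#' @param e_a_j,e_d_j Activation/deactivation energy of Jmax (J mol-1).
#'   Defaults 47400 and 200000.
#' @param t_opt Optimal temperature for Jmax (K). Default 305.
#' @param theta_j Curvature of the light response curve (-), in (0, 1).
#'   Default 0.7.
#' @param alpha_season Seasonal apex quantum yield (-). Default 0.19.
#' @param a_jmax Ratio between peak Jmax and leaf-mass N concentration
#'   (mol m-2 s-1 per kg N kg-1 leaf). Default 0.02.
#' @param s_min Delayed-temperature threshold below which photosynthesis is
#'   inactive (degC). Default 0.
#' @param delta_s Width of the linear activation ramp above `s_min` (degC).
#'   Default 18.29.
#' @param tau First-order delay constant of temperature acclimation (days),
#'   >= 1. Default 14.87.
#' @param g_ratio Ratio of combined stomatal+mesophyll conductance to stomatal
#'   conductance (-). Default 0.42.
#' @param t_ref Reference temperature of the Arrhenius response (K).
#'   Default 298.
#' @return A named list of class `photo_params`.
#' @export
#' @examples
#' p <- photo_params()
#' gamma_star(298 - 273.15, p) # equals gamma_star_ref at the reference T
photo_params <- function(gamma_star_ref = 4.17, e_a_gamma = 23420,
                         e_a_j = 47400, e_d_j = 200000, t_opt = 305,
                         theta_j = 0.7, alpha_season = 0.19, a_jmax = 0.02,
                         s_min = 0, delta_s = 18.29, tau = 14.87,
                         g_ratio = 0.42, t_ref = 298) {
  stopifnot(theta_j > 0, theta_j < 1, tau >= 1, delta_s >= 0,
            g_ratio > 0, g_ratio <= 1,
            e_a_gamma > 0, e_a_j > 0, e_d_j > 0)
  structure(list(
    gamma_star_ref = gamma_star_ref, e_a_gamma = e_a_gamma, e_a_j = e_a_j,
    e_d_j = e_d_j, t_opt = t_opt, theta_j = theta_j,
    alpha_season = alpha_season, a_jmax = a_jmax, s_min = s_min,
    delta_s = delta_s, tau = tau, g_ratio = g_ratio, t_ref = t_ref
  ), class = "photo_params")
}

#' Hydraulics parameters
#'
#' Soil water retention (Brooks-Corey), xylem vulnerability, and the maximum
#' soil-to-canopy conductance per leaf area.  `f_crit` anchors the hydraulic
#' cost at the commonly observed lethal loss of conductivity of 88%.
#'
#' @param k_sc_max Maximum soil-canopy conductance
#'   (mol m-2 leaf s-1 MPa-1). Defaults to the fertilized-stand value 0.00057;
#'   use 0.00067 for the control stand.
#' @param psi50_sc Water potential causing 50% conductivity loss (MPa,
#'   negative). Default -2.7.
#' @param b_sc Shape parameter of the vulnerability curve (-). Default 2.15.
#' @param f_crit Fraction of `k_sc_max` at which the hydraulic cost is
#'   exhausted (-). Default 0.12 (88% loss is lethal).
#' @param theta_s,theta_r Saturated and residual volumetric soil water
#'   contents (-). Defaults 0.41 and 0.006.
#' @param psi_a Air-entry tension (MPa, negative). Default -0.098.
#' @param lambda_pore Pore-size distribution index (-). Default 1.
#' @param rho_w Density of water (kg m-3). Default 997.
#' @param g_grav Gravitational acceleration (m s-2). Default 9.82.
#' @return A named list of class `hydraulic_params`.
#' @export
hydraulic_params <- function(k_sc_max = 0.00057, psi50_sc = -2.7, b_sc = 2.15,
                             f_crit = 0.12, theta_s = 0.41, theta_r = 0.006,
                             psi_a = -0.098, lambda_pore = 1,
                             rho_w = 997, g_grav = 9.82) {
  stopifnot(k_sc_max > 0, psi50_sc < 0, psi_a < 0,
            f_crit > 0, f_crit < 1, theta_r >= 0, theta_r < theta_s,
            theta_s <= 1)
  structure(list(
    k_sc_max = k_sc_max, psi50_sc = psi50_sc, b_sc = b_sc, f_crit = f_crit,
    theta_s = theta_s, theta_r = theta_r, psi_a = psi_a,
    lambda_pore = lambda_pore, rho_w = rho_w, g_grav = g_grav
  ), class = "hydraulic_params")
}

#' Nitrogen cost parameters
#'
#' @param n_r Ratio between dark respiration and Jmax (-). Default 0.0056.
#' @param n_u Carbon cost of nitrogen uptake (-); treatment specific.
#'   Default 0 (fertilized stand); the control stand estimate is 0.012.
#' @return A named list of class `cost_params`.
#' @export
cost_params <- function(n_r = 0.0056, n_u = 0) {
  stopifnot(n_r >= 0, n_u >= 0)
  structure(list(n_r = n_r, n_u = n_u), class = "cost_params")
}

#' Stand parameters
#'
#' @param height Canopy height (m). Default 19.5 (fertilized stand).
#' @param lai Projected leaf area index (m2 m-2). Default 2.4.
#' @param k_ext Light extinction coefficient (-). Default 0.52.
#' @param m_leaf Leaf transmittance (-). Default 0.05.
#' @param zeta Ecosystem upscale factor GPP_e / GPP_c (-), >= 1. Default 1.2
#'   (fertilized); the control estimate is 1.13.
#' @return A named list of class `stand_params`.
#' @export
stand_params <- function(height = 19.5, lai = 2.4, k_ext = 0.52,
                         m_leaf = 0.05, zeta = 1.2) {
  stopifnot(lai >= 0, k_ext > 0, k_ext < 1.5, zeta >= 1, m_leaf >= 0, m_leaf < 1)
  structure(list(height = height, lai = lai, k_ext = k_ext, m_leaf = m_leaf,
                 zeta = zeta), class = "stand_params")
}

#' Bundle all model parameters
#'
#' @param photo [photo_params()] group.
#' @param hydraulics [hydraulic_params()] group.
#' @param cost [cost_params()] group.
#' @param stand [stand_params()] group.
#' @param p_atm Atmospheric pressure (Pa). Default 101325.
#' @return A named list of class `model_params`.
#' @export
model_params <- function(photo = photo_params(), hydraulics = hydraulic_params(),
                         cost = cost_params(), stand = stand_params(),
                         p_atm = 101325) {
  structure(list(photo = photo, hydraulics = hydraulics, cost = cost,
                 stand = stand, p_atm = p_atm), class = "model_params")
}

#' Default parameter bundles per stand treatment
#'
#' Returns the calibrated parameter set for one of the two experimental stand
#' treatments.  Only the nitrogen-uptake cost `n_u`, the maximum soil-canopy
#' conductance `k_sc_max`, canopy size descriptors and the upscale factor
#' `zeta` differ between the treatments; all other parameters are shared.
#'
#' @param treatment `"fertilized"` or `"control"`.
#' @return A `model_params` bundle.
#' @export
#' @examples
#' default_params("control")$cost$n_u
default_params <- function(treatment = c("fertilized", "control")) {
  treatment <- match.arg(treatment)
  if (treatment == "fertilized") {
    model_params(
      hydraulics = hydraulic_params(k_sc_max = 0.00057),
      cost = cost_params(n_u = 0),
      stand = stand_params(height = 19.5, lai = 2.4, zeta = 1.2)
    )
  } else {
    model_params(
      hydraulics = hydraulic_params(k_sc_max = 0.00067),
      cost = cost_params(n_u = 0.012),
      stand = stand_params(height = 21.1, lai = 2.25, zeta = 1.13)
    )
  }
}

#' Optimizer and solver options
#'
#' Numerical controls for the canopy water-potential fixed-point solver and
#' the two-step weekly trait optimization.
#'
#' @param panels Even number of Simpson panels for the vulnerability integral.
#'   Default 50.
#' @param fp_tol Relative convergence tolerance of the fixed-point iteration.
#'   Default 1e-9.
#' @param fp_maxit Maximum fixed-point iterations. Default 200.
#' @param nm_tol,nm_maxit Relative tolerance and iteration cap of the
#'   Nelder-Mead polish.
#' @param nstarts Number of deterministic starts (top grid cells polished).
#'   Default 3.
#' @param grid_n,grid_g Coarse seeding grid resolution for leaf N and for each
#'   stomatal conductance axis.
#' @param gs_min,gs_max Search bounds on stomatal conductance
#'   (mol m-2 s-1). The effective upper bound per segment is
#'   `min(gs_max, critical_gs(...))`.
#' @param nmf_min,nmf_max Search bounds on leaf N mass concentration
#'   (kg N kg-1 leaf). Defaults 0.007 and 0.05.
#' @param daily_refine Run the per-day fine-tuning step (step 2). Default TRUE.
#' @param night_cost Include the night-time Jmax maintenance cost in the
#'   fitness integral. Default FALSE (daylight only).
#' @return A named list of class `optim_opts`.
#' @export
optim_opts <- function(panels = 50, fp_tol = 1e-9, fp_maxit = 200,
                       nm_tol = 1e-10, nm_maxit = 400, nstarts = 3,
                       grid_n = 10, grid_g = 8,
                       gs_min = 0.001, gs_max = 1, nmf_min = 0.007,
                       nmf_max = 0.05, daily_refine = TRUE,
                       night_cost = FALSE) {
  stopifnot(panels >= 2, fp_tol > 0, gs_min > 0, gs_min < gs_max,
            nmf_min < nmf_max)
  structure(list(panels = as.integer(panels), fp_tol = fp_tol,
                 fp_maxit = as.integer(fp_maxit), nm_tol = nm_tol,
                 nm_maxit = as.integer(nm_maxit), nstarts = as.integer(nstarts),
                 grid_n = as.integer(grid_n), grid_g = as.integer(grid_g),
                 gs_min = gs_min, gs_max = gs_max, nmf_min = nmf_min,
                 nmf_max = nmf_max, daily_refine = daily_refine,
                 night_cost = night_cost), class = "optim_opts")
}

# coerce a model_params bundle to the plain list layout the kernel expects
params_for_kernel <- function(params) {
  stopifnot(inherits(params, "model_params"))
  list(photo = unclass(params$photo), hydraulics = unclass(params$hydraulics),
       cost = unclass(params$cost), stand = unclass(params$stand),
       p_atm = params$p_atm)
}
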