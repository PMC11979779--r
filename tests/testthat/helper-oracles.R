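# Independent oracles written in base R (integrate/uniroot/polyroot), kept
# deliberately separate from the package's compiled solution paths.

# Arrhenius compensation point, direct evaluation
oracle_gamma_star <- function(temp_c, p = photo_params()) {
  T <- temp_c + 273.15
  p$gamma_star_ref * exp(p$e_a_gamma * (T - p$t_ref) / (T * 8.314 * p$t_ref))
}

# peaked Jmax temperature response, direct evaluation
oracle_f_jmax <- function(temp_c, p = photo_params()) {
  T <- temp_c + 273.15
  num <- p$e_d_j * exp(p$e_a_j * (T - p$t_opt) / (T * 8.314 * p$t_opt))
  den <- p$e_d_j - p$e_a_j * (1 - exp(p$e_d_j * (T - p$t_opt) / (T * 8.314 * p$t_opt)))
  num / den
}

# smaller root of the light-response quadratic via polyroot
oracle_etrans_root <- function(alpha_i, jm, theta_j) {
  if (alpha_i <= 0 || jm <= 0) return(0)
  r <- Re(polyroot(c(alpha_i * jm, -(alpha_i + jm), theta_j)))
  min(r)
}

# intercellular CO2 by bisection on the supply/demand balance
oracle_ci <- function(gs, ca, gamma, j, g_ratio = 0.42, p_atm = 101325,
                      tol = 1e-10) {
  g <- g_ratio * gs
  bal <- function(ci) g / p_atm * (ca - ci) - j / 4 * (ci - gamma) / (ci + 2 * gamma)
  uniroot(bal, c(gamma, ca), tol = tol)$root
}

# vulnerability curve, direct evaluation
oracle_vuln <- function(psi, h = hydraulic_params()) {
  0.5^((psi / h$psi50_sc)^h$b_sc)
}

oracle_soil_psi <- function(theta, h = hydraulic_params()) {
  se <- (theta - h$theta_r) / (h$theta_s - h$theta_r)
  h$psi_a * se^(-1 / h$lambda_pore)
}

# canopy water state by bisection on psi_c with adaptive quadrature of the
# vulnerability curve (independent of Simpson + fixed point)
oracle_canopy_state <- function(gs, vpd, theta, height, h = hydraulic_params(),
                                p_atm = 101325, tol = 1e-10) {
  psi_pd <- oracle_soil_psi(theta, h) - height * h$rho_w * h$g_grav * 1e-6
  E <- 1.6 * gs * vpd / p_atm
  if (E <= 0) {
    return(list(psi_c = psi_pd, psi_c_pd = psi_pd,
                k_sc = h$k_sc_max * oracle_vuln(psi_pd, h)))
  }
  supply <- function(psi_c) {
    h$k_sc_max * integrate(function(x) oracle_vuln(x, h), psi_c, psi_pd,
                           rel.tol = 1e-12, abs.tol = 1e-14)$value - E
  }
  lo <- psi_pd
  step <- 0.5
  repeat { # bracket downward; supply increases as psi_c decreases
    lo <- lo - step
    step <- step * 2
    if (supply(lo) > 0) break
    if (lo < 50 * h$psi50_sc) stop("oracle: no solution (runaway)")
  }
  psi_c <- uniroot(supply, c(lo, psi_pd), tol = tol)$root
  list(psi_c = psi_c, psi_c_pd = psi_pd, k_sc = E / (psi_pd - psi_c))
}

# critical gs by dense grid scan for the sign change of P(psi_c(gs)) - f_crit
oracle_critical_gs <- function(vpd, theta, height, h = hydraulic_params(),
                               p_atm = 101325, n_grid = 4000, gs_max = 1) {
  f <- function(gs) {
    st <- tryCatch(oracle_canopy_state(gs, vpd, theta, height, h, p_atm),
                   error = function(e) NULL)
    if (is.null(st)) return(-h$f_crit) # runaway: past the threshold
    oracle_vuln(st$psi_c, h) - h$f_crit
  }
  gs_grid <- seq(1e-4, gs_max, length.out = n_grid)
  v <- vapply(gs_grid, f, numeric(1))
  i <- which(v < 0)[1]
  if (is.na(i)) return(gs_max)
  uniroot(f, c(gs_grid[i - 1], gs_grid[i]), tol = 1e-10)$root
}

# growing season by brute-force run scan
oracle_growing_season <- function(tmean, threshold = 5, run_length = 5) {
  n <- length(tmean)
  first_run <- function(flag, from = 1) {
    for (i in from:(n - run_length + 1)) {
      if (all(flag[i:(i + run_length - 1)])) return(i)
    }
    NA_integer_
  }
  start <- first_run(tmean >= threshold)
  if (is.na(start)) return(c(NA_integer_, NA_integer_))
  cold <- first_run(tmean < threshold, from = start)
  end <- if (is.na(cold)) n else cold - 1L
  c(start, as.integer(end))
}

# deterministic benign test week (mild temperatures, moderate VPD)
benign_week <- function(n = 7) {
  tibble::tibble(
    i0 = seq(28, 34, length.out = n),
    t_min = rep(8, n), t_mean = rep(13, n), t_max = rep(19, n),
    vpd = seq(400, 600, length.out = n),
    ca = rep(40, n), theta = rep(0.18, n), dt_g = rep(17, n)
  )
}
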