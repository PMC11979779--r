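weather_cols <- c("i0", "t_min", "t_mean", "t_max", "vpd", "ca", "theta", "dt_g")

# day-level weather tibble -> kernel driver matrix (fixed column order)
weather_matrix <- function(days) {
  missing <- setdiff(weather_cols, names(days))
  if (length(missing) > 0) {
    rlang::abort(paste0("weather is missing columns: ",
                        paste(missing, collapse = ", ")),
                 class = "canopyoptim_bad_weather")
  }
  m <- as.matrix(days[, weather_cols])
  storage.mode(m) <- "double"
  m
}

#' Instantaneous fitness proxy
#'
#' G = A * k_cost - (N_r + N_u) * Jmax: carbon assimilation of a top-canopy
#' leaf discounted by the hydraulic risk factor, minus the respiration and
#' nitrogen-uptake cost of maintaining photosynthetic capacity.
#'
#' @param gs Stomatal conductance (mol m-2 s-1).
#' @param n_mf Leaf N mass concentration (kg N kg-1 leaf).
#' @param i_inc Irradiance incident on the top leaf (mol m-2 s-1).
#' @param temp Air temperature (degC).
#' @param vpd Vapor pressure deficit (Pa).
#' @param ca Ambient CO2 partial pressure (Pa).
#' @param theta Soil water content (fraction).
#' @param x_t Activation factor in `[0, 1]`.
#' @param params [model_params()].
#' @param opts [optim_opts()].
#' @return A tibble with columns `g` (the fitness proxy, mol m-2 s-1), `a`,
#'   `k_cost`, `jmax`, `psi_c` and `converged`.
#' @export
fitness <- function(gs, n_mf, i_inc, temp, vpd, ca, theta, x_t = 1,
                    params = default_params(), opts = optim_opts()) {
  n <- max(length(gs), length(n_mf), length(i_inc), length(temp),
           length(vpd), length(ca), length(theta), length(x_t))
  args <- tibble::tibble(gs = rep_len(gs, n), n_mf = rep_len(n_mf, n),
                         i_inc = rep_len(i_inc, n), temp = rep_len(temp, n),
                         vpd = rep_len(vpd, n), ca = rep_len(ca, n),
                         theta = rep_len(theta, n), x_t = rep_len(x_t, n))
  ph <- assimilation(args$gs, args$i_inc, args$temp, args$ca, args$n_mf,
                     args$x_t, params$photo, params$p_atm)
  hs <- solve_canopy_state(args$gs, args$vpd, args$theta, params$stand$height,
                           params$hydraulics, params$p_atm,
                           opts$panels, opts$fp_tol, opts$fp_maxit)
  tibble::tibble(
    g = ph$a * hs$k_cost - (params$cost$n_r + params$cost$n_u) * ph$jmax,
    a = ph$a, k_cost = hs$k_cost, jmax = ph$jmax, psi_c = hs$psi_c,
    converged = hs$converged
  )
}

#' Diurnal driver interpolation (two-segment daily scheme)
#'
#' Maps day-level forcing to instantaneous drivers at hour `t` after sunrise:
#' radiation follows a half-sine whose integral over daylight equals the
#' daily total; temperature a sinusoid spanning `[t_min, t_max]` peaking in
#' mid-afternoon (0.75 of the daylight period); VPD is reconstructed from the
#' saturation curve at the instantaneous temperature holding the daily actual
#' vapor pressure constant; CO2 and soil water are constant over the day.
#'
#' @param day One-row data frame with columns `i0`, `t_min`, `t_mean`,
#'   `t_max`, `vpd`, `ca`, `theta`, `dt_g`.
#' @param t Hours from sunrise, in `[0, dt_g]`; vectorized.
#' @return A tibble with columns `t`, `i` (mol m-2 s-1 above-canopy), `temp`
#'   (degC), `vpd` (Pa), `ca` (Pa), `theta`.
#' @export
diurnal_drivers <- function(day, t) {
  day <- as.list(day[1, , drop = FALSE])
  stopifnot(all(t >= 0), all(t <= day$dt_g + 1e-9))
  out <- cpp_diurnal(day[weather_cols], as.numeric(t))
  tibble::tibble(t = as.numeric(t), i = out$i, temp = out$temp, vpd = out$vpd,
                 ca = day$ca, theta = day$theta)
}

#' Daily fitness integral
#'
#' Sum of the instantaneous fitness proxy over the two daylight segments
#' (morning and afternoon halves represented by their midpoints), weighted by
#' segment duration.  Nighttime contributes nothing by default.
#'
#' @param gs_am,gs_pm Morning and afternoon stomatal conductance
#'   (mol m-2 s-1).
#' @param n_mf Leaf N mass concentration (kg N kg-1 leaf).
#' @param day One-row weather data frame (see [diurnal_drivers()]).
#' @param x_t Activation factor for the day.
#' @param params [model_params()].
#' @param opts [optim_opts()].
#' @return Daily fitness (mol C m-2 day-1).
#' @export
daily_fitness <- function(gs_am, gs_pm, n_mf, day, x_t = 1,
                          params = default_params(), opts = optim_opts()) {
  cpp_daily_fitness(gs_am, gs_pm, n_mf, weather_matrix(day[1, , drop = FALSE]),
                    x_t, params_for_kernel(params), unclass(opts))
}

#' Weekly fitness objective
#'
#' The step-1 objective of the two-step optimization: the sum over the block's
#' days of the daily fitness evaluated on the week-average day, with each
#' day's own activation factor.
#'
#' @param n_mf Leaf N mass concentration.
#' @param gs_am,gs_pm Morning/afternoon stomatal conductance.
#' @param days Weather data frame, one row per day of the block.
#' @param x_t Activation factor vector (one per day).
#' @param params [model_params()].
#' @param opts [optim_opts()].
#' @return Weekly fitness (mol C m-2 block-1).
#' @export
weekly_fitness <- function(n_mf, gs_am, gs_pm, days, x_t,
                           params = default_params(), opts = optim_opts()) {
  stopifnot(length(x_t) == nrow(days))
  cpp_weekly_fitness(n_mf, gs_am, gs_pm, weather_matrix(days),
                     as.numeric(x_t), params_for_kernel(params), unclass(opts))
}

#' Weekly fitness on a trait grid
#'
#' Evaluates [weekly_fitness()] on the full cartesian grid of candidate trait
#' values.  Shared sub-computations (canopy states per conductance,
#' assimilation per N-conductance pair) are factorized, so large grids are
#' cheap; the values are identical to pointwise evaluation.
#'
#' @param n_mf,gs_am,gs_pm Grid axis values.
#' @inheritParams weekly_fitness
#' @return A numeric array with dim `c(length(n_mf), length(gs_am),
#'   length(gs_pm))`.
#' @export
weekly_fitness_grid <- function(n_mf, gs_am, gs_pm, days, x_t,
                                params = default_params(), opts = optim_opts()) {
  stopifnot(length(x_t) == nrow(days))
  cpp_weekly_fitness_grid(as.numeric(n_mf), as.numeric(gs_am),
                          as.numeric(gs_pm), weather_matrix(days),
                          as.numeric(x_t), params_for_kernel(params),
                          unclass(opts))
}

#' Two-step weekly trait optimization
#'
#' Step 1 maximizes the weekly fitness over (N_mf, gs_am, gs_pm) on the
#' week-average day (deterministic coarse-grid seeding followed by a
#' projected Nelder-Mead polish from the top cells).  Step 2 fixes N_mf and
#' re-optimizes each day's conductance pair from the step-1 values.  Every
#' returned conductance is capped at that day's segment-specific critical
#' value, so accepted states satisfy P(psi_c) >= f_crit.
#'
#' @param days Weather data frame (1-7 rows; trailing partial weeks allowed).
#' @param x_t Activation factor vector, one per day.
#' @param params [model_params()].
#' @param opts [optim_opts()].
#' @return A tibble of class `trait_solution` with one row per day: columns
#'   `n_mf`, `gs_am`, `gs_pm`, `flag` (1 = clamped to the lower bound because
#'   the day is beyond the cavitation threshold), and attributes
#'   `fitness_weekly`, `step1_gs`.
#' @export
#' @examples
#' wk <- synthesize_weather(n_days = 7, seed = 1)
#' acc <- acclimation(wk$t_mean, photo_params())
#' optimize_week(wk, acc$x_t)
optimize_week <- function(days, x_t, params = default_params(),
                          opts = optim_opts()) {
  stopifnot(nrow(days) >= 1, length(x_t) == nrow(days))
  sol <- cpp_optimize_week(weather_matrix(days), as.numeric(x_t),
                           params_for_kernel(params), unclass(opts))
  out <- tibble::tibble(
    n_mf = rep(sol$n_mf, nrow(days)),
    gs_am = sol$gs_am, gs_pm = sol$gs_pm, flag = sol$flag
  )
  attr(out, "fitness_weekly") <- sol$fitness
  attr(out, "step1_gs") <- c(am = sol$step1_gs_am, pm = sol$step1_gs_pm)
  class(out) <- c("trait_solution", class(out))
  out
}
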