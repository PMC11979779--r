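test_that("CO2 compensation point follows the Arrhenius response", {
  p <- photo_params()
  # reference value at 298 K (24.85 degC)
  expect_equal(gamma_star(24.85, p), 4.17, tolerance = 1e-12)
  # zero activation energy makes it temperature-independent
  p0 <- photo_params(e_a_gamma = 1e-300)
  expect_equal(gamma_star(c(-5, 10, 35), p0), rep(4.17, 3), tolerance = 1e-9)
  # matches direct high-precision evaluation and is strictly increasing
  temps <- c(-5, 0, 10, 18.3, 25, 33)
  expect_equal(gamma_star(temps, p), oracle_gamma_star(temps, p),
               tolerance = 1e-12)
  expect_true(all(diff(gamma_star(seq(-10, 40, by = 0.5), p)) > 0))
})

test_that("Jmax temperature response peaks at the optimal temperature", {
  p <- photo_params()
  expect_equal(f_jmax_temp(305 - 273.15, p), 1, tolerance = 1e-12)
  temps <- c(5, 15, 25, 31.85, 40)
  expect_equal(f_jmax_temp(temps, p), oracle_f_jmax(temps, p),
               tolerance = 1e-12)
  f <- f_jmax_temp(c(15, 25, 31.85, 40), p)
  expect_true(f[1] < f[2])
  expect_true(f[2] < f[3])
  expect_true(f[3] > f[4])
  expect_true(all(f[-3] < 1))
})

test_that("acclimation recursion is first-order with the expected branches", {
  p <- photo_params(tau = 14.87, s_min = 0, delta_s = 18.29)
  # tau = 1: full update to the current temperature
  p1 <- photo_params(tau = 1)
  expect_equal(update_acclimation(3.7, 12, p1)$s_t, 12)
  # ramp branch values at the printed closed boundaries
  ramp <- photo_params(tau = 1, s_min = 4, delta_s = 10)
  expect_equal(update_acclimation(0, 4, ramp)$x_t, 0)
  expect_equal(update_acclimation(0, 9, ramp)$x_t, 0.5)
  expect_equal(update_acclimation(0, 14, ramp)$x_t, 1)
  expect_equal(update_acclimation(0, 20, ramp)$x_t, 1)
  expect_equal(update_acclimation(0, -3, ramp)$x_t, 0)
  # geometric convergence to a constant forcing: error shrinks by (1-1/tau)^k
  s0 <- 2; tt <- 16; k <- 25
  acc <- acclimation(rep(tt, k), p, s0 = s0)
  expect_equal(acc$s_t[k], tt - (tt - s0) * (1 - 1 / p$tau)^k,
               tolerance = 1e-12)
  # 63% of a step change is reached in about tau days
  step <- acclimation(rep(10, 60), p, s0 = 0)
  t63 <- which(step$s_t >= 0.632 * 10)[1]
  expect_lt(abs(t63 - p$tau), 1.5)
})

test_that("Jmax is proportional to leaf N and gated by the activation factor", {
  p <- photo_params()
  expect_equal(jmax(0, 20, 1, p), 0)
  expect_equal(jmax(0.02, 31.85, 1, p), 4e-4, tolerance = 1e-9)
  expect_equal(jmax(0.04, 17, 0.8, p), 2 * jmax(0.02, 17, 0.8, p))
  expect_equal(jmax(0.02, 17, 0, p), 0)
})

test_that("electron transport is the smaller quadratic root within its bounds", {
  p <- photo_params()
  expect_equal(electron_transport(0, 4e-4, 1, p), 0)
  # saturates at Jmax for large irradiance
  expect_equal(electron_transport(1e3, 4e-4, 1, p), 4e-4, tolerance = 1e-4)
  # matches an independent polynomial root-finder, incl. the aI = Jm case
  set.seed(11)
  for (i in 1:50) {
    i_inc <- runif(1, 1e-5, 2e-3); jm <- runif(1, 1e-5, 1e-3)
    expect_equal(electron_transport(i_inc, jm, 1, p),
                 oracle_etrans_root(p$alpha_season * i_inc, jm, p$theta_j),
                 tolerance = 1e-10)
  }
  jm <- 3e-4; i_eq <- jm / p$alpha_season
  expect_equal(electron_transport(i_eq, jm, 1, p),
               oracle_etrans_root(jm, jm, p$theta_j), tolerance = 1e-12)
  # never exceeds min(alpha I, Jmax); scales linearly with X_t
  set.seed(12)
  for (i in 1:200) {
    i_inc <- runif(1, 0, 3e-3); jm <- runif(1, 0, 1e-3); xt <- runif(1)
    j <- electron_transport(i_inc, jm, xt, p)
    expect_lte(j, xt * min(p$alpha_season * i_inc, jm) + 1e-15)
    expect_equal(j, xt * electron_transport(i_inc, jm, 1, p), tolerance = 1e-12)
  }
})

test_that("intercellular CO2 is the greater root and stays in [gamma, ca]", {
  p <- photo_params()
  # no demand: ci = ca; unconstrained supply: ci -> ca
  expect_equal(solve_ci(0.1, 40, 4.17, 0, p), 40)
  expect_equal(solve_ci(1e4, 40, 4.17, 1e-4, p), 40, tolerance = 1e-4)
  # bisection oracle on the supply/demand balance
  ci <- solve_ci(0.1, 40, 4.17, 1e-4, p)
  expect_equal(ci, oracle_ci(0.1, 40, 4.17, 1e-4), tolerance = 1e-8)
  set.seed(13)
  for (i in 1:100) {
    gs <- runif(1, 0.005, 0.5); ca <- runif(1, 38, 41)
    gam <- runif(1, 2, 6); j <- runif(1, 1e-6, 5e-4)
    ci <- solve_ci(gs, ca, gam, j, p)
    expect_gte(ci, gam - 1e-10)
    expect_lte(ci, ca + 1e-10)
    expect_equal(ci, oracle_ci(gs, ca, gam, j), tolerance = 1e-7)
  }
  expect_error(solve_ci(0.1, -1, 4.17, 1e-4, p),
               class = "canopyoptim_degenerate_input")
})

test_that("assimilation satisfies supply/demand consistency", {
  p <- photo_params()
  expect_equal(assimilation(0.1, 0, 15, 40, 0.02, 1, p)$a, 0)
  expect_equal(assimilation(0.1, 5e-4, 15, 40, 0, 1, p)$a, 0)
  # Fick supply equals co-limited demand at the solved ci (1000 random draws)
  set.seed(14)
  n <- 1000
  gs <- runif(n, 0.005, 0.5); i_inc <- runif(n, 1e-5, 2e-3)
  temp <- runif(n, -2, 35); ca <- runif(n, 38.5, 40.9)
  nmf <- runif(n, 0.007, 0.05); xt <- runif(n, 0.05, 1)
  out <- assimilation(gs, i_inc, temp, ca, nmf, xt, p)
  gam <- gamma_star(temp, p)
  a_demand <- out$j / 4 * (out$ci - gam) / (out$ci + 2 * gam)
  expect_lt(max(abs(out$a - a_demand) / pmax(out$a, 1e-12)), 1e-8)
})

test_that("assimilation is increasing and concave in stomatal conductance", {
  p <- photo_params()
  gs <- seq(0.005, 0.4, length.out = 200)
  a <- assimilation(gs, 8e-4, 18, 40, 0.025, 1, p)$a
  d1 <- diff(a)
  expect_true(all(d1 > 0))
  expect_true(all(diff(d1) < 1e-12))
})
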