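test_that("leaf transpiration is the linear Fick form", {
  expect_equal(leaf_transpiration(0, 1000), 0)
  expect_equal(leaf_transpiration(0.1, 1000), 1.6 * 0.1 * 1000 / 101325)
  expect_equal(leaf_transpiration(0.1, 2000), 2 * leaf_transpiration(0.1, 1000))
  expect_equal(leaf_transpiration(0.2, 800), 2 * leaf_transpiration(0.1, 800))
})

test_that("soil water potential follows the Brooks-Corey retention curve", {
  h <- hydraulic_params()
  expect_equal(soil_water_potential(h$theta_s, h), h$psi_a)
  # printed value at theta = 21.1%
  expect_equal(round(soil_water_potential(0.211, h), 2), -0.19)
  # direct evaluation at theta = 9.9% (printed -0.42, truncated toward zero)
  expect_equal(soil_water_potential(0.099, h), -0.098 * (0.093 / 0.404)^(-1),
               tolerance = 1e-12)
  expect_equal(round(soil_water_potential(0.099, h), 4), -0.4257)
  th <- seq(0.05, 0.41, by = 0.01)
  expect_true(all(diff(soil_water_potential(th, h)) > 0))
  expect_true(all(soil_water_potential(th, h) <= h$psi_a))
  expect_error(soil_water_potential(0.004, h), class = "canopyoptim_out_of_range")
  expect_error(soil_water_potential(0.45, h), class = "canopyoptim_out_of_range")
})

test_that("observed soil moisture ranges map onto the printed potential ranges", {
  h <- hydraulic_params()
  # fertilized stand: 9.9-29.8% <-> about -0.42..-0.13 MPa (values truncated
  # toward zero at two decimals)
  fert <- soil_water_potential(c(0.099, 0.298), h)
  expect_lt(abs(fert[1] - (-0.42)), 0.01)
  expect_lt(abs(fert[2] - (-0.13)), 0.01)
  # control stand: 6.7-21.1% <-> about -0.64..-0.19 MPa
  ctrl <- soil_water_potential(c(0.067, 0.211), h)
  expect_lt(abs(ctrl[1] - (-0.64)), 0.01)
  expect_lt(abs(ctrl[2] - (-0.19)), 0.01)
})

test_that("vulnerability curve has the sigmoid anchor points", {
  h <- hydraulic_params()
  expect_equal(vulnerability(0, h), 1)
  expect_equal(vulnerability(h$psi50_sc, h), 0.5)
  expect_equal(vulnerability(2 * h$psi50_sc, h), 0.5^(2^h$b_sc),
               tolerance = 1e-12)
  psi <- seq(0, -8, by = -0.1)
  expect_true(all(diff(vulnerability(psi, h)) < 0))
})

test_that("hydraulic cost factor is the linear discount to the lethal threshold", {
  h <- hydraulic_params()
  expect_equal(k_cost(h$k_sc_max, h), 1)
  expect_equal(k_cost(0.12 * h$k_sc_max, h), 0) # exhausted at 88% loss
  expect_equal(k_cost(0.56 * h$k_sc_max, h), 0.5)
})

test_that("canopy state solve has the exact zero-flux limits", {
  h <- hydraulic_params()
  st <- solve_canopy_state(0, 800, 0.15, 21, h)
  expect_equal(st$psi_c, st$psi_c_pd)
  expect_equal(st$k_sc, h$k_sc_max * vulnerability(st$psi_c_pd, h))
  # saturated soil, zero height, zero flux: psi_c = air-entry tension
  st0 <- solve_canopy_state(0, 500, h$theta_s, 0, h)
  expect_equal(st0$psi_c, h$psi_a)
})

test_that("fixed-point solver agrees with the quadrature + bisection oracle", {
  set.seed(101)
  worst <- 0
  n_ok <- 0
  for (i in 1:500) {
    k <- hydraulic_params(k_sc_max = runif(1, 3e-4, 1.2e-3))
    gs <- runif(1, 0.001, 0.15); vpd <- runif(1, 50, 1400)
    theta <- runif(1, 0.08, 0.3); H <- runif(1, 15, 25)
    gc <- critical_gs(vpd, theta, H, k, on_beyond = "na")
    if (is.na(gc) || gs > gc) next
    st <- solve_canopy_state(gs, vpd, theta, H, k)
    or <- oracle_canopy_state(gs, vpd, theta, H, k)
    worst <- max(worst, abs(st$psi_c - or$psi_c))
    n_ok <- n_ok + 1
  }
  expect_gt(n_ok, 300)
  expect_lt(worst, 1e-5)
})

test_that("solved state is Darcy-consistent and ordered", {
  h <- hydraulic_params()
  gs <- seq(0.005, 0.07, length.out = 12)
  st <- solve_canopy_state(gs, 900, 0.14, 21, h)
  # E = k_sc (psi_pd - psi_c), relative error < 1e-8
  expect_lt(max(abs(st$e_leaf - st$k_sc * (st$psi_c_pd - st$psi_c)) /
                  st$e_leaf), 1e-8)
  expect_true(all(st$psi_c <= st$psi_c_pd))
  expect_true(all(diff(st$psi_c) < 0))   # more flux, lower potential
  expect_true(all(diff(st$k_sc) < 0))
  expect_true(all(st$k_sc > 0 & st$k_sc <= h$k_sc_max))
})

test_that("runaway embolism is reported, not silently solved", {
  h <- hydraulic_params()
  st <- solve_canopy_state(0.5, 1400, 0.08, 21, h)
  expect_false(st$converged)
  expect_true(is.na(st$psi_c))
})

test_that("critical gs matches the dense-scan oracle and is monotone", {
  h <- hydraulic_params()
  g1 <- critical_gs(1000, 0.12, 21, h)
  expect_lt(abs(g1 - oracle_critical_gs(1000, 0.12, 21, h)), 1e-5)
  # P(psi_c) = f_crit at the returned conductance
  st <- solve_canopy_state(g1, 1000, 0.12, 21, h)
  expect_equal(vulnerability(st$psi_c, h), 0.12, tolerance = 1e-6)
  # decreasing in VPD, increasing in soil wetness
  expect_lt(critical_gs(1200, 0.12, 21, h), critical_gs(400, 0.12, 21, h))
  expect_lt(critical_gs(800, 0.1, 21, h), critical_gs(800, 0.2, 21, h))
  # VPD -> 0 returns the upper search bound
  expect_equal(critical_gs(0, 0.15, 21, h), 1)
  # beyond-critical precondition
  dry <- hydraulic_params(psi_a = -3.5)
  expect_error(critical_gs(800, 0.05, 21, dry),
               class = "canopyoptim_beyond_critical")
  expect_true(is.na(critical_gs(800, 0.05, 21, dry, on_beyond = "na")))
})
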