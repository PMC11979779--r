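test_that("fitness proxy has the exact degenerate limits", {
  params <- default_params("control")
  # no light: pure maintenance cost, non-positive
  dark <- fitness(0.05, 0.02, i_inc = 0, temp = 12, vpd = 500, ca = 40,
                  theta = 0.18, x_t = 1, params)
  expect_equal(dark$g, -(params$cost$n_r + params$cost$n_u) * dark$jmax)
  expect_lte(dark$g, 0)
  # no capacity: exactly zero (no gain, no cost)
  bare <- fitness(0.05, 0, i_inc = 5e-4, temp = 12, vpd = 500, ca = 40,
                  theta = 0.18, x_t = 1, params)
  expect_equal(bare$g, 0)
  # uptake cost is a pointwise penalty
  p0 <- default_params("fertilized"); p0$cost$n_u <- 0
  p1 <- default_params("fertilized"); p1$cost$n_u <- 0.012
  g0 <- fitness(0.05, 0.02, 5e-4, 15, 600, 40, 0.18, 1, p0)$g
  g1 <- fitness(0.05, 0.02, 5e-4, 15, 600, 40, 0.18, 1, p1)$g
  expect_gte(g0, g1)
})

test_that("diurnal radiation conserves the daily total and T stays in range", {
  day <- benign_week(1)
  day$t_min <- 8; day$t_max <- 22; day$t_mean <- 14; day$i0 <- 30; day$dt_g <- 18
  tt <- seq(0, day$dt_g, length.out = 20001)
  dd <- diurnal_drivers(day, tt)
  # trapezoid integral of I(t) over daylight equals I0 (mol m-2 day-1)
  total <- sum((dd$i[-1] + dd$i[-length(tt)]) / 2 * diff(tt * 3600))
  expect_equal(total, day$i0, tolerance = 1e-7)
  expect_true(all(dd$temp >= day$t_min & dd$temp <= day$t_max))
  expect_true(all(dd$vpd >= 0))
  # afternoon is warmer than morning (peak at 0.75 of daylight)
  mid <- diurnal_drivers(day, c(0.25, 0.75) * day$dt_g)
  expect_gt(mid$temp[2], mid$temp[1])
  # closed-form check of the radiation at the segment midpoints
  expect_equal(mid$i, rep(pi * 30 / (2 * 18 * 3600) * sin(pi / 4), 2),
               tolerance = 1e-12)
})

test_that("daily fitness reduces to the pure-cost value in darkness", {
  params <- default_params("control")
  opts <- optim_opts()
  day <- benign_week(1)
  day$i0 <- 0
  got <- daily_fitness(0.001, 0.001, 0.007, day, x_t = 0.5, params, opts)
  # expected: -(Nr+Nu) * sum of segment Jmax * duration
  mid <- diurnal_drivers(day, c(0.25, 0.75) * day$dt_g)
  jm <- jmax(0.007, mid$temp, 0.5, params$photo)
  want <- -(params$cost$n_r + params$cost$n_u) * sum(jm * day$dt_g / 2 * 3600)
  expect_equal(got, want, tolerance = 1e-10)
  expect_lt(got, 0)
})

test_that("a symmetric day yields equal morning and afternoon conductance", {
  day <- benign_week(1)
  day$t_min <- 14; day$t_max <- 14; day$t_mean <- 14
  sol <- optimize_week(day, x_t = 0.8)
  expect_equal(sol$gs_am, sol$gs_pm, tolerance = 1e-4)
})

test_that("a week of identical days returns identical day solutions", {
  wk <- benign_week(7)
  wk$i0 <- 31; wk$vpd <- 500
  sol <- optimize_week(wk, x_t = rep(0.7, 7))
  expect_equal(sol$gs_am, rep(sol$gs_am[1], 7), tolerance = 1e-6)
  expect_equal(sol$gs_pm, rep(sol$gs_pm[1], 7), tolerance = 1e-6)
  s1 <- attr(sol, "step1_gs")
  expect_equal(sol$gs_am[1], unname(s1["am"]), tolerance = 1e-3)
  expect_equal(sol$gs_pm[1], unname(s1["pm"]), tolerance = 1e-3)
})

test_that("returned traits respect bounds and the cavitation threshold", {
  params <- default_params("control")
  opts <- optim_opts()
  for (seed in 1:4) {
    wk <- synthesize_weather(n_days = 7, seed = seed)
    acc <- acclimation(wk$t_mean)
    sol <- optimize_week(wk, acc$x_t, params, opts)
    expect_true(all(sol$n_mf >= 0.007 & sol$n_mf <= 0.05))
    expect_true(all(sol$gs_am >= 0.001 & sol$gs_pm >= 0.001))
    for (d in 1:7) {
      st <- fitness(c(sol$gs_am[d], sol$gs_pm[d]), sol$n_mf[d],
                    5e-4, wk$t_mean[d], wk$vpd[d], wk$ca[d], wk$theta[d],
                    acc$x_t[d], params, opts)
      expect_true(all(vulnerability(st$psi_c, params$hydraulics) >= 0.12 - 1e-6))
    }
  }
})

test_that("weekly optimum carries a vanishing interior gradient", {
  params <- default_params("control")
  for (seed in c(3, 21, 101)) {
    wk <- synthesize_weather(n_days = 7, seed = seed)
    acc <- acclimation(wk$t_mean)
    sol <- optimize_week(wk, acc$x_t, params)
    x0 <- c(sol$n_mf[1], attr(sol, "step1_gs"))
    f0 <- weekly_fitness(x0[1], x0[2], x0[3], wk, acc$x_t, params)
    hs <- c(1e-6, 1e-7, 1e-7)
    grad <- vapply(1:3, function(j) {
      xp <- x0; xm <- x0
      xp[j] <- xp[j] + hs[j]; xm[j] <- xm[j] - hs[j]
      (weekly_fitness(xp[1], xp[2], xp[3], wk, acc$x_t, params) -
         weekly_fitness(xm[1], xm[2], xm[3], wk, acc$x_t, params)) /
        (2 * hs[j])
    }, numeric(1))
    # relative to the fitness scale per unit relative trait change
    rel <- abs(grad) * x0 / abs(f0)
    expect_lt(max(rel), 1e-6)
  }
})

test_that("raising the N uptake cost lowers the optimal leaf N", {
  wk <- benign_week(7)
  x <- rep(0.8, 7)
  p0 <- default_params("fertilized"); p0$cost$n_u <- 0
  p1 <- default_params("fertilized"); p1$cost$n_u <- 0.012
  n0 <- optimize_week(wk, x, p0)$n_mf[1]
  n1 <- optimize_week(wk, x, p1)$n_mf[1]
  expect_lt(n1, n0)
})

test_that("the two-step optimizer matches a coarse grid-search oracle", {
  # smoke-scale version of the acceptance-grade comparison
  params <- default_params("control")
  opts <- optim_opts()
  wk <- synthesize_weather(n_days = 7, seed = 21)
  acc <- acclimation(wk$t_mean)
  sol <- optimize_week(wk, acc$x_t, params, opts)
  ns <- seq(opts$nmf_min, opts$nmf_max, length.out = 15)
  gcrit <- sapply(1:2, function(s) {
    mid <- diurnal_drivers(dplyr::summarise_all(wk, mean),
                           c(0.25, 0.75) * mean(wk$dt_g))
    critical_gs(mid$vpd[s], mean(wk$theta), params$stand$height,
                params$hydraulics)
  })
  ga <- seq(opts$gs_min, gcrit[1], length.out = 15)
  gp <- seq(opts$gs_min, gcrit[2], length.out = 15)
  grid <- weekly_fitness_grid(ns, ga, gp, wk, acc$x_t, params, opts)
  step1 <- attr(sol, "step1_gs")
  f_opt <- weekly_fitness(sol$n_mf[1], step1["am"], step1["pm"], wk, acc$x_t,
                          params, opts)
  expect_gte(f_opt, max(grid) * (1 - 5e-3) - 5e-3 * abs(max(grid)))
})

test_that("grid evaluation equals pointwise evaluation of the same objective", {
  wk <- benign_week(5)
  x <- seq(0.5, 0.9, length.out = 5)
  ns <- c(0.01, 0.03); ga <- c(0.02, 0.05); gp <- c(0.03, 0.06)
  grid <- weekly_fitness_grid(ns, ga, gp, wk, x)
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    expect_equal(grid[i, j, k], weekly_fitness(ns[i], ga[j], gp[k], wk, x),
                 tolerance = 1e-12)
  }
})
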