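#' Laplace error-scale table
#'
#' Scale parameters (intercept `a`, slope `b` on the model prediction) and
#' data-type weights `w` of the Laplace error model, per observable and stand
#' treatment.  GPP scales are shared across treatments and may be estimated
#' alongside the model parameters; transpiration and leaf-N scales are fixed
#' from independent estimates.
#'
#' @return A tibble with columns `kind` (`"GPP"`, `"Ec"`, `"Nmf"`),
#'   `treatment`, `a`, `b`, `w`.
#' @export
laplace_scales <- function() {
  tibble::tribble(
    ~kind, ~treatment,    ~a,     ~b,   ~w,
    "GPP", "fertilized",  0.41,   0.08, 1.5,
    "GPP", "control",     0.41,   0.08, 1.5,
    "Ec",  "fertilized",  0.069,  0.15, 1.0,
    "Ec",  "control",     0.043,  0.18, 1.0,
    "Nmf", "fertilized",  0.0023, 0,    1.0,
    "Nmf", "control",     0.0023, 0,    1.0
  )
}

#' Weighted Laplace log-likelihood
#'
#' Sum over observations of
#' `w * (-log(2 (a + b m)) - |y - m| / (a + b m))`, the log of the Laplace
#' likelihood with a scale linear in the model prediction.  Additive over
#' points and invariant to their ordering.
#'
#' @param y Observed values.
#' @param m Matched model predictions (same length).
#' @param a,b Scale intercept and slope (recycled).
#' @param w Data-type weight (recycled).
#' @return The log-likelihood (scalar).
#' @export
#' @examples
#' laplace_loglik(2.1, 2.1, a = 0.41, b = 0.08) # -log(2 * scale)
laplace_loglik <- function(y, m, a, b, w = 1) {
  stopifnot(length(y) == length(m))
  s <- a + b * m
  if (any(s <= 0)) {
    rlang::abort("Laplace scale a + b * m must be positive",
                 class = "canopyoptim_invalid_scale")
  }
  sum(w * (-log(2 * s) - abs(y - m) / s))
}

#' Laplace random deviates
#'
#' @param n Number of deviates.
#' @param location,scale Location and scale (scale > 0).
#' @return Numeric vector.
#' @export
rlaplace <- function(n, location = 0, scale = 1) {
  stopifnot(all(scale > 0))
  u <- stats::runif(n) - 0.5
  location - scale * sign(u) * log(1 - 2 * abs(u))
}

#' Free-parameter scheme
#'
#' Declares which model parameters are estimated, their bounds, and whether
#' each is shared across the two stand treatments.  In the default scheme
#' every parameter is shared except the nitrogen-uptake cost `n_u` and the
#' maximum soil-canopy conductance `k_sc_max`, which are treatment specific.
#'
#' @param free Character vector of parameters to estimate; any of `"tau"`,
#'   `"delta_s"`, `"a_jmax"`, `"alpha_season"`, `"k_sc_max"`, `"n_u"`,
#'   `"a_gpp"`, `"b_gpp"`.
#' @param shared Named logical overrides of the default sharing map.
#' @return A tibble with columns `param`, `lower`, `upper`, `shared`.
#' @export
param_scheme <- function(free = c("tau", "delta_s", "a_jmax", "alpha_season",
                                  "k_sc_max", "n_u", "a_gpp", "b_gpp"),
                         shared = NULL) {
  # strictly positive scale parameters are searched on log10 scale
  all_params <- tibble::tribble(
    ~param,         ~lower, ~upper, ~shared, ~log,
    "tau",          2,      40,     TRUE,    FALSE,
    "delta_s",      1,      30,     TRUE,    FALSE,
    "a_jmax",       0.005,  0.1,    TRUE,    TRUE,
    "alpha_season", 0.05,   0.5,    TRUE,    FALSE,
    "k_sc_max",     1e-4,   5e-3,   FALSE,   TRUE,
    "n_u",          0,      0.05,   FALSE,   FALSE,
    "a_gpp",        0.01,   5,      TRUE,    FALSE,
    "b_gpp",        0,      1,      TRUE,    FALSE
  )
  bad <- setdiff(free, all_params$param)
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown parameters: ", paste(bad, collapse = ", ")),
                 class = "canopyoptim_bad_scheme")
  }
  out <- all_params[all_params$param %in% free, ]
  if (!is.null(shared)) {
    for (nm in names(shared)) out$shared[out$param == nm] <- shared[[nm]]
  }
  out
}

# expand a scheme into the flat optimization vector layout
scheme_layout <- function(scheme, treatments = c("fertilized", "control")) {
  if (!"log" %in% names(scheme)) scheme$log <- FALSE
  rows <- list()
  for (i in seq_len(nrow(scheme))) {
    trs <- if (scheme$shared[i]) "shared" else treatments
    for (tr in trs) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        param = scheme$param[i], treatment = tr,
        lower = scheme$lower[i], upper = scheme$upper[i],
        log = scheme$log[i])
    }
  }
  dplyr::bind_rows(rows)
}

param_slot <- list(
  tau = c("photo", "tau"), delta_s = c("photo", "delta_s"),
  a_jmax = c("photo", "a_jmax"), alpha_season = c("photo", "alpha_season"),
  s_min = c("photo", "s_min"), k_sc_max = c("hydraulics", "k_sc_max"),
  n_u = c("cost", "n_u")
)

# apply a flat parameter vector to per-treatment bundles + scales
apply_free_params <- function(x, layout, params, scales) {
  for (i in seq_len(nrow(layout))) {
    pm <- layout$param[i]; tr <- layout$treatment[i]; val <- x[i]
    if (pm %in% c("a_gpp", "b_gpp")) {
      col <- if (pm == "a_gpp") "a" else "b"
      scales[scales$kind == "GPP", col] <- val
    } else {
      slot <- param_slot[[pm]]
      targets <- if (tr == "shared") names(params) else tr
      for (t in targets) params[[t]][[slot[1]]][[slot[2]]] <- val
    }
  }
  list(params = params, scales = scales)
}

# per-treatment model predictions matched to the observation layout
predict_observables <- function(weather, params, opts) {
  if ("season" %in% names(weather)) {
    parts <- split(weather, weather$season)
    sim <- dplyr::bind_rows(lapply(parts, function(w) {
      run_simulation(w, params, opts)
    }))
  } else {
    sim <- run_simulation(weather, params, opts)
  }
  tibble::tibble(day = seq_len(nrow(sim)), gpp = sim$gpp_e, ec = sim$e_c,
                 n_mf = sim$n_mf)
}

# log-likelihood of an observation table given per-treatment predictions
obs_loglik <- function(obs, preds, scales) {
  ll <- 0
  for (tr in unique(obs$treatment)) {
    p <- preds[[tr]]
    o <- obs[obs$treatment == tr, ]
    for (kd in unique(o$kind)) {
      ok <- o[o$kind == kd, ]
      m <- switch(kd,
        GPP = p$gpp[ok$day],
        Ec = p$ec[ok$day],
        Nmf = rep(mean(p$n_mf), nrow(ok)),
        rlang::abort(paste0("unknown observation kind: ", kd)))
      sc <- scales[scales$kind == kd & scales$treatment == tr, ]
      if (nrow(sc) != 1) {
        rlang::abort("no unique error scale for this kind/treatment",
                     class = "canopyoptim_invalid_scale")
      }
      ll <- ll + laplace_loglik(ok$value, m, sc$a, sc$b, sc$w)
    }
  }
  ll
}

#' Differential evolution (rand/1/bin, seeded)
#'
#' Compact global maximizer over a box: classic DE/rand/1/bin with dithered
#' differential weight and reflection at the bounds.  Deterministic under a
#' fixed seed.
#'
#' @param fn Objective to maximize, taking a numeric vector.
#' @param lower,upper Bound vectors.
#' @param popsize Population size. Default `max(10, 4 * d)`.
#' @param maxiter Number of generations.
#' @param seed Integer seed.
#' @param cr Crossover probability. Default 0.9.
#' @param init Optional matrix of initial candidate rows.
#' @return A list with `par`, `value`, `trace` (best value per generation)
#'   and `n_evals`.
#' @export
diff_evolution <- function(fn, lower, upper, popsize = NULL, maxiter = 30,
                           seed = 1, cr = 0.9, init = NULL) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper >= lower))
  if (is.null(popsize)) popsize <- max(10, 4 * d)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))
  pop <- matrix(stats::runif(popsize * d, lower, upper), nrow = popsize,
                byrow = TRUE)
  if (!is.null(init)) {
    k <- min(nrow(init), popsize)
    pop[seq_len(k), ] <- init[seq_len(k), , drop = FALSE]
  }
  fit <- apply(pop, 1, fn)
  n_evals <- popsize
  trace <- numeric(maxiter)
  reflect <- function(x) {
    for (j in seq_len(d)) {
      if (x[j] < lower[j]) x[j] <- min(2 * lower[j] - x[j], upper[j])
      if (x[j] > upper[j]) x[j] <- max(2 * upper[j] - x[j], lower[j])
      x[j] <- min(max(x[j], lower[j]), upper[j])
    }
    x
  }
  for (g in seq_len(maxiter)) {
    for (i in seq_len(popsize)) {
      r <- sample(setdiff(seq_len(popsize), i), 3)
      Fw <- stats::runif(1, 0.5, 1)
      mutant <- pop[r[1], ] + Fw * (pop[r[2], ] - pop[r[3], ])
      jrand <- sample.int(d, 1)
      cross <- stats::runif(d) < cr
      cross[jrand] <- TRUE
      trial <- ifelse(cross, mutant, pop[i, ])
      trial <- reflect(trial)
      ftrial <- fn(trial)
      n_evals <- n_evals + 1
      if (ftrial >= fit[i]) {
        pop[i, ] <- trial
        fit[i] <- ftrial
      }
    }
    trace[g] <- max(fit)
  }
  best <- which.max(fit)
  list(par = pop[best, ], value = fit[best], trace = trace, n_evals = n_evals)
}

#' Calibration options
#'
#' @param popsize,maxiter Differential-evolution population size and
#'   generation count.
#' @param sim_opts [optim_opts()] used inside calibration model runs; the
#'   defaults trade a little solver precision for speed (coarser Simpson
#'   panels, single polish start).
#' @param fit_error_scales Estimate the GPP error scales alongside the model
#'   parameters. Default FALSE.
#' @return A named list of class `calib_opts`.
#' @export
calib_opts <- function(popsize = 16, maxiter = 35, polish_maxit = 300,
                       sim_opts = optim_opts(panels = 8, fp_tol = 1e-6,
                                             nstarts = 1, grid_n = 4,
                                             grid_g = 4, nm_maxit = 60,
                                             nm_tol = 1e-8),
                       fit_error_scales = FALSE) {
  structure(list(popsize = popsize, maxiter = maxiter,
                 polish_maxit = polish_maxit, sim_opts = sim_opts,
                 fit_error_scales = fit_error_scales), class = "calib_opts")
}

#' Fit model parameters by maximum Laplace likelihood
#'
#' Estimates the free parameters of the coupled model from observations of
#' daily GPP, daily canopy transpiration and per-treatment mean leaf N
#' concentration, by maximizing the weighted Laplace log-likelihood with a
#' seeded differential-evolution search.  Parameters flagged as shared in the
#' scheme take one value across treatments; the others are estimated per
#' treatment.
#'
#' @param obs Observation table with columns `kind` (`"GPP"`, `"Ec"`,
#'   `"Nmf"`), `treatment`, `day` (row index into that treatment's weather;
#'   ignored for `Nmf`, which is compared against the mean modeled leaf N)
#'   and `value`.
#' @param weather Named list of weather tibbles, one per treatment (an
#'   optional `season` column splits multi-season input; acclimation restarts
#'   per season).
#' @param params Named list of starting [model_params()] bundles per
#'   treatment; non-free parameters keep these values.
#' @param scheme [param_scheme()].
#' @param scales [laplace_scales()].
#' @param opts [calib_opts()].
#' @param seed Integer seed for the global search.
#' @return An object of class `canopyoptim_fit` with [tidy()] and [glance()]
#'   methods: estimates, achieved log-likelihood, optimizer trace, seed.
#' @export
fit_parameters <- function(obs, weather,
                           params = list(fertilized = default_params("fertilized"),
                                         control = default_params("control")),
                           scheme = param_scheme(), scales = laplace_scales(),
                           opts = calib_opts(), seed = 1) {
  stopifnot(all(c("kind", "treatment", "day", "value") %in% names(obs)))
  stopifnot(all(unique(obs$treatment) %in% names(weather)))
  if (!opts$fit_error_scales) {
    scheme <- scheme[!scheme$param %in% c("a_gpp", "b_gpp"), ]
  }
  layout <- scheme_layout(scheme, names(params))
  # scale parameters are searched on log10 scale
  to_search <- function(x) ifelse(layout$log, log10(x), x)
  to_natural <- function(x) ifelse(layout$log, 10^x, x)
  s_lower <- to_search(layout$lower)
  s_upper <- to_search(layout$upper)
  objective <- function(x) {
    ap <- apply_free_params(to_natural(x), layout, params, scales)
    preds <- lapply(names(ap$params), function(tr) {
      predict_observables(weather[[tr]], ap$params[[tr]], opts$sim_opts)
    })
    names(preds) <- names(ap$params)
    obs_loglik(obs, preds, ap$scales)
  }
  de <- diff_evolution(objective, lower = s_lower, upper = s_upper,
                       popsize = opts$popsize, maxiter = opts$maxiter,
                       seed = seed)
  best <- de$par
  value <- de$value
  n_evals <- de$n_evals
  if (opts$polish_maxit > 0) {
    # local simplex polish of the global-search result, box-projected; two
    # restarts (a fresh simplex after the first pass escapes stalls)
    clamp <- function(x) pmin(pmax(x, s_lower), s_upper)
    for (pass in 1:2) {
      pol <- stats::optim(best, function(x) objective(clamp(x)),
                          method = "Nelder-Mead",
                          control = list(fnscale = -1,
                                         maxit = ceiling(opts$polish_maxit / 2),
                                         parscale = s_upper - s_lower))
      n_evals <- n_evals + pol$counts[["function"]]
      if (pol$value > value) {
        best <- clamp(pol$par)
        value <- pol$value
      }
    }
  }
  estimates <- layout
  estimates$estimate <- to_natural(best)
  structure(list(estimates = estimates, loglik = value,
                 trace = de$trace, n_evals = n_evals, seed = seed,
                 scheme = scheme, params = params, scales = scales),
            class = "canopyoptim_fit")
}

#' @export
print.canopyoptim_fit <- function(x, ...) {
  cat("<canopyoptim_fit>  logLik:", format(x$loglik, digits = 6),
      " evals:", x$n_evals, " seed:", x$seed, "\n")
  print(x$estimates)
  invisible(x)
}

#' Validation metrics
#'
#' Root-mean-square error, mean absolute percentage error (in percent,
#' zero-valued observations excluded with a count) and the coefficient of
#' determination.
#'
#' @param obs Observed values (length >= 2, not all equal).
#' @param pred Matched predictions.
#' @return A one-row tibble: `rmse`, `mape`, `r2`, `n`, `n_mape_excluded`.
#' @export
#' @examples
#' validation_metrics(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))
validation_metrics <- function(obs, pred) {
  stopifnot(length(obs) == length(pred), length(obs) >= 2)
  if (stats::sd(obs) == 0) {
    rlang::abort("R2 undefined: observations are constant",
                 class = "canopyoptim_degenerate_input")
  }
  rmse <- sqrt(mean((obs - pred)^2))
  nz <- obs != 0
  mape <- if (any(nz)) 100 * mean(abs((obs[nz] - pred[nz]) / obs[nz])) else NA_real_
  r2 <- 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  tibble::tibble(rmse = rmse, mape = mape, r2 = r2, n = length(obs),
                 n_mape_excluded = sum(!nz))
}

#' Repeated random holdout splits
#'
#' Uniform random selection without replacement of a validation fraction,
#' repeated with distinct sub-seeds; train and validation sets are disjoint
#' and exhaustive.
#'
#' @param n Number of data points.
#' @param fraction Validation fraction in (0, 1). Default 0.2.
#' @param repeats Number of splits. Default 10.
#' @param seed Integer seed.
#' @param size Absolute validation-set size overriding
#'   `round(fraction * n)`.
#' @return A list of length `repeats`; each element has `train` and
#'   `validation` integer index vectors.
#' @export
holdout_protocol <- function(n, fraction = 0.2, repeats = 10, seed = 1,
                             size = NULL) {
  if (is.null(size)) {
    stopifnot(fraction > 0, fraction < 1)
    size <- round(fraction * n)
  }
  stopifnot(size >= 1, size < n)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  lapply(seq_len(repeats), function(r) {
    set.seed(as.integer(seed) + r - 1L)
    val <- sort(sample.int(n, size))
    list(train = setdiff(seq_len(n), val), validation = val)
  })
}

#' Simulate noisy observations from the model
#'
#' Generates an observation table by running the model at known parameters
#' and adding Laplace noise with the error-scale table: one daily GPP and one
#' daily transpiration observation per simulated day, and one seasonal-mean
#' leaf N observation per treatment.  Used by the parameter-recovery
#' machinery; also a convenient synthetic test-bed.
#'
#' @param weather Named list of weather tibbles per treatment.
#' @param params Named list of [model_params()] per treatment (the truth).
#' @param scales [laplace_scales()].
#' @param seed Integer seed for the noise.
#' @param sim_opts [optim_opts()] for the model runs.
#' @return An observation tibble (`kind`, `treatment`, `day`, `value`); the
#'   attribute `"truth"` carries the noise-free predictions.
#' @export
simulate_observations <- function(weather, params, scales = laplace_scales(),
                                  seed = 1, sim_opts = optim_opts()) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))
  out <- list()
  truth <- list()
  for (tr in names(weather)) {
    p <- predict_observables(weather[[tr]], params[[tr]], sim_opts)
    truth[[tr]] <- p
    sc <- function(kind) scales[scales$kind == kind & scales$treatment == tr, ]
    sg <- sc("GPP"); se <- sc("Ec"); sn <- sc("Nmf")
    out[[length(out) + 1]] <- tibble::tibble(
      kind = "GPP", treatment = tr, day = p$day,
      value = p$gpp + rlaplace(nrow(p), 0, sg$a + sg$b * p$gpp))
    out[[length(out) + 1]] <- tibble::tibble(
      kind = "Ec", treatment = tr, day = p$day,
      value = p$ec + rlaplace(nrow(p), 0, se$a + se$b * p$ec))
    mn <- mean(p$n_mf)
    out[[length(out) + 1]] <- tibble::tibble(
      kind = "Nmf", treatment = tr, day = NA_integer_,
      value = mn + rlaplace(1, 0, sn$a + sn$b * mn))
  }
  res <- dplyr::bind_rows(out)
  attr(res, "truth") <- truth
  res
}

#' Ablation experiments
#'
#' Re-runs the model with one source of variation removed and reports the
#' effect against the baseline run:
#' * `static_nmf`: leaf N frozen at its baseline season median, per treatment;
#' * `shared_nmf`: one leaf N value (mean of the two treatment medians) for
#'   both treatments;
#' * `shared_nu`: one nitrogen-uptake cost for both treatments
#'   (`nu_shared`, default the mean of the two);
#' * `static_theta`: soil water content replaced by its season mean, per
#'   treatment.
#'
#' When observations are supplied, the report compares R2 against them;
#' otherwise the baseline predictions serve as the reference.
#'
#' @param mode One of `"static_nmf"`, `"shared_nmf"`, `"shared_nu"`,
#'   `"static_theta"`.
#' @param weather Named list of weather tibbles per treatment.
#' @param params Named list of fitted [model_params()] per treatment.
#' @param obs Optional observation table (as in [fit_parameters()]).
#' @param nu_shared Shared uptake cost for `shared_nu`.
#' @param sim_opts [optim_opts()].
#' @return A tibble with one row per treatment: mean predicted leaf N under
#'   baseline and ablation, and R2 of GPP and transpiration for both runs
#'   with their differences.
#' @export
run_ablation <- function(mode = c("static_nmf", "shared_nmf", "shared_nu",
                                  "static_theta"),
                         weather, params, obs = NULL, nu_shared = NULL,
                         sim_opts = optim_opts()) {
  mode <- match.arg(mode)
  trs <- names(weather)
  base <- lapply(trs, function(tr) predict_observables(weather[[tr]],
                                                       params[[tr]], sim_opts))
  names(base) <- trs
  med_nmf <- vapply(base, function(b) stats::median(b$n_mf), numeric(1))
  abl <- lapply(trs, function(tr) {
    w <- weather[[tr]]
    p <- params[[tr]]
    fixed <- NULL
    if (mode == "static_nmf") fixed <- med_nmf[[tr]]
    if (mode == "shared_nmf") fixed <- mean(med_nmf)
    if (mode == "shared_nu") {
      p$cost$n_u <- if (is.null(nu_shared)) {
        mean(vapply(params, function(q) q$cost$n_u, numeric(1)))
      } else nu_shared
    }
    if (mode == "static_theta") w$theta <- mean(w$theta)
    if (is.null(fixed)) {
      predict_observables(w, p, sim_opts)
    } else {
      if ("season" %in% names(w)) {
        sim <- dplyr::bind_rows(lapply(split(w, w$season), function(ws) {
          run_simulation(ws, p, sim_opts, fixed_nmf = fixed)
        }))
      } else {
        sim <- run_simulation(w, p, sim_opts, fixed_nmf = fixed)
      }
      tibble::tibble(day = seq_len(nrow(sim)), gpp = sim$gpp_e, ec = sim$e_c,
                     n_mf = sim$n_mf)
    }
  })
  names(abl) <- trs
  ref_for <- function(tr, kind) {
    if (!is.null(obs)) {
      o <- obs[obs$treatment == tr & obs$kind == kind, ]
      list(day = o$day, value = o$value)
    } else {
      b <- base[[tr]]
      v <- if (kind == "GPP") b$gpp else b$ec
      list(day = b$day, value = v)
    }
  }
  purrr::map_dfr(trs, function(tr) {
    rg <- ref_for(tr, "GPP"); re <- ref_for(tr, "Ec")
    r2 <- function(ref, p, col) {
      validation_metrics(ref$value, p[[col]][ref$day])$r2
    }
    tibble::tibble(
      mode = mode, treatment = tr,
      mean_nmf_baseline = mean(base[[tr]]$n_mf),
      mean_nmf_ablation = mean(abl[[tr]]$n_mf),
      r2_gpp_baseline = r2(rg, base[[tr]], "gpp"),
      r2_gpp_ablation = r2(rg, abl[[tr]], "gpp"),
      r2_ec_baseline = r2(re, base[[tr]], "ec"),
      r2_ec_ablation = r2(re, abl[[tr]], "ec")
    ) |>
      dplyr::mutate(delta_r2_gpp = .data$r2_gpp_ablation - .data$r2_gpp_baseline,
                    delta_r2_ec = .data$r2_ec_ablation - .data$r2_ec_baseline)
  })
}
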