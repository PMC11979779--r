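#' Tidy a calibration fit
#'
#' @param x A `canopyoptim_fit` from [fit_parameters()].
#' @param ... Unused.
#' @return A tibble with one row per estimated parameter slot: `param`,
#'   `treatment` (`"shared"` or the stand treatment), `estimate`, `lower`,
#'   `upper`.
#' @export
tidy.canopyoptim_fit <- function(x, ...) {
  dplyr::relocate(x$estimates, "param", "treatment", "estimate", "lower",
                  "upper")
}

#' Glance at a calibration fit
#'
#' @inheritParams tidy.canopyoptim_fit
#' @return A one-row tibble: `logLik`, `n_params`, `n_evals`, `seed`.
#' @export
glance.canopyoptim_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n_params = nrow(x$estimates),
                 n_evals = x$n_evals, seed = x$seed)
}
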