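#' Plot a simulated season
#'
#' Faceted daily time series of ecosystem GPP, canopy transpiration, the
#' optimized traits and the minimum canopy water potential.
#'
#' @param object A `canopy_simulation` from [run_simulation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.canopy_simulation <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if (!"date" %in% names(df)) df$date <- seq_len(nrow(df))
  df$gs <- (df$gs_am + df$gs_pm) / 2
  long <- tidyr::pivot_longer(
    df[, c("date", "gpp_e", "e_c", "n_mf", "gs", "psi_c_min")],
    -"date", names_to = "variable", values_to = "value")
  long$variable <- factor(long$variable,
    levels = c("gpp_e", "e_c", "n_mf", "gs", "psi_c_min"),
    labels = c("GPP[e]~(g~C~m^-2~d^-1)", "E[c]~(mm~d^-1)",
               "N[mf]~(kg~kg^-1)", "g[s]~(mol~m^-2~s^-1)",
               "psi[c]~(MPa)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$date, y = .data$value)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::facet_wrap(~variable, scales = "free_y", ncol = 1,
                        labeller = ggplot2::label_parsed) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot trait-weather correlations
#'
#' Tile panel of Pearson correlations between optimized plant variables and
#' weather drivers.
#'
#' @param corr A [trait_weather_correlations()] table.
#' @return A ggplot object.
#' @export
plot_trait_correlations <- function(corr) {
  ggplot2::ggplot(corr, ggplot2::aes(x = .data$driver, y = .data$trait,
                                     fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$r), "NA", sprintf("%.2f", .data$r)))) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", limits = c(-1, 1)) +
    ggplot2::labs(x = "weather driver", y = "plant variable",
                  fill = "Pearson r") +
    ggplot2::theme_minimal()
}

#' Plot a calibration trace
#'
#' Best log-likelihood per differential-evolution generation.
#'
#' @param fit A `canopyoptim_fit`.
#' @return A ggplot object.
#' @export
plot_fit_trace <- function(fit) {
  df <- tibble::tibble(generation = seq_along(fit$trace), logLik = fit$trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$logLik)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "generation", y = "best log-likelihood") +
    ggplot2::theme_minimal()
}
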