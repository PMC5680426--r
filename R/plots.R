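#' Plot a fitted dose-response curve over the observed mortality fractions
#'
#' @param object A [fit_binomial_glm()] fit with an intercept + concentration
#'   design.
#' @param n_grid Number of concentrations in the prediction grid.
#' @param ... Unused.
#' @return A ggplot: observed per-unit mortality fractions, the fitted logit
#'   curve, and a dashed marker at the LC50.
#' @export
autoplot.tox_glm <- function(object, n_grid = 200, ...) {
  d <- object$data
  grid <- tibble::tibble(
    conc_mg_l = seq(min(d$conc_mg_l), max(d$conc_mg_l), length.out = n_grid)
  )
  b <- object$coefficients
  grid$p <- plogis(b[1] + b[2] * grid$conc_mg_l)
  lc <- tryCatch(estimate_lc50(object)$lc50, error = function(e) NA_real_)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$conc_mg_l)) +
    ggplot2::geom_jitter(
      ggplot2::aes(y = .data$n_dead / .data$n_exposed),
      width = diff(range(d$conc_mg_l)) / 80, height = 0.01, alpha = 0.5
    ) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$p), linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = lc, linetype = "dashed") +
    ggplot2::labs(
      x = "Chloride concentration (mg/L)", y = "Mortality fraction",
      title = "Binomial logit dose-response",
      subtitle = if (is.finite(lc)) sprintf("LC50 = %.0f mg/L", lc) else NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-group phylogenetic-signal statistics
#'
#' Dot plot of Pagel's lambda and Blomberg's K for each analysed taxonomic
#' group, filled by whether the group's test is significant at `alpha`.
#'
#' @param signal Tibble from [run_signal_suite()].
#' @param alpha Significance threshold used for the fill (default 0.05).
#' @return A ggplot.
#' @export
plot_signal_results <- function(signal, alpha = 0.05) {
  stopifnot(is.data.frame(signal), all(c("group", "lambda", "K") %in% names(signal)))
  long <- signal |>
    dplyr::transmute(
      group = .data$group,
      lambda = .data$lambda, K = .data$K,
      p_lambda = .data$p_lambda, p_K = .data$p_K
    ) |>
    tidyr::pivot_longer(c("lambda", "K"),
      names_to = "statistic", values_to = "value"
    ) |>
    dplyr::mutate(
      p = ifelse(.data$statistic == "lambda", .data$p_lambda, .data$p_K),
      significant = .data$p < alpha
    )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$value, y = .data$group, fill = .data$significant
  )) +
    ggplot2::geom_point(shape = 21, size = 3) +
    ggplot2::facet_wrap(~ .data$statistic, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "black", `FALSE` = "white")) +
    ggplot2::labs(
      x = "Statistic value", y = NULL, fill = sprintf("p < %.2f", alpha),
      title = "Phylogenetic signal of chloride LC50 by taxonomic group"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
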