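#' Tidy a binomial dose-response GLM
#'
#' @param x A [fit_binomial_glm()] fit.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @export
tidy.tox_glm <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  z <- x$coefficients / se
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = unname(z),
    p.value = 2 * stats::pnorm(-abs(unname(z)))
  )
}

#' @rdname tidy.tox_glm
#' @export
glance.tox_glm <- function(x, ...) {
  tibble::tibble(
    logLik = x$log_lik, AIC = x$aic, deviance = x$deviance,
    df.residual = x$n_obs - length(x$coefficients),
    nobs = x$n_obs, n_iter = x$n_iter, converged = x$converged
  )
}

#' Tidy a Laplace-fitted binomial mixed model
#'
#' Fixed effects are reported on the raw mg/L concentration scale; random
#' effect rows carry the estimated logit-scale SDs (broom.mixed layout).
#'
#' @param x A [fit_glmm_laplace()] fit.
#' @param effects Which rows to return: `"fixed"`, `"ran_pars"`, or both.
#' @param ... Unused.
#' @return Tibble with `effect`, `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
tidy.tox_glmm <- function(x, effects = c("fixed", "ran_pars"), ...) {
  effects <- match.arg(effects, several.ok = TRUE)
  fixed <- x$fixed_effects |>
    dplyr::transmute(
      effect = "fixed", term = .data$term, estimate = .data$estimate,
      std.error = .data$se, statistic = .data$z, p.value = .data$p_value
    )
  ran <- tibble::tibble(
    effect = "ran_pars",
    term = paste0("sd__", names(x$sigma)),
    estimate = unname(x$sigma),
    std.error = NA_real_, statistic = NA_real_, p.value = NA_real_
  )
  out <- dplyr::bind_rows(
    if ("fixed" %in% effects) fixed,
    if ("ran_pars" %in% effects) ran
  )
  out
}

#' @rdname tidy.tox_glmm
#' @export
glance.tox_glmm <- function(x, ...) {
  tibble::tibble(
    logLik = x$log_lik, AIC = x$aic, nobs = x$n_obs, df = x$k,
    sigma_pond = x$sigma[["pond"]], sigma_unit = x$sigma[["unit"]],
    boundary = x$boundary_flag, converged = x$converged
  )
}

#' @export
generics::tidy

#' @export
generics::glance
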