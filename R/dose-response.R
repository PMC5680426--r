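#' Read an acute-exposure mortality CSV
#'
#' Expects columns `pond_id, type, conc_mg_l, replicate, n_exposed, n_dead`
#' with `type` in `{roadside, woodland}` — one row per experimental unit
#' (container) of the acute-exposure design.
#'
#' @param path Path to the CSV file.
#' @return A validated tibble.
#' @export
read_mortality_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("Mortality CSV not found: %s", path))
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_mortality(tbl)
}

validate_mortality <- function(data) {
  data <- tibble::as_tibble(data)
  needed <- c("pond_id", "type", "conc_mg_l", "replicate", "n_exposed", "n_dead")
  miss <- setdiff(needed, names(data))
  if (length(miss)) {
    abort(sprintf("Mortality table is missing columns: %s.", paste(miss, collapse = ", ")))
  }
  if (any(data$n_exposed <= 0)) abort("n_exposed must be > 0.")
  if (any(data$n_dead < 0 | data$n_dead > data$n_exposed)) {
    abort("Need 0 <= n_dead <= n_exposed in every row.")
  }
  if (any(!is.finite(data$conc_mg_l)) || any(data$conc_mg_l < 0)) {
    abort("Concentrations must be finite and >= 0 (mg/L).")
  }
  key <- paste(data$pond_id, data$conc_mg_l, data$replicate)
  if (anyDuplicated(key)) abort("Duplicate (pond, concentration, replicate) rows.")
  data
}

data_fingerprint <- function(data) {
  c(
    n = nrow(data),
    dead = sum(data$n_dead),
    exposed = sum(data$n_exposed),
    conc = round(sum(data$conc_mg_l), 6)
  )
}

binom_loglik <- function(y, n, p) {
  p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
  sum(lchoose(n, y) + ifelse(y > 0, y * log(p), 0) +
    ifelse(y < n, (n - y) * log1p(-p), 0))
}

# numerically stable log(1 + exp(x))
log1pexp <- function(x) {
  ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))
}

binom_deviance <- function(y, n, p) {
  mu <- n * p
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  t2 <- ifelse(y < n, (n - y) * log((n - y) / (n - mu)), 0)
  2 * sum(t1 + t2)
}

#' Fit a binomial logit dose-response GLM by IRLS
#'
#' Maximum-likelihood logistic regression on aggregated binomial counts
#' (`n_dead` of `n_exposed`), fitted by iteratively reweighted least squares.
#' Convergence is declared when the relative deviance change falls below
#' `1e-10` (at most 100 iterations); the coefficient covariance is the
#' inverse Fisher information at the optimum.  Complete separation is
#' detected as a diverging linear predictor and raised as an error.
#'
#' @param data Mortality tibble (see [read_mortality_csv()]).
#' @param predictors One-sided formula over columns of `data`; default
#'   `~ conc_mg_l` gives the intercept + concentration model used for LC50
#'   estimation.
#' @return A `tox_glm` object: coefficients, `vcov`, `log_lik`, `deviance`,
#'   `aic`, `n_obs`, `converged`, `n_iter`.  Supports [tidy()], [glance()],
#'   [estimate_lc50()], [compare_aic()].
#' @examples
#' toy <- tibble::tibble(
#'   pond_id = "p1", type = "woodland", conc_mg_l = c(2, 4, 6),
#'   replicate = 1:3, n_exposed = 10, n_dead = c(1, 5, 9)
#' )
#' fit <- fit_binomial_glm(toy)
#' estimate_lc50(fit) # exactly 4 by symmetry
#' @export
fit_binomial_glm <- function(data, predictors = ~conc_mg_l) {
  data <- validate_mortality(data)
  X <- model.matrix(predictors, data = data)
  if (qr(X)$rank < ncol(X)) abort("Design matrix is rank deficient.")
  y <- data$n_dead
  n <- data$n_exposed
  if (length(unique(data$conc_mg_l)) < 2) abort("Need >= 2 distinct concentrations.")

  p <- (y + 0.5) / (n + 1)
  eta <- qlogis(p)
  dev <- binom_deviance(y, n, p)
  beta <- NULL
  converged <- FALSE
  it <- 0
  while (it < 100) {
    it <- it + 1
    w <- n * p * (1 - p)
    z <- eta + (y / n - p) / (p * (1 - p))
    XtW <- t(X * w)
    beta <- solve(XtW %*% X, XtW %*% z)
    eta <- drop(X %*% beta)
    if (max(abs(eta)) > 30) {
      abort(paste0(
        "Complete or quasi-complete separation: the linear predictor is ",
        "diverging (|eta| > 30); the mortality pattern is degenerate at the ",
        "observed doses."
      ))
    }
    p <- plogis(eta)
    dev_new <- binom_deviance(y, n, p)
    if (abs(dev_new - dev) / (abs(dev) + 0.1) < 1e-10) {
      converged <- TRUE
      dev <- dev_new
      break
    }
    dev <- dev_new
  }
  if (!converged) abort("IRLS did not converge in 100 iterations.")

  w <- n * p * (1 - p)
  info <- t(X * w) %*% X
  vc <- solve(info)
  ll <- binom_loglik(y, n, p)
  k <- ncol(X)
  structure(
    list(
      coefficients = setNames(drop(beta), colnames(X)),
      vcov = vc,
      log_lik = ll,
      deviance = dev,
      aic = 2 * k - 2 * ll,
      n_obs = nrow(data),
      converged = converged,
      n_iter = it,
      predictors = predictors,
      fingerprint = data_fingerprint(data),
      data = data
    ),
    class = "tox_glm"
  )
}

#' @export
print.tox_glm <- function(x, ...) {
  cat("Binomial logit GLM (IRLS), n =", x$n_obs, "units\n")
  print(round(x$coefficients, 6))
  cat(
    "logLik:", format(x$log_lik, digits = 8),
    " deviance:", format(x$deviance, digits = 8),
    " AIC:", format(x$aic, digits = 8), "\n"
  )
  invisible(x)
}

#' LC50 with delta-method confidence interval
#'
#' For an intercept + concentration logit fit, the median lethal
#' concentration is `-b0/b1`; its standard error follows from the first-order
#' (delta-method) expansion
#' `var = (v00 + 2*LC50*v01 + LC50^2*v11) / b1^2`, and the 95% interval uses
#' the normal quantile 1.959964.
#'
#' @param fit A converged [fit_binomial_glm()] fit with exactly an intercept
#'   and one dose coefficient.
#' @param population_label Optional label (e.g. `"roadside"`) carried into
#'   the output.
#' @return One-row tibble: `population`, `lc50`, `se`, `ci_low`, `ci_high`
#'   (all mg/L), `slope`, `n_obs`.
#' @export
estimate_lc50 <- function(fit, population_label = NA_character_) {
  stopifnot(inherits(fit, "tox_glm"))
  if (!fit$converged) abort("Fit did not converge.")
  if (length(fit$coefficients) != 2 || names(fit$coefficients)[1] != "(Intercept)") {
    abort("LC50 requires an intercept + single-dose-term fit.")
  }
  b0 <- fit$coefficients[[1]]
  b1 <- fit$coefficients[[2]]
  z_slope <- b1 / sqrt(fit$vcov[2, 2])
  if (abs(b1) < 1e-12 || abs(z_slope) < 1e-6) {
    abort("Dose slope is indistinguishable from 0: LC50 unidentified.")
  }
  lc50 <- -b0 / b1
  v <- fit$vcov
  se <- sqrt((v[1, 1] + 2 * lc50 * v[1, 2] + lc50^2 * v[2, 2]) / b1^2)
  zq <- 1.959964
  tibble::tibble(
    population = population_label,
    lc50 = lc50, se = se,
    ci_low = lc50 - zq * se, ci_high = lc50 + zq * se,
    slope = b1, n_obs = fit$n_obs
  )
}

#' Rank fitted models by AIC
#'
#' Accepts any mix of [fit_binomial_glm()] and [fit_glmm_laplace()] fits on
#' the same data rows and returns the usual selection table.
#'
#' @param fits Named list of fits.
#' @return Tibble `(model, k, log_lik, aic, delta_aic)` sorted ascending by
#'   AIC.
#' @export
compare_aic <- function(fits) {
  if (!length(fits)) abort("No fits supplied.")
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_along(fits))
  fps <- lapply(fits, function(f) f$fingerprint)
  if (!all(vapply(fps, function(fp) isTRUE(all.equal(fp, fps[[1]])), logical(1)))) {
    abort("Fits were not computed on identical data rows (fingerprint mismatch).")
  }
  tbl <- purrr::imap(fits, function(f, nm) {
    k <- if (inherits(f, "tox_glmm")) f$k else length(f$coefficients)
    tibble::tibble(model = nm, k = k, log_lik = f$log_lik, aic = f$aic)
  }) |> dplyr::bind_rows()
  tbl |>
    dplyr::arrange(.data$aic) |>
    dplyr::mutate(delta_aic = .data$aic - min(.data$aic))
}

#' Convert a road-salt dose to chloride concentration
#'
#' `Cl mg/L = NaCl g/L * 1000 * (35.453 / 58.443)` (atomic masses of Cl and
#' NaCl), optionally rounded to a stated granularity — acute-exposure designs
#' typically report doses to the nearest 100 mg/L Cl.
#'
#' @param nacl_g_per_l Non-negative NaCl dose(s) in g/L.
#' @param round_to Optional rounding granularity in mg/L (e.g. 100), or
#'   `NULL` for no rounding.
#' @return Chloride concentration(s) in mg/L.
#' @examples
#' nacl_to_chloride(c(6.3, 8.4, 10.7, 12), round_to = 100)
#' @export
nacl_to_chloride <- function(nacl_g_per_l, round_to = NULL) {
  if (any(!is.finite(nacl_g_per_l)) || any(nacl_g_per_l < 0)) {
    abort("NaCl dose must be finite and >= 0.")
  }
  cl <- nacl_g_per_l * 1000 * (35.453 / 58.443)
  if (!is.null(round_to)) cl <- round(cl / round_to) * round_to
  cl
}
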