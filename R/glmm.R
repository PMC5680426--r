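# Laplace-approximate ML for the logit-binomial mixed model
#
#   logit p_ij = x_ij' beta + b_pond(i) + b_unit(ij)
#   b_pond ~ N(0, sigma_pond^2),  b_unit ~ N(0, sigma_unit^2) (observation
#   level, absorbing overdispersion), all independent.
#
# The marginal likelihood integrates the random effects out; we approximate
# the integral by Laplace's method: an inner Newton loop finds the joint mode
# b-hat of the penalized log-likelihood, and
#   logL ~= l(y|b-hat) - b-hat'D^-1 b-hat/2 - log det(D)/2 - log det(H)/2
# with H = Z'WZ + D^-1 the negative Hessian at the mode.

glmm_design <- function(data, predictors) {
  X <- model.matrix(predictors, data = data)
  if (qr(X)$rank < ncol(X)) abort("Fixed-effect design matrix is rank deficient.")
  pond <- factor(data$pond_id)
  n <- nrow(data)
  Z_pond <- model.matrix(~ pond - 1)
  list(X = X, Z_pond = unname(Z_pond), n_pond = nlevels(pond), n = n)
}

# Mode-finding Newton loop + Laplace log-likelihood for fixed (beta, sigmas).
# Blocks with sigma below `sigma_tol` are treated as absent (b = 0).
laplace_eval <- function(y, n, X, Z_pond, beta, sigma_pond, sigma_unit,
                         b_start = NULL, sigma_tol = 1e-8) {
  nobs <- length(y)
  use_pond <- sigma_pond > sigma_tol
  use_unit <- sigma_unit > sigma_tol
  Zs <- list()
  dvar <- numeric(0)
  if (use_pond) {
    Zs <- c(Zs, list(Z_pond))
    dvar <- c(dvar, rep(sigma_pond^2, ncol(Z_pond)))
  }
  if (use_unit) {
    Zs <- c(Zs, list(diag(nobs)))
    dvar <- c(dvar, rep(sigma_unit^2, nobs))
  }
  offset <- drop(X %*% beta)
  const <- sum(lchoose(n, y))
  if (!length(Zs)) {
    p <- plogis(offset)
    return(list(log_lik = binom_loglik(y, n, p), b = numeric(0)))
  }
  Z <- do.call(cbind, Zs)
  q <- ncol(Z)
  dinv <- 1 / dvar
  b <- if (!is.null(b_start) && length(b_start) == q) b_start else numeric(q)

  pen_obj <- function(b) {
    eta <- offset + drop(Z %*% b)
    const + sum(y * eta - n * log1pexp(eta)) - 0.5 * sum(dinv * b^2)
  }
  obj <- pen_obj(b)
  H_chol <- NULL
  for (it in seq_len(100)) {
    eta <- offset + drop(Z %*% b)
    p <- plogis(eta)
    g <- drop(crossprod(Z, y - n * p)) - dinv * b
    if (max(abs(g)) < 1e-9) break
    w <- pmax(n * p * (1 - p), 1e-12)
    H <- crossprod(Z * w, Z)
    diag(H) <- diag(H) + dinv
    step <- drop(solve(H, g))
    # damped Newton: halve until the penalized objective improves
    s <- 1
    repeat {
      b_new <- b + s * step
      obj_new <- pen_obj(b_new)
      if (is.finite(obj_new) && obj_new >= obj - 1e-12) break
      s <- s / 2
      if (s < 1e-8) break
    }
    if (obj_new < obj + 1e-12 && it > 1) {
      b <- b_new
      obj <- obj_new
      break
    }
    b <- b_new
    obj <- obj_new
  }
  eta <- offset + drop(Z %*% b)
  p <- plogis(eta)
  w <- pmax(n * p * (1 - p), 1e-12)
  H <- crossprod(Z * w, Z)
  diag(H) <- diag(H) + dinv
  R <- chol(H)
  logdet_H <- 2 * sum(log(diag(R)))
  logdet_D <- sum(log(dvar))
  ll <- binom_loglik(y, n, p) - 0.5 * sum(dinv * b^2) -
    0.5 * logdet_D - 0.5 * logdet_H
  list(log_lik = ll, b = b)
}

#' Laplace log-likelihood of the logit-binomial mixed model at fixed parameters
#'
#' Evaluates the Laplace-approximate marginal log-likelihood at supplied
#' fixed effects and variance components, without any optimization.  Exposed
#' so the approximation itself can be checked against quadrature.
#'
#' @param data Mortality tibble.
#' @param beta Fixed-effect vector matching `model.matrix(predictors, data)`.
#' @param sigma_pond,sigma_unit Random-intercept SDs on the logit scale
#'   (>= 0); a component of 0 drops that term exactly.
#' @param predictors One-sided fixed-effects formula (default
#'   `~ conc_mg_l`).
#' @return Scalar log-likelihood.
#' @export
glmm_laplace_loglik <- function(data, beta, sigma_pond = 0, sigma_unit = 0,
                                predictors = ~conc_mg_l) {
  data <- validate_mortality(data)
  des <- glmm_design(data, predictors)
  stopifnot(length(beta) == ncol(des$X), sigma_pond >= 0, sigma_unit >= 0)
  laplace_eval(
    data$n_dead, data$n_exposed, des$X, des$Z_pond,
    beta, sigma_pond, sigma_unit
  )$log_lik
}

#' Fit the logit-binomial mixed model by Laplace-approximate ML
#'
#' Fits mortality on chloride concentration, population type and their
#' interaction, with independent normal random intercepts for pond of origin
#' and for experimental unit (an observation-level term absorbing the
#' overdispersion typical of binomial mortality data).  Concentration is
#' standardized internally for optimizer stability and every reported fixed
#' effect is back-transformed to the raw mg/L scale.  The outer optimization
#' over fixed effects and variance-component SDs uses bounded quasi-Newton
#' (L-BFGS-B, SDs bounded below by 0); Wald z tests condition on the
#' estimated variance components, as is conventional for GLMMs.
#'
#' @param data Mortality tibble containing both population types (unless
#'   `predictors` overrides the default design).
#' @param random Character subset of `c("pond", "unit")`: which random
#'   intercepts to include.  The default includes both; passing fewer terms
#'   gives the reduced models compared during AIC selection.
#' @param predictors Fixed-effects formula on the *standardized* concentration
#'   column `conc_s`; default `~ conc_s * type`.
#' @return A `tox_glmm` object with `fixed_effects` (raw-scale tibble: term,
#'   estimate, se, z, p), `sigma` (named SDs), `log_lik`, `aic`, `k`,
#'   `interaction` (one-row Wald summary, `NA` when the design has no
#'   interaction term), `boundary_flag`, `converged`.  Supports [tidy()] and
#'   [glance()].
#' @export
fit_glmm_laplace <- function(data, random = c("pond", "unit"),
                             predictors = ~ conc_s * type) {
  data <- validate_mortality(data)
  random <- match.arg(random, several.ok = TRUE)
  if (length(unique(data$conc_mg_l)) < 2) abort("Need >= 2 distinct concentrations.")
  uses_type <- "type" %in% all.vars(predictors)
  if (uses_type) {
    types <- unique(data$type)
    if (length(types) < 2) abort("Both population types must be present.")
    for (ty in types) {
      if (length(unique(data$pond_id[data$type == ty])) < 2) {
        abort(sprintf("Population type '%s' has fewer than 2 ponds.", ty))
      }
    }
  }
  m <- mean(data$conc_mg_l)
  s <- stats::sd(data$conc_mg_l)
  data$conc_s <- (data$conc_mg_l - m) / s
  des <- glmm_design(data, predictors)
  y <- data$n_dead
  ntot <- data$n_exposed
  p_fix <- ncol(des$X)

  est_pond <- "pond" %in% random
  est_unit <- "unit" %in% random

  # warm start: plain GLM on the same fixed design
  glm_start <- tryCatch(
    fit_binomial_glm(data, predictors = predictors)$coefficients,
    error = function(e) rep(0, p_fix)
  )

  env <- new.env()
  env$b_last <- NULL
  theta_to_sigmas <- function(theta) {
    sp <- if (est_pond) theta[p_fix + 1] else 0
    su <- if (est_unit) theta[p_fix + est_pond + 1] else 0
    c(sp, su)
  }
  negll <- function(theta) {
    beta <- theta[seq_len(p_fix)]
    sg <- theta_to_sigmas(theta)
    ev <- laplace_eval(y, ntot, des$X, des$Z_pond, beta, sg[1], sg[2],
      b_start = env$b_last
    )
    env$b_last <- ev$b
    -ev$log_lik
  }

  start <- c(glm_start, rep(0.3, est_pond + est_unit))
  lower <- c(rep(-Inf, p_fix), rep(0, est_pond + est_unit))
  opt <- optim(start, negll,
    method = "L-BFGS-B", lower = lower,
    control = list(maxit = 500, factr = 1e7)
  )
  if (opt$convergence != 0) {
    abort(sprintf(
      "GLMM outer optimization did not converge (code %d): %s",
      opt$convergence, opt$message %||% ""
    ))
  }
  theta_hat <- opt$par
  beta_hat <- theta_hat[seq_len(p_fix)]
  sg <- theta_to_sigmas(theta_hat)
  boundary <- c(pond = est_pond && sg[1] < 1e-4, unit = est_unit && sg[2] < 1e-4)
  ll <- -opt$value
  k <- p_fix + est_pond + est_unit

  # Wald covariance of beta, conditioning on the estimated variance components
  H_beta <- stats::optimHess(beta_hat, function(b) negll(c(b, theta_hat[-seq_len(p_fix)])))
  vc_beta <- tryCatch(solve(H_beta), error = function(e) matrix(NA_real_, p_fix, p_fix))

  # back-transform from conc_s = (conc - m)/s to raw mg/L:
  # every coefficient on conc_s divides by s; each term interacting with
  # conc_s also corrects the matching non-conc term by m/s.
  terms_std <- colnames(des$X)
  Tmat <- diag(p_fix)
  rownames(Tmat) <- colnames(Tmat) <- terms_std
  for (j in seq_along(terms_std)) {
    tj <- terms_std[j]
    if (!grepl("conc_s", tj)) next
    Tmat[j, ] <- 0
    Tmat[j, j] <- 1 / s
    partner <- sub("conc_s:?", "", tj)
    partner <- sub(":?conc_s", "", partner)
    if (partner == "") partner <- "(Intercept)"
    pj <- match(partner, terms_std)
    if (!is.na(pj)) Tmat[pj, j] <- -m / s
  }
  beta_raw <- drop(Tmat %*% beta_hat)
  vc_raw <- Tmat %*% vc_beta %*% t(Tmat)
  terms_raw <- sub("conc_s", "conc_mg_l", terms_std)
  se_raw <- sqrt(pmax(diag(vc_raw), 0))
  fixed <- tibble::tibble(
    term = terms_raw,
    estimate = unname(beta_raw),
    se = unname(se_raw),
    z = beta_raw / se_raw,
    p_value = 2 * stats::pnorm(-abs(beta_raw / se_raw))
  )
  int_idx <- grep(":", terms_raw)
  interaction <- if (length(int_idx) == 1) fixed[int_idx, ] else fixed[0, ]

  structure(
    list(
      fixed_effects = fixed,
      coefficients_std = setNames(beta_hat, terms_std),
      vcov_std = vc_beta,
      sigma = c(
        pond = if (est_pond) sg[1] else 0,
        unit = if (est_unit) sg[2] else 0
      ),
      log_lik = ll,
      aic = 2 * k - 2 * ll,
      k = k,
      n_obs = nrow(data),
      interaction = interaction,
      boundary_flag = any(boundary),
      boundary = boundary,
      converged = TRUE,
      conc_center = m,
      conc_scale = s,
      random = random,
      fingerprint = data_fingerprint(data),
      data = data
    ),
    class = "tox_glmm"
  )
}

#' @export
print.tox_glmm <- function(x, ...) {
  cat(
    "Logit-binomial mixed model (Laplace ML), n =", x$n_obs,
    "units; random:", paste(x$random, collapse = " + "), "\n"
  )
  print(as.data.frame(x$fixed_effects), digits = 4)
  cat(
    "sigma_pond:", format(x$sigma[["pond"]], digits = 4),
    " sigma_unit:", format(x$sigma[["unit"]], digits = 4),
    if (x$boundary_flag) " [boundary]" else "", "\n"
  )
  cat(
    "logLik:", format(x$log_lik, digits = 8),
    " AIC:", format(x$aic, digits = 8), "\n"
  )
  invisible(x)
}
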