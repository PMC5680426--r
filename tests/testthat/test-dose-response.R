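test_that("IRLS fit recovers the symmetric toy LC50 of 4 exactly", {
  fit <- fit_binomial_glm(toy_mortality())
  est <- estimate_lc50(fit, "toy")
  expect_equal(est$lc50, 4, tolerance = 1e-9)
  expect_true(est$ci_low < 4 && 4 < est$ci_high)
  expect_gt(est$se, 0)
})

test_that("IRLS matches stats::glm and a direct likelihood-maximization oracle", {
  for (s in 1:3) {
    sim <- simulate_mortality(
      sigma_pond = 0, sigma_unit = 0, ponds_per_type = 2, seed = 800 + s
    )
    d <- sim[sim$type == "woodland", ]
    fit <- fit_binomial_glm(d)

    g <- glm(cbind(n_dead, n_exposed - n_dead) ~ conc_mg_l,
      family = binomial, data = d
    )
    expect_equal(unname(fit$coefficients), unname(coef(g)), tolerance = 1e-8)
    expect_equal(fit$log_lik, as.numeric(logLik(g)), tolerance = 1e-8)
    expect_equal(fit$aic, AIC(g), tolerance = 1e-6)
    # glm()'s vcov comes from the working weights of its last IRLS step and
    # its looser stopping rule, so agreement is to ~1e-4 relative
    expect_equal(unname(fit$vcov), unname(vcov(g)), tolerance = 1e-3)

    # independent route: numerical maximization of the binomial likelihood
    negll <- function(b) {
      p <- plogis(b[1] + b[2] * d$conc_mg_l / 1000)
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      -sum(lchoose(d$n_exposed, d$n_dead) + d$n_dead * log(p) +
        (d$n_exposed - d$n_dead) * log(1 - p))
    }
    grid <- expand.grid(b0 = seq(-12, 0, length.out = 25), b1 = seq(0, 8, length.out = 25))
    vals <- apply(grid, 1, negll)
    start <- as.numeric(grid[which.min(vals), ])
    op <- optim(start, negll, method = "Nelder-Mead",
      control = list(reltol = 1e-15, maxit = 20000)
    )
    op <- optim(op$par, negll, method = "Nelder-Mead",
      control = list(reltol = 1e-15, maxit = 20000)
    )
    expect_equal(fit$log_lik, -op$value, tolerance = 1e-6)
  }
})

test_that("complete separation is raised as an informative error", {
  dead <- toy_mortality(dead = c(10L, 10L, 10L))
  expect_error(fit_binomial_glm(dead), "separation|degenerate")
  split <- toy_mortality(conc = c(1, 2, 5, 6), dead = c(0L, 0L, 10L, 10L))
  expect_error(fit_binomial_glm(split), "separation")
})

test_that("LC50 is equivariant under scaling and shifting of the dose axis", {
  sim <- simulate_mortality(sigma_pond = 0, sigma_unit = 0, seed = 12)
  d <- sim[sim$type == "woodland", ]
  base <- estimate_lc50(fit_binomial_glm(d))

  d_scaled <- dplyr::mutate(d, conc_mg_l = conc_mg_l * 2.5)
  sc <- estimate_lc50(fit_binomial_glm(d_scaled))
  expect_equal(sc$lc50, base$lc50 * 2.5, tolerance = 1e-6)
  expect_equal(sc$se, base$se * 2.5, tolerance = 1e-6)
  expect_equal(sc$ci_low, base$ci_low * 2.5, tolerance = 1e-6)

  d_shift <- dplyr::mutate(d, conc_mg_l = conc_mg_l + 500)
  sh <- estimate_lc50(fit_binomial_glm(d_shift))
  expect_equal(sh$lc50, base$lc50 + 500, tolerance = 1e-6)
  expect_equal(sh$se, base$se, tolerance = 1e-4)
})

test_that("delta-method CI agrees with a parametric bootstrap", {
  sim <- simulate_mortality(sigma_pond = 0, sigma_unit = 0, seed = 4)
  d <- sim[sim$type == "woodland", ]
  fit <- fit_binomial_glm(d)
  est <- estimate_lc50(fit)

  b <- fit$coefficients
  p_hat <- plogis(b[1] + b[2] * d$conc_mg_l)
  boot <- withr::with_seed(99, {
    vapply(seq_len(2000), function(i) {
      db <- dplyr::mutate(d, n_dead = rbinom(dplyr::n(), n_exposed, p_hat))
      fb <- tryCatch(fit_binomial_glm(db), error = function(e) NULL)
      if (is.null(fb)) return(NA_real_)
      -fb$coefficients[1] / fb$coefficients[2]
    }, numeric(1))
  })
  boot_ci <- quantile(boot, c(0.025, 0.975), na.rm = TRUE)
  width <- est$ci_high - est$ci_low
  expect_lt(abs(est$ci_low - boot_ci[[1]]), 0.05 * width)
  expect_lt(abs(est$ci_high - boot_ci[[2]]), 0.05 * width)
})

test_that("flat dose response leaves the LC50 unidentified", {
  flat <- toy_mortality(conc = c(2, 4, 6, 8), dead = c(5L, 5L, 5L, 5L))
  fit <- fit_binomial_glm(flat)
  expect_error(estimate_lc50(fit), "unidentified")
})

test_that("NaCl doses convert to the printed chloride concentrations", {
  expect_equal(nacl_to_chloride(0), 0)
  expect_equal(nacl_to_chloride(12, round_to = 100), 7300)
  expect_equal(
    nacl_to_chloride(c(6.3, 8.4, 10.7), round_to = 100),
    c(3800, 5100, 6500)
  )
  expect_equal(nacl_to_chloride(1), 1000 * 35.453 / 58.443)
  expect_error(nacl_to_chloride(-1), ">= 0")
})

test_that("AIC table ranks models and guards against mixed data", {
  sim <- simulate_mortality(sigma_pond = 0, sigma_unit = 0, seed = 31)
  d <- sim[sim$type == "roadside", ]
  dose <- fit_binomial_glm(d, predictors = ~conc_mg_l)
  null <- fit_binomial_glm(d, predictors = ~1)
  tab <- compare_aic(list(dose = dose, intercept_only = null))
  expect_equal(tab$model[1], "dose")
  expect_equal(tab$delta_aic[1], 0)
  expect_equal(tab$aic, 2 * tab$k - 2 * tab$log_lik)

  same <- compare_aic(list(a = dose, b = dose))
  expect_equal(same$delta_aic, c(0, 0))

  other <- fit_binomial_glm(sim[sim$type == "woodland", ])
  expect_error(compare_aic(list(a = dose, b = other)), "fingerprint")
})

test_that("tidy and glance expose the GLM in broom layout", {
  fit <- fit_binomial_glm(toy_mortality())
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "conc_mg_l"))
  expect_equal(td$estimate, unname(fit$coefficients))
  gl <- glance(fit)
  expect_equal(gl$AIC, fit$aic)
  expect_true(gl$converged)
})
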