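# Independent oracles used across the suite.  These deliberately take
# different computational routes from the package implementation.

# Dense multivariate-normal log-density, via determinant() and solve()
# rather than Cholesky back-substitution.
mvn_loglik_oracle <- function(x, mu, Sigma) {
  n <- length(x)
  r <- x - mu
  ld <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  -0.5 * (n * log(2 * pi) + ld + drop(t(r) %*% solve(Sigma, r)))
}

# Gauss-Hermite nodes/weights by Golub-Welsch (eigen decomposition of the
# Jacobi matrix for the physicists' weight exp(-x^2)).
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  nodes <- e$values
  weights <- sqrt(pi) * e$vectors[1, ]^2
  list(nodes = nodes, weights = weights)
}

# Adaptive Gauss-Hermite marginal log-likelihood for a logit-binomial model
# with a single pond-level random intercept: product over ponds of 1-D
# integrals, each centered and scaled at the integrand's mode.
ghq_glmm_loglik <- function(data, beta, sigma_pond, predictors = ~conc_mg_l,
                            n_nodes = 50) {
  gh <- gauss_hermite(n_nodes)
  X <- model.matrix(predictors, data = data)
  eta0 <- drop(X %*% beta)
  y <- data$n_dead
  n <- data$n_exposed
  const <- sum(lchoose(n, y))
  total <- 0
  for (pond in unique(data$pond_id)) {
    idx <- data$pond_id == pond
    logf <- function(u) {
      eta <- eta0[idx] + u
      sum(y[idx] * eta - n[idx] * ifelse(eta > 0, eta + log1p(exp(-eta)),
        log1p(exp(eta))
      )) + dnorm(u, 0, sigma_pond, log = TRUE)
    }
    # mode and curvature for the adaptive transform
    op <- optimize(function(u) -logf(u), c(-20, 20))
    mode <- op$minimum
    h <- 1e-4
    curv <- -(logf(mode + h) - 2 * logf(mode) + logf(mode - h)) / h^2
    s <- 1 / sqrt(max(curv, 1e-8))
    u <- mode + sqrt(2) * s * gh$nodes
    lv <- vapply(u, logf, numeric(1)) + gh$nodes^2 + log(gh$weights) +
      log(sqrt(2) * s)
    m <- max(lv)
    total <- total + m + log(sum(exp(lv - m)))
  }
  total + const
}

# Patristic distance by the root-depth identity d(i,j) = depth(i) + depth(j)
# - 2 * depth(mrca(i,j)).
patristic_oracle <- function(tree) {
  ntip <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  mrca <- ape::mrca(tree)
  d <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip)) {
    for (j in seq_len(ntip)) {
      d[i, j] <- depth[i] + depth[j] - 2 * depth[mrca[i, j]]
    }
  }
  d
}

# All permutations of 1..n (n small).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1]] <- append(p, n, after = k - 1)
    }
  }
  out
}

toy_mortality <- function(conc = c(2, 4, 6), dead = c(1L, 5L, 9L), n = 10L,
                          type = "woodland") {
  tibble::tibble(
    pond_id = "p1", type = type, conc_mg_l = conc,
    replicate = seq_along(conc), n_exposed = n, n_dead = dead
  )
}
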