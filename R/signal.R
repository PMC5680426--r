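#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal entries of `C` by `lam`, leaving the diagonal
#' untouched.  `lam = 1` is pure Brownian motion, `lam = 0` erases all
#' phylogenetic correlation.  The transform stays positive-semidefinite for
#' `lam` up to `max(diag(C)) / max(offdiag(C))`.
#'
#' @param C Phylogenetic covariance matrix (see [phylo_vcv()]).
#' @param lam Scalar in `[0, lambda_max(C)]`.
#' @return The rescaled covariance matrix.
#' @export
lambda_transform <- function(C, lam) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  lam_max <- lambda_upper_bound(C)
  if (!is.finite(lam) || lam < 0 || lam > lam_max + 1e-12) {
    abort(sprintf("lambda = %g outside feasible range [0, %g].", lam, lam_max))
  }
  out <- C * lam
  diag(out) <- diag(C)
  out
}

lambda_upper_bound <- function(C) {
  off <- C[upper.tri(C)]
  if (!length(off) || max(off) <= 0) return(Inf)
  max(diag(C)) / max(off)
}

#' Profile log-likelihood of a trait under Brownian motion
#'
#' For trait vector `x` with covariance proportional to `C`, profiles out the
#' GLS root state \eqn{\hat\mu = (1'C^{-1}1)^{-1} 1'C^{-1}x} and the rate
#' \eqn{\hat\sigma^2 = (x-\hat\mu 1)'C^{-1}(x-\hat\mu 1)/n}, returning the
#' maximized multivariate-normal log-likelihood
#' \eqn{-\tfrac12[n\log(2\pi\hat\sigma^2) + \log\det C + n]}.
#'
#' @param x Named numeric trait vector (names must match `rownames(C)`), not
#'   constant.
#' @param C Positive-definite phylogenetic covariance matrix.
#' @return List with `log_lik`, `mu`, `sigma2`.
#' @export
bm_profile_loglik <- function(x, C) {
  stopifnot(is.numeric(x), is.matrix(C), length(x) == nrow(C))
  if (!is.null(names(x)) && !is.null(rownames(C))) {
    if (!identical(names(x), rownames(C))) {
      if (!setequal(names(x), rownames(C))) {
        abort("Trait names do not match covariance labels.")
      }
      x <- x[rownames(C)]
    }
  }
  n <- length(x)
  if (n < 3) abort("Need at least 3 taxa.")
  if (isTRUE(all.equal(var(x), 0)) || var(x) == 0) {
    abort("Trait is constant: Brownian likelihood undefined (zero variance).")
  }
  R <- tryCatch(chol(C), error = function(e) abort("Covariance matrix is singular or not positive definite."))
  logdet <- 2 * sum(log(diag(R)))
  Cinv_x <- backsolve(R, forwardsolve(t(R), x))
  Cinv_1 <- backsolve(R, forwardsolve(t(R), rep(1, n)))
  mu <- sum(Cinv_x) / sum(Cinv_1)
  r <- x - mu
  q <- sum(r * backsolve(R, forwardsolve(t(R), r)))
  sigma2 <- q / n
  if (sigma2 <= 0) abort("Degenerate residual variance.")
  log_lik <- -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
  list(log_lik = log_lik, mu = mu, sigma2 = sigma2)
}

align_trait_tree <- function(x, tree) {
  if (is.null(names(x))) abort("Trait vector must be named by species.")
  common <- intersect(tree$tip.label, names(x))
  if (length(common) < length(x) || length(common) < ape::Ntip(tree)) {
    tree <- prune_to_taxa(tree, common)
  }
  list(x = x[tree$tip.label], tree = tree)
}

#' Maximum-likelihood estimate of Pagel's lambda
#'
#' Maximizes the Brownian profile likelihood over the lambda-transformed
#' covariance on `[0, lambda_max]` with a grid scan plus bounded
#' golden-section refinement from several spread starting brackets (tolerance
#' `1e-8`), and reports a likelihood-ratio test of signal against
#' `lambda = 0` on the upper tail of \eqn{\chi^2_1}.  The boundary null makes
#' this test conservative.
#'
#' @param x Named trait vector (>= 4 species shared with the tree).
#' @param tree `phylo` tree with branch lengths.
#' @return One-row tibble: `lambda`, `lambda_max`, `log_lik`, `log_lik_0`,
#'   `p_value`, `n`.
#' @examples
#' tr <- simulate_yule_tree(30, seed = 1)
#' x <- simulate_bm_traits(tr, sigma2 = 1, lambda_true = 1, seed = 2)
#' estimate_lambda(x, tr)
#' @export
estimate_lambda <- function(x, tree) {
  al <- align_trait_tree(x, tree)
  x <- al$x
  tree <- al$tree
  if (length(x) < 4) abort("Need at least 4 species shared between trait and tree.")
  C <- phylo_vcv(tree)
  lam_max <- lambda_upper_bound(C)
  # the covariance is exactly singular at lam_max (a tip pair becomes
  # perfectly correlated), so the likelihood is evaluated on [0, lam_hi]
  # just inside the bound and a failed factorization scores -Inf
  f <- function(lam) {
    tryCatch(
      bm_profile_loglik(x, lambda_transform(C, lam))$log_lik,
      error = function(e) -Inf
    )
  }
  ll0 <- f(0)
  if (!is.finite(lam_max)) {
    # star tree: lambda has no effect
    return(tibble::tibble(
      lambda = 0, lambda_max = Inf, log_lik = ll0, log_lik_0 = ll0,
      p_value = 1, n = length(x)
    ))
  }
  lam_hi <- lam_max * (1 - 1e-6)
  grid <- seq(0, lam_hi, length.out = 21)
  gvals <- vapply(grid, f, numeric(1))
  best <- grid[which.max(gvals)]
  # refine from several spread brackets so a local ripple cannot trap the
  # optimizer; keep the best of all candidates including the bounds
  brackets <- unique(rbind(
    c(max(0, best - 2 * lam_hi / 20), min(lam_hi, best + 2 * lam_hi / 20)),
    c(0, lam_hi),
    c(0, lam_hi / 2),
    c(lam_hi / 2, lam_hi)
  ))
  cand <- lapply(seq_len(nrow(brackets)), function(i) {
    optimize(f, interval = brackets[i, ], maximum = TRUE, tol = 1e-8)
  })
  lams <- c(vapply(cand, `[[`, numeric(1), "maximum"), grid)
  lls <- c(vapply(cand, `[[`, numeric(1), "objective"), gvals)
  i <- which.max(lls)
  lambda_hat <- lams[i]
  ll_hat <- lls[i]
  p <- pchisq(2 * max(ll_hat - ll0, 0), df = 1, lower.tail = FALSE)
  tibble::tibble(
    lambda = lambda_hat, lambda_max = lam_max, log_lik = ll_hat,
    log_lik_0 = ll0, p_value = p, n = length(x)
  )
}

blomberg_K_core <- function(x, C) {
  n <- length(x)
  R <- chol(C)
  Cinv_x <- backsolve(R, forwardsolve(t(R), x))
  Cinv_1 <- backsolve(R, forwardsolve(t(R), rep(1, n)))
  one_Cinv_one <- sum(Cinv_1)
  mu <- sum(Cinv_x) / one_Cinv_one
  r <- x - mu
  mse0 <- sum(r * r) / (n - 1)
  mse <- sum(r * backsolve(R, forwardsolve(t(R), r))) / (n - 1)
  expected_ratio <- (sum(diag(C)) - n / one_Cinv_one) / (n - 1)
  list(K = (mse0 / mse) / expected_ratio, mse = mse, mse0 = mse0)
}

#' Blomberg's K statistic
#'
#' Ratio of the observed phylogenetic dependence of a trait to the dependence
#' expected under Brownian motion on the same tree.  With the GLS root state
#' \eqn{\hat\mu}: `K = (MSE0/MSE) / E[MSE0/MSE | BM]` where
#' `MSE0 = (x-mu)'(x-mu)/(n-1)`, `MSE = (x-mu)'C^{-1}(x-mu)/(n-1)` and the
#' Brownian expectation is `[tr(C) - n/(1'C^{-1}1)]/(n-1)`.  `K = 1` matches
#' Brownian motion; `K < 1` means less similarity among relatives than
#' Brownian motion predicts.  On a star phylogeny `K` is identically 1.
#'
#' @inheritParams estimate_lambda
#' @return Scalar `K >= 0`.
#' @export
blomberg_K <- function(x, tree) {
  al <- align_trait_tree(x, tree)
  if (length(al$x) < 4) abort("Need at least 4 species shared between trait and tree.")
  if (var(al$x) == 0) abort("Trait is constant.")
  C <- phylo_vcv(al$tree)
  blomberg_K_core(al$x, C)$K
}

#' Permutation test for Blomberg's K
#'
#' Shuffles trait values across tips `n_perm` times and summarizes
#' phylogenetic signal by the GLS mean squared error `MSE` (smaller MSE =
#' stronger signal).  The one-tailed p-value is
#' `(1 + #\{MSE_perm <= MSE_obs\}) / (1 + n_perm)`.
#'
#' @inheritParams estimate_lambda
#' @param n_perm Number of permutations (>= 99; default 999).
#' @param seed Integer seed; the test is reproducible given `(seed, n_perm)`.
#' @return One-row tibble: `K`, `p_value`, `n_perm`, `seed`, `n`.
#' @export
permutation_test_K <- function(x, tree, n_perm = 999, seed = 1) {
  if (n_perm < 99) abort("n_perm must be at least 99.")
  al <- align_trait_tree(x, tree)
  x <- al$x
  if (length(x) < 4) abort("Need at least 4 species shared between trait and tree.")
  if (var(x) == 0) abort("Trait is constant.")
  C <- phylo_vcv(al$tree)
  obs <- blomberg_K_core(x, C)
  mse_perm <- withr::with_seed(split_seed(seed, 1L), {
    vapply(seq_len(n_perm), function(i) {
      blomberg_K_core(sample(x), C)$mse
    }, numeric(1))
  })
  p <- (1 + sum(mse_perm <= obs$mse)) / (1 + n_perm)
  tibble::tibble(
    K = obs$K, p_value = p, n_perm = as.integer(n_perm),
    seed = as.integer(seed), n = length(x)
  )
}

#' Pairwise trait-difference distance matrix
#'
#' Absolute difference between each pair of species values (one-dimensional
#' Euclidean distance), the trait-side input of the Mantel test.
#'
#' @param values Named numeric vector of per-species trait values, or a
#'   tibble with columns `species` and `lc50` as returned by
#'   [aggregate_species()].
#' @return Symmetric matrix with zero diagonal, dimnames = species.
#' @export
trait_distance_matrix <- function(values) {
  if (is.data.frame(values)) {
    values <- setNames(values$lc50, values$species)
  }
  if (length(values) < 2) abort("Need at least 2 species.")
  if (is.null(names(values))) abort("Values must be named by species.")
  d <- abs(outer(values, values, "-"))
  dimnames(d) <- list(names(values), names(values))
  d
}

mantel_r <- function(D1, D2) {
  u <- upper.tri(D1)
  a <- D1[u]
  b <- D2[u]
  if (var(a) == 0 || var(b) == 0) {
    abort("Zero variance in a distance matrix: Mantel r undefined.")
  }
  sum((a - mean(a)) * (b - mean(b))) / sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}

#' Mantel matrix-correlation test
#'
#' Pearson correlation between the upper triangles of two distance matrices,
#' with significance from jointly permuting the rows and columns of `D2`.
#' One-tailed for positive association (the working hypothesis being that
#' phylogenetically close species have similar trait values):
#' `p = (1 + #\{r_perm >= r_obs\}) / (1 + n_perm)`.
#'
#' @param D1,D2 Distance matrices with identical dimnames in identical order
#'   (e.g. [patristic_distances()] and [trait_distance_matrix()]).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return One-row tibble: `r`, `p_value`, `n_perm`, `seed`, `n`,
#'   `small_n_flag` (TRUE when n < 4, where the permutation space is tiny).
#' @export
mantel_test <- function(D1, D2, n_perm = 999, seed = 1) {
  stopifnot(is.matrix(D1), is.matrix(D2))
  if (is.null(rownames(D1)) || is.null(rownames(D2)) ||
    !identical(rownames(D1), rownames(D2)) ||
    !identical(colnames(D1), colnames(D2))) {
    abort("Distance matrices must carry identical labels in identical order.")
  }
  n <- nrow(D1)
  if (n < 3) abort("Need at least 3 taxa for a Mantel test.")
  if (n < 4) warn("Mantel test with n = 3 has only 6 permutations; p is nearly meaningless.")
  r_obs <- mantel_r(D1, D2)
  r_perm <- withr::with_seed(split_seed(seed, 2L), {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n)
      mantel_r(D1, D2[idx, idx])
    }, numeric(1))
  })
  p <- (1 + sum(r_perm >= r_obs - 1e-12)) / (1 + n_perm)
  tibble::tibble(
    r = r_obs, p_value = p, n_perm = as.integer(n_perm),
    seed = as.integer(seed), n = n, small_n_flag = n < 4
  )
}
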