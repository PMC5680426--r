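test_that("lambda transform scales off-diagonals only, within its feasible range", {
  C <- phylo_vcv(grafen_branch_lengths(parse_newick("((A,B),(C,D));")))
  expect_equal(lambda_transform(C, 1), C)
  expect_equal(lambda_transform(C, 0), diag(diag(C)), ignore_attr = TRUE)
  half <- lambda_transform(C, 0.5)
  expect_equal(half["A", "B"], 1 / 3)
  expect_equal(diag(half), diag(C))
  expect_error(lambda_transform(C, -0.1), "feasible")
  expect_error(lambda_transform(C, 2), "feasible")
})

test_that("Brownian profile likelihood reduces to OLS on the identity and matches the MVN oracle", {
  set.seed(42)
  x <- rnorm(8)
  names(x) <- paste0("t", 1:8)
  C <- diag(8)
  dimnames(C) <- list(names(x), names(x))
  fit <- bm_profile_loglik(x, C)
  expect_equal(fit$mu, mean(x))
  expect_equal(fit$sigma2, mean((x - mean(x))^2))

  for (s in 1:4) {
    tr <- simulate_yule_tree(10, seed = 400 + s)
    xx <- simulate_bm_traits(tr, sigma2 = 2, root_state = 5, seed = s)
    C <- phylo_vcv(tr)
    fit <- bm_profile_loglik(xx, C)
    oracle <- mvn_loglik_oracle(
      unname(xx[rownames(C)]), fit$mu,
      fit$sigma2 * C
    )
    expect_equal(fit$log_lik, oracle, tolerance = 1e-10)
    # location shift moves mu, leaves sigma2 and logL untouched
    sh <- bm_profile_loglik(xx + 100, C)
    expect_equal(sh$mu, fit$mu + 100, tolerance = 1e-8)
    expect_equal(sh$sigma2, fit$sigma2, tolerance = 1e-8)
    expect_equal(sh$log_lik, fit$log_lik, tolerance = 1e-8)
  }

  expect_error(
    bm_profile_loglik(setNames(rep(1, 8), paste0("t", 1:8)), diag(8)),
    "constant"
  )
})

test_that("lambda MLE beats every grid point and agrees with phytools", {
  skip_if_not_installed("phytools")
  for (s in 1:3) {
    tr <- simulate_yule_tree(40, seed = 500 + s)
    x <- simulate_bm_traits(tr, sigma2 = 1, lambda_true = 0.7, seed = 500 + s)
    est <- estimate_lambda(x, tr)
    C <- phylo_vcv(tr)
    grid_ll <- vapply(
      seq(0, min(1, est$lambda_max * (1 - 1e-6)), by = 0.05),
      function(l) bm_profile_loglik(x, lambda_transform(C, l))$log_lik,
      numeric(1)
    )
    expect_true(est$log_lik >= max(grid_ll) - 1e-6)

    ph <- phytools::phylosig(tr, x, method = "lambda", test = TRUE)
    expect_equal(est$lambda, ph$lambda, tolerance = 1e-3)
    expect_equal(est$log_lik, ph$logL, tolerance = 1e-4)
    expect_equal(est$p_value, ph$P, tolerance = 1e-4)
  }
})

test_that("lambda is near zero for traits shuffled across a deep tree", {
  tr <- simulate_yule_tree(80, seed = 77)
  lam <- vapply(1:5, function(s) {
    x <- simulate_bm_traits(tr, sigma2 = 1, lambda_true = 1, seed = 600 + s)
    xp <- withr::with_seed(s, setNames(sample(unname(x)), names(x)))
    estimate_lambda(xp, tr)$lambda
  }, numeric(1))
  expect_lt(mean(lam), 0.15)
})

test_that("Blomberg's K is exactly 1 on a star phylogeny", {
  star <- parse_newick(paste0("(", paste0("t", 1:25, ":1", collapse = ","), ");"))
  for (s in 1:5) {
    x <- withr::with_seed(s, setNames(rnorm(25), paste0("t", 1:25)))
    expect_equal(blomberg_K(x, star), 1, tolerance = 1e-10)
  }
})

test_that("Blomberg's K matches an independent dense-matrix oracle and picante", {
  # 4-tip worked case, all matrix algebra done longhand with solve()
  bal <- grafen_branch_lengths(parse_newick("((A,B),(C,D));"))
  x <- setNames(c(0, 0, 1, 1), c("A", "B", "C", "D"))
  C <- phylo_vcv(bal)
  Ci <- solve(C)
  one <- rep(1, 4)
  mu <- drop((t(one) %*% Ci %*% x) / (t(one) %*% Ci %*% one))
  r <- x - mu
  mse0 <- drop(t(r) %*% r) / 3
  mse <- drop(t(r) %*% Ci %*% r) / 3
  er <- (sum(diag(C)) - 4 / drop(t(one) %*% Ci %*% one)) / 3
  expect_equal(blomberg_K(x, bal), (mse0 / mse) / er, tolerance = 1e-12)

  skip_if_not_installed("picante")
  for (s in 1:3) {
    tr <- simulate_yule_tree(20, seed = 700 + s)
    xx <- simulate_bm_traits(tr, seed = 700 + s)
    expect_equal(
      blomberg_K(xx, tr),
      as.numeric(picante::Kcalc(xx[tr$tip.label], tr)),
      tolerance = 1e-8
    )
  }
})

test_that("K permutation test is seeded, and flags clade-clustered traits", {
  tr <- simulate_yule_tree(20, seed = 33)
  x <- simulate_bm_traits(tr, seed = 33)
  a <- permutation_test_K(x, tr, n_perm = 199, seed = 5)
  b <- permutation_test_K(x, tr, n_perm = 199, seed = 5)
  expect_identical(a, b)
  expect_true(a$p_value >= (1 / 200) && a$p_value <= 1)

  # two clades of 10, trait 0 in one clade and 1 in the other
  two <- grafen_branch_lengths(parse_newick(paste0(
    "((", paste0("a", 1:10, collapse = ","), "),(",
    paste0("b", 1:10, collapse = ","), "));"
  )))
  x2 <- setNames(rep(c(0, 1), each = 10), two$tip.label)
  x2 <- x2 + withr::with_seed(1, rnorm(20, 0, 1e-3)) # break exact ties only
  out <- permutation_test_K(x2, two, n_perm = 999, seed = 9)
  expect_lte(out$p_value, 0.01)
})

test_that("Mantel r is 1 for affinely related matrices and errors on degenerate input", {
  tr <- simulate_yule_tree(12, seed = 8)
  D1 <- patristic_distances(tr)
  expect_equal(mantel_test(D1, D1, n_perm = 99, seed = 1)$r, 1)
  D2 <- 3.7 * D1 + 2
  diag(D2) <- 0
  expect_equal(mantel_test(D1, D2, n_perm = 99, seed = 1)$r, 1, tolerance = 1e-12)

  D3 <- D1[c(2:nrow(D1), 1), c(2:ncol(D1), 1)]
  expect_error(mantel_test(D1, D3, n_perm = 99, seed = 1), "identical labels")
  flat <- matrix(1, 12, 12, dimnames = dimnames(D1))
  diag(flat) <- 0
  expect_error(mantel_test(D1, flat, n_perm = 99, seed = 1), "variance")
})

test_that("Mantel permutation p matches exhaustive enumeration at n = 5", {
  skip_if_not_installed("vegan")
  tr <- simulate_yule_tree(5, seed = 21)
  D1 <- patristic_distances(tr)
  x <- simulate_bm_traits(tr, seed = 21)
  D2 <- trait_distance_matrix(x)

  r_obs <- mantel_test(D1, D2, n_perm = 99, seed = 1)$r
  expect_equal(r_obs, unname(vegan::mantel(D1, D2, permutations = 99)$statistic),
    tolerance = 1e-10
  )

  perms <- all_perms(5)
  r_all <- vapply(perms, function(p) {
    Dp <- D2[p, p]
    u <- upper.tri(D1)
    cor(D1[u], Dp[u])
  }, numeric(1))
  p_exact <- mean(r_all >= r_obs - 1e-12)

  out <- mantel_test(D1, D2, n_perm = 1999, seed = 4)
  mc_se <- sqrt(p_exact * (1 - p_exact) / 2000)
  expect_lt(abs(out$p_value - p_exact), 3 * mc_se + 2 / 2000)
})

test_that("trait distance matrix is the elementwise absolute difference", {
  expect_equal(trait_distance_matrix(c(A = 1, B = 4))["A", "B"], 3)
  vals <- withr::with_seed(3, setNames(rnorm(7), paste0("s", 1:7)))
  d <- trait_distance_matrix(vals)
  for (i in 1:7) {
    for (j in 1:7) {
      expect_equal(d[i, j], abs(vals[[i]] - vals[[j]]))
    }
  }
  same <- trait_distance_matrix(c(A = 2, B = 2, C = 2))
  expect_true(all(same == 0))
})

test_that("signal suite rows are per-group, isolated, and skip undersized groups", {
  tr <- simulate_yule_tree(30, seed = 55)
  x <- simulate_bm_traits(tr, sigma2 = 1, lambda_true = 1, seed = 55)
  sv <- tibble::tibble(species = names(x), lc50 = 10^(x / 4 + 3))

  g_all <- list(all = sv$species)
  g_two <- list(
    all = sv$species,
    sub = sv$species[1:10],
    tiny = sv$species[1:3]
  )
  expect_warning(
    suite <- run_signal_suite(sv, tr,
      groups = g_two, n_perm = 99, seed = 2,
      trait_scale = "log10"
    ),
    "skipped"
  )
  expect_equal(suite$group, c("all", "sub"))
  expect_equal(attr(suite, "skipped"), "tiny")

  alone <- run_signal_suite(sv, tr,
    groups = g_all, n_perm = 99, seed = 2,
    trait_scale = "log10"
  )
  expect_equal(
    as.data.frame(suite[suite$group == "all", ]),
    as.data.frame(alone),
    ignore_attr = TRUE
  )
  expect_gt(suite$lambda[suite$group == "all"], 0.8)
  expect_error(run_signal_suite(sv, tr, groups = list(), n_perm = 99), "Empty group")
})
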