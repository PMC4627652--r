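test_that("trapezoidal AUC matches hand computation and is linear", {
  grid <- sparsity_grid()
  c_curve <- rep(3.7, length(grid$values))
  expect_equal(auc_trapezoid(c_curve, grid), 0.23 * 3.7, tolerance = 1e-12)
  g3 <- c(0.1, 0.2, 0.3)
  expect_equal(auc_trapezoid(g3, g3),
               (0.1 + 0.2) / 2 * 0.1 + (0.2 + 0.3) / 2 * 0.1)
  expect_equal(auc_trapezoid(g3, g3), 0.04)
  set.seed(501)
  y <- rnorm(24); z <- rnorm(24)
  expect_equal(auc_trapezoid(2 * y + 5 * z, grid),
               2 * auc_trapezoid(y, grid) + 5 * auc_trapezoid(z, grid),
               tolerance = 1e-12)
  expect_error(auc_trapezoid(1:5, grid), "length")
})

test_that("residualization removes covariate effects via OLS", {
  set.seed(502)
  n <- 40
  age <- rnorm(n, 55, 10)
  sex <- rep(c("M", "F"), n / 2)
  # values that are an exact linear function of age vanish
  expect_lt(max(abs(residualize(2 * age, age, sex))), 1e-9)
  # residuals orthogonal to covariates, and equal to the normal-equations oracle
  v <- rnorm(n)
  r <- residualize(v, age, sex)
  X <- cbind(1, age, as.numeric(factor(sex)) - 1)
  beta <- solve(t(X) %*% X) %*% t(X) %*% v
  expect_equal(r, as.numeric(v - X %*% beta), tolerance = 1e-8)
  expect_lt(abs(sum(r * age)), 1e-6 * sqrt(sum(r^2) * sum(age^2)))
  expect_lt(abs(sum(r)), 1e-8)
  # collinear covariates are named
  expect_error(residualize(v, rep(2, n), sex), "age")
})

test_that("permutation test is two-tailed, valid, and smooth", {
  expect_equal(permutation_test(rep(1, 5), rep(1, 6), 500, 1)$p_perm, 1)
  set.seed(503)
  a <- rnorm(15) + 10
  b <- rnorm(15)
  res <- permutation_test(a, b, 1999, 7)
  expect_lte(res$p_perm, 0.001)
  expect_equal(res$observed_diff, mean(a) - mean(b))
  # p is never 0 and is reproducible under the seed
  expect_gt(res$p_perm, 0)
  expect_equal(permutation_test(a, b, 1999, 7)$p_perm, res$p_perm)
  # direction-agnostic: swapping groups flips the sign, not the p-value
  res2 <- permutation_test(b, a, 1999, 7)
  expect_equal(res2$observed_diff, -res$observed_diff)
})

test_that("pooled t-test reproduces the textbook formula", {
  set.seed(504)
  a <- rnorm(12); b <- rnorm(9)
  res <- per_threshold_ttest(a, b)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p.value, ref$p.value, tolerance = 1e-12)
  # group summary stats 3 (0.64, n=30) vs 2.88 (0.9, n=26) give t ~ 0.58
  g1 <- as.numeric(scale(rnorm(30))) * 0.64 + 3
  g2 <- as.numeric(scale(rnorm(26))) * 0.90 + 2.88
  res2 <- per_threshold_ttest(g1, g2)
  expect_equal(res2$statistic, 0.581, tolerance = 1e-2)
  x <- rnorm(10)
  r0 <- per_threshold_ttest(x, x)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p.value, 1)
  expect_error(per_threshold_ttest(rep(2, 5), rep(2, 4)), "variance")
})

test_that("BH correction matches the exhaustive step-up oracle", {
  expect_true(all(fdr_correct(rep(0.001, 10), 0.05)))
  expect_false(any(fdr_correct(rep(0.9, 10), 0.05)))
  set.seed(505)
  for (i in 1:20) {
    p <- runif(30)^2
    expect_identical(fdr_correct(p, 0.05), oracle_bh_flags(p, 0.05))
    # flags invariant under reordering
    ord <- sample(30)
    expect_identical(fdr_correct(p, 0.05)[ord], fdr_correct(p[ord], 0.05))
    # monotone in p: every rejected p <= every accepted p
    fl <- fdr_correct(p, 0.05)
    if (any(fl) && any(!fl)) expect_lt(max(p[fl]), min(p[!fl]) + 1e-15)
  }
})

test_that("hub sign test uses the binomial tail over threshold levels", {
  grid <- sparsity_grid()
  nl <- length(grid$values)
  set.seed(506)
  b <- matrix(rexp(20 * nl), 20, nl)
  b[3, ] <- max(b) * 10   # dominates at every level
  b[7, ] <- 0             # never exceeds
  tab <- hub_sign_test(b, grid)
  expect_equal(tab$n_exceed[3], nl)
  expect_equal(tab$p_sign[3], 0.5^24, tolerance = 1e-12)
  expect_equal(tab$p_sign[3], 6.0e-8, tolerance = 0.01)
  expect_true(tab$is_hub[3])
  expect_equal(tab$n_exceed[7], 0L)
  expect_equal(tab$p_sign[7], 1)
  expect_false(tab$is_hub[7])
  expect_true(all(tab$n_exceed >= 0 & tab$n_exceed <= nl))
  expect_error(hub_sign_test(b[, 1, drop = FALSE], grid), "levels")
})

test_that("group-mean networks average Fisher-z matrices element-wise", {
  c1 <- random_connectivity(8, seed = 507)
  expect_equal(mean_group_network(list(c1))$z, c1$z)
  cneg <- connsweep:::z_connectivity_from_matrix(-c1$z)
  expect_true(all(mean_group_network(list(c1, cneg))$z == 0))
  c2 <- random_connectivity(8, seed = 508)
  c3 <- random_connectivity(8, seed = 509)
  m <- mean_group_network(list(c1, c2, c3))
  expect_equal(m$z, (c1$z + c2$z + c3$z) / 3, tolerance = 1e-12)
  c_bad <- random_connectivity(9, seed = 510)
  expect_error(mean_group_network(list(c1, c_bad)), "mismatch")
})

test_that("clinical correlation applies the t transform of Pearson r", {
  set.seed(511)
  x <- rnorm(26)
  res <- clinical_correlation(x, -x)
  expect_equal(res$r, -1)
  y <- 0.6 * x + rnorm(26)
  res2 <- clinical_correlation(x, y)
  r_hand <- sum(scale(x) * scale(y)) / 25
  t_hand <- r_hand * sqrt(24) / sqrt(1 - r_hand^2)
  expect_equal(res2$r, r_hand, tolerance = 1e-12)
  expect_equal(res2$p, 2 * pt(-abs(t_hand), 24), tolerance = 1e-12)
  expect_error(clinical_correlation(rep(1, 10), rnorm(10)), "variance")
  expect_error(clinical_correlation(rnorm(3), rnorm(3)), "4")
})

test_that("module counting propagates degenerate group comparisons as conditions", {
  nets_a <- replicate(4, two_cliques_net(4), simplify = FALSE)
  nets_b <- replicate(4, two_cliques_net(4), simplify = FALSE)
  res <- count_modules(nets_a, nets_b)
  expect_equal(res$counts_a, rep(2L, 4))
  expect_true(inherits(res$test, "condition"))  # zero pooled variance
})
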