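test_that("spearman_matrix reproduces the rank-difference formula", {
  X <- cbind(a = c(1, 2, 3, 4, 5), b = c(2, 1, 4, 3, 5))
  S <- spearman_matrix(X)
  expect_equal(S$values["a", "b"], 0.8)  # 1 - 6*4/(5*24)
  expect_equal(diag(S$values), c(a = 1, b = 1))
  expect_equal(spearman_matrix(cbind(x = 1:3, y = 3:1))$values["x", "y"], -1)
  expect_true(all(S$pairwise_n == 5))
})

test_that("spearman_matrix applies pairwise deletion and validates input", {
  set.seed(1)
  X <- matrix(sample(0:4, 60, TRUE), 20, 3,
              dimnames = list(NULL, c("u", "v", "w")))
  X[1:4, 1] <- NA
  X[3:6, 2] <- NA
  S <- spearman_matrix(X)
  ok <- !is.na(X[, "u"]) & !is.na(X[, "v"])
  expect_equal(S$values["u", "v"],
               cor(rank(X[ok, "u"]), rank(X[ok, "v"])))
  expect_identical(S$pairwise_n["u", "v"], sum(ok))

  Xconst <- cbind(c1 = rep(2, 10), c2 = 1:10)
  expect_error(spearman_matrix(Xconst), "zero variance.*c1")
  Xfew <- cbind(a = c(1, 2, NA, NA, NA), b = c(NA, 2, 3, 1, 5))
  expect_error(spearman_matrix(Xfew), "fewer than 3 complete pairs")
})

test_that("spearman estimates are invariant to monotone transformations", {
  set.seed(9)
  Z <- rmvn(400, cov2cor(solve(chain_precision(5, 0.4))), 9)
  X <- discretize_cols(Z, 5L)
  colnames(X) <- paste0("i", 1:5)
  net_a <- estimate_network(X)
  Xt <- X
  Xt[, 2] <- exp(Xt[, 2])          # strictly increasing
  Xt[, 4] <- Xt[, 4]^3 + 10        # strictly increasing on 0..4
  net_b <- estimate_network(Xt)
  expect_equal(net_a$weights, net_b$weights, tolerance = 1e-12)
})

test_that("nearest_pd_repair clips, rescales, and is idempotent", {
  C_pd <- random_corr(5, 2)
  r1 <- nearest_pd_repair(C_pd)
  expect_false(r1$repaired)
  expect_equal(r1$values, C_pd)

  C_bad <- matrix(0.9, 3, 3)
  C_bad[1, 2] <- C_bad[2, 1] <- -0.9
  diag(C_bad) <- 1
  expect_lt(min(eigen(C_bad, only.values = TRUE)$values), 0)
  r2 <- nearest_pd_repair(C_bad)
  expect_true(r2$repaired)
  expect_gte(min(eigen(r2$values, only.values = TRUE)$values), 1e-8)
  expect_equal(unname(diag(r2$values)), rep(1, 3))
  r3 <- nearest_pd_repair(r2)
  expect_false(r3$repaired)
  expect_equal(r3$values, r2$values)

  expect_equal(nearest_pd_repair(diag(4))$values, diag(4))
})

test_that("glasso matches its analytic fixed points", {
  # identity input stays the empty graph at any penalty
  for (lam in c(0, 0.1, 1)) {
    K <- glasso_fit(diag(4), lam)$values
    expect_equal(K, diag(4), tolerance = 1e-10)
  }
  C <- matrix(c(1, .5, .2, .5, 1, .3, .2, .3, 1), 3)
  # full shrinkage: penalty at/above the largest correlation empties the graph
  K_max <- glasso_fit(C, 0.5)$values
  expect_true(all(K_max[upper.tri(K_max)] == 0))
  # KKT zero-pattern oracle: zeros exactly where |C_ij| <= lambda
  K_mid <- glasso_fit(C, 0.25)$values
  expect_identical(K_mid[upper.tri(K_mid)] == 0,
                   abs(C[upper.tri(C)]) <= 0.25)
  # unpenalized solution is the matrix inverse
  expect_equal(glasso_fit(C, 0)$values, solve(C), tolerance = 1e-6)
})

test_that("glasso solutions satisfy the subgradient conditions", {
  for (seed in 1:5) {
    C <- random_corr(6, seed)
    lam <- 0.05 + 0.1 * (seed %% 3)
    fit <- glasso_fit(C, lam)
    kkt <- check_glasso_kkt(fit, C, lam)
    expect_true(kkt$ok)
  }
})

test_that("ebic_score matches an independently coded formula", {
  # empty model: no edge term, so the score cannot depend on gamma
  expect_equal(ebic_score(diag(3), diag(3), n = 100, gamma = 0.7),
               ebic_score(diag(3), diag(3), n = 100, gamma = 0))

  K <- matrix(c(1.2, -0.3, 0, -0.3, 1.1, 0.2, 0, 0.2, 0.9), 3)
  C <- random_corr(3, 4)
  n <- 419
  # direct arithmetic oracle
  oracle <- function(K, C, n, gamma) {
    L <- (n / 2) * (determinant(K)$modulus[1] - sum(diag(C %*% K)))
    E <- sum(K[upper.tri(K)] != 0)
    -2 * L + E * log(n) + 4 * E * gamma * log(ncol(K))
  }
  expect_equal(ebic_score(K, C, n, gamma = 0.5), oracle(K, C, n, 0.5))
  # gamma = 0 reduces to plain BIC
  expect_equal(ebic_score(K, C, n, gamma = 0), oracle(K, C, n, 0))
  expect_error(ebic_score(matrix(c(1, 2, 2, 1), 2), diag(2), 10),
               "positive-definite")
})

test_that("uncorrelated input selects the empty network for every gamma", {
  X <- cbind(p = c(1, 2, 3, 4), q = c(2, 4, 1, 3))  # zero rank correlation
  for (g in c(0, 0.25, 0.5, 1)) {
    net <- estimate_network(X, gamma = g)
    expect_true(all(net$weights == 0))
  }
})

test_that("edge count is monotone along the penalty path", {
  cfg <- simulation_config(n_subjects = 400, catalog = mixed_catalog(6, 4),
                           prevalence_w1 = 0.4, prevalence_w2 = 0.4,
                           weight_range = c(0.3, 0.5), within_density = 0.3,
                           between_density = 0.1, missing_rate = 0, seed = 6)
  pan <- sim_panel_quiet(build_true_network(cfg), cfg)
  net <- estimate_network(pan, wave = 1)
  path <- net$ebic_path
  # path is stored lambda-descending: edges non-decreasing, allowing <= 1
  # solver-tolerance slip
  slips <- sum(pmax(0, -diff(path$n_edges)) > 0)
  expect_lte(slips, 1)
  # sparsity pattern of weights equals that of the selected precision
  expect_identical(net$weights == 0, net$precision == 0 | diag(10) == 1)
  expect_true(all(abs(net$weights[upper.tri(net$weights)]) < 1))
  expect_equal(net$weights, t(net$weights))
  expect_true(all(diag(net$weights) == 0))
  kkt <- check_glasso_kkt(net$precision, net$correlation$values,
                          net$selected_lambda)
  expect_true(kkt$ok)
})

test_that("data from the zero network estimate as (near-)empty", {
  set.seed(7)
  X <- matrix(sample(0:4, 1000 * 10, TRUE), 1000, 10)
  net <- estimate_network(X)
  expect_lte(sum(net$weights[upper.tri(net$weights)] != 0), 2)
})
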