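test_that("empty-graph config yields zero partials and identity precision", {
  cfg <- simulation_config(n_subjects = 50, catalog = binary_catalog(6),
                           within_density = 0, between_density = 0,
                           prevalence_w1 = 0.5, prevalence_w2 = 0.5,
                           missing_rate = 0, seed = 1)
  tr <- build_true_network(cfg)
  expect_true(all(tr$partials_w1 == 0))
  expect_identical(unname(tr$precisions_w1), diag(6))
  expect_equal(tr$ridge_delta[["w1"]], 0)
})

test_that("default catalog produces 41x41 truth with self-consistent partials", {
  cfg <- simulation_config(seed = 11)
  tr <- build_true_network(cfg)
  expect_identical(dim(tr$partials_w1), c(41L, 41L))
  expect_identical(dim(tr$partials_w2), c(41L, 41L))
  # elementwise recomputation oracle, independent double loop
  for (wv in c("w1", "w2")) {
    K <- tr[[paste0("precisions_", wv)]]
    P <- tr[[paste0("partials_", wv)]]
    p <- ncol(K)
    for (i in seq_len(p)) {
      for (j in seq_len(p)) {
        want <- if (i == j) 0 else -K[i, j] / sqrt(K[i, i] * K[j, j])
        expect_equal(P[i, j], want, tolerance = 1e-12)
      }
    }
    expect_true(min(eigen(K, only.values = TRUE)$values) > 0)
    expect_true(all(abs(P[upper.tri(P)]) < 1))
  }
  # per-item latent cutpoints strictly increasing
  expect_true(all(vapply(tr$thresholds_w1,
                         function(x) !is.unsorted(x, strictly = TRUE),
                         logical(1))))
})

test_that("planted change on an unknown item is rejected", {
  cfg <- simulation_config(n_subjects = 50, catalog = binary_catalog(4),
                           planted_changes = data.frame(
                             item_i = "b01", item_j = "nope", delta = 0.1),
                           seed = 1)
  expect_error(build_true_network(cfg), "unknown item")
})

test_that("binary endorsement rates match prevalence under the zero network", {
  cfg <- simulation_config(n_subjects = 100000, catalog = binary_catalog(6),
                           within_density = 0, between_density = 0,
                           prevalence_w1 = 0.5, prevalence_w2 = 0.5,
                           missing_rate = 0, seed = 3)
  pan <- simulate_panel(build_true_network(cfg), cfg)
  expect_true(all(abs(colMeans(pan$wave1) - 0.5) < 0.01))
  expect_true(all(abs(colMeans(pan$wave2) - 0.5) < 0.01))
})

test_that("a planted partial dominates every true-zero pair in sample Spearman", {
  cfg <- simulation_config(n_subjects = 100000, catalog = binary_catalog(6),
                           within_density = 0, between_density = 0,
                           prevalence_w1 = 0.5, prevalence_w2 = 0.5,
                           missing_rate = 0, seed = 12,
                           planted_changes = data.frame(
                             item_i = "b02", item_j = "b05", delta = 0.3))
  pan <- simulate_panel(build_true_network(cfg), cfg)
  S <- spearman_matrix(pan$wave2)$values
  planted <- S["b02", "b05"]
  zero_pairs <- abs(S[upper.tri(S)])
  zero_pairs <- zero_pairs[zero_pairs != abs(planted)]
  expect_gt(planted, max(zero_pairs))
})

test_that("sampled latents reproduce the wave-1 covariance (copula fidelity)", {
  cat8 <- mixed_catalog(4, 4)
  cfg <- simulation_config(n_subjects = 100000, catalog = cat8,
                           prevalence_w1 = 0.4, prevalence_w2 = 0.4,
                           weight_range = c(0.3, 0.5),
                           within_density = 0.4, between_density = 0.15,
                           cross_wave_rho = 0.15, missing_rate = 0,
                           planted_changes = no_changes, seed = 8)
  tr <- build_true_network(cfg)
  pan <- simulate_panel(tr, cfg, keep_latents = TRUE)
  Z1 <- attr(pan, "latents")[, 1:8]
  S1 <- cov2cor(solve(tr$precisions_w1))
  expect_lt(max(abs(cor(Z1) - S1)), 0.01)
})

test_that("raising wave-2 prevalence raises wave-2 endorsement", {
  cfg <- simulation_config(n_subjects = 10000, catalog = binary_catalog(4),
                           within_density = 0, between_density = 0,
                           prevalence_w1 = 0.2, prevalence_w2 = 0.35,
                           missing_rate = 0, seed = 5)
  pan <- simulate_panel(build_true_network(cfg), cfg)
  expect_true(all(colMeans(pan$wave2) > colMeans(pan$wave1)))
})

test_that("identical config and seed give bitwise-identical panels", {
  cfg <- simulation_config(n_subjects = 200, catalog = mixed_catalog(5, 3),
                           seed = 77)
  tr <- build_true_network(cfg)
  p1 <- sim_panel_quiet(tr, cfg)
  p2 <- sim_panel_quiet(tr, cfg)
  expect_identical(p1, p2)
})

test_that("MCAR masking matches its binomial oracle", {
  cfg <- simulation_config(n_subjects = 10, catalog = binary_catalog(10),
                           within_density = 0, between_density = 0,
                           prevalence_w1 = 0.5, prevalence_w2 = 0.5,
                           missing_rate = 0, seed = 2)
  pan <- simulate_panel(build_true_network(cfg), cfg)

  expect_identical(apply_missingness(pan, 0), pan)
  expect_error(apply_missingness(pan, 1), "< 1")

  rate <- 0.9
  masked <- apply_missingness(pan, rate, seed = 4)
  n_missing <- sum(is.na(masked$wave1)) + sum(is.na(masked$wave2))
  band <- qbinom(c(0.005, 0.995), 200, rate)
  expect_gte(n_missing, band[1])
  expect_lte(n_missing, band[2])
  expect_identical(dim(masked$wave1), dim(pan$wave1))
})

test_that("the default panel has the study's cell count and ~24 missing cells", {
  cfg <- simulation_config(seed = 2)
  pan <- sim_panel_quiet(build_true_network(cfg), cfg)
  n_cells <- length(pan$wave1) + length(pan$wave2)
  expect_identical(n_cells, 34358L)
  n_missing <- sum(is.na(pan$wave1)) + sum(is.na(pan$wave2))
  band <- qbinom(c(0.005, 0.995), 34358, 24 / 34358)
  expect_gte(n_missing, band[1])
  expect_lte(n_missing, band[2])
})
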