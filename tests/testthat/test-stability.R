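strong_panel <- function(n = 1000, seed = 21) {
  cfg <- simulation_config(n_subjects = n, catalog = mixed_catalog(5, 5),
                           prevalence_w1 = 0.5, prevalence_w2 = 0.5,
                           weight_range = c(0.3, 0.5), within_density = 0.3,
                           between_density = 0.1, missing_rate = 0,
                           planted_changes = no_changes, seed = seed)
  sim_panel_quiet(build_true_network(cfg), cfg)
}

test_that("CS follows the pass-up-to-first-failure rule on hand-built tables", {
  pass <- rep(1, 100)                     # all replicates clear 0.70
  fail <- c(rep(1, 80), rep(0.2, 20))     # only 80% clear it
  res <- fake_stability(c(0.1, 0.2, 0.3, 0.4),
                        list(pass, pass, pass, fail))
  expect_equal(cs_coefficient(res)$value, 0.3)

  res_fail_first <- fake_stability(c(0.1, 0.2), list(fail, pass))
  expect_equal(cs_coefficient(res_fail_first)$value, 0)

  res_all <- fake_stability(c(0.25, 0.5, 0.75), list(pass, pass, pass))
  expect_equal(cs_coefficient(res_all)$value, 0.75)

  # a later failure cannot resurrect CS (monotone enforcement)
  res_gap <- fake_stability(c(0.1, 0.2, 0.3), list(pass, fail, pass))
  expect_equal(cs_coefficient(res_gap)$value, 0.1)

  res_empty <- fake_stability(c(0.1, 0.2), list(pass, numeric(0)))
  expect_error(cs_coefficient(res_empty), "no usable bootstrap")
})

test_that("relaxing the correlation threshold never decreases CS", {
  set.seed(31)
  cors <- lapply(c(0.99, 0.9, 0.8, 0.65, 0.5),
                 function(m) pmin(1, rnorm(60, m, 0.08)))
  res <- fake_stability(seq(0.1, 0.5, by = 0.1), cors)
  cs_vals <- vapply(c(0.9, 0.8, 0.7, 0.6, 0.5),
                    function(th) cs_coefficient(res, threshold = th)$value,
                    numeric(1))
  expect_false(is.unsorted(cs_vals))
})

test_that("drop level zero always correlates perfectly with the full sample", {
  pan <- strong_panel(n = 200, seed = 41)
  res <- case_drop_bootstrap(pan$wave1, metric = "edges",
                             drop_levels = c(0, 0.2), n_boot = 10,
                             seed = 3, n_lambda = 40, thr = 1e-7)
  expect_true(all(res$correlations[[1]] == 1))
  expect_identical(res$n_boot_per_level, c(5L, 5L))
})

test_that("bootstraps allocate equally with the remainder to shallow levels", {
  pan <- strong_panel(n = 150, seed = 43)
  res <- case_drop_bootstrap(pan$wave1, metric = "strength",
                             drop_levels = c(0.1, 0.3, 0.5), n_boot = 11,
                             seed = 5, n_lambda = 30, thr = 1e-7)
  expect_identical(res$n_boot_per_level, c(4L, 4L, 3L))
  expect_identical(vapply(res$correlations, length, integer(1)) +
                     res$failures, c(4L, 4L, 3L))
})

test_that("mean bootstrap correlation decays with the drop proportion", {
  pan <- strong_panel(n = 1000, seed = 21)
  res <- case_drop_bootstrap(pan$wave1, metric = "edges",
                             drop_levels = seq(0.1, 0.5, by = 0.1),
                             n_boot = 150, seed = 9, n_lambda = 50,
                             thr = 1e-7)
  m <- vapply(res$correlations, mean, numeric(1))
  expect_false(is.unsorted(rev(m)))
  expect_true(all(unlist(res$correlations) >= -1 &
                    unlist(res$correlations) <= 1))
  # identical seed reproduces the full bootstrap
  res2 <- case_drop_bootstrap(pan$wave1, metric = "edges",
                              drop_levels = seq(0.1, 0.5, by = 0.1),
                              n_boot = 150, seed = 9, n_lambda = 50,
                              thr = 1e-7)
  expect_identical(res$correlations, res2$correlations)
})

test_that("a pure-noise item does not destroy shallow-level edge stability", {
  pan <- strong_panel(n = 1000, seed = 21)
  X <- pan$wave1
  set.seed(4)
  X[, 10] <- sample(0:4, nrow(X), TRUE)
  res <- case_drop_bootstrap(X, metric = "edges",
                             drop_levels = c(0.05, 0.1, 0.2), n_boot = 60,
                             seed = 2, n_lambda = 50, thr = 1e-7)
  expect_true(all(unlist(res$correlations) > 0))
})

test_that("edge-stability CS does not degrade as the sample grows", {
  cfg0 <- simulation_config(n_subjects = 200, catalog = mixed_catalog(5, 5),
                            prevalence_w1 = 0.5, prevalence_w2 = 0.5,
                            weight_range = c(0.3, 0.5), within_density = 0.3,
                            between_density = 0.1, missing_rate = 0,
                            planted_changes = no_changes, seed = 21)
  truth <- build_true_network(cfg0)
  votes <- 0L
  for (s in 1:3) {
    cs_by_n <- vapply(c(200L, 400L, 1000L), function(n) {
      cfg <- cfg0
      cfg$n_subjects <- n
      cfg$seed <- 300L + s
      pan <- sim_panel_quiet(truth, cfg)
      res <- case_drop_bootstrap(pan$wave1, metric = "edges",
                                 drop_levels = seq(0.1, 0.5, by = 0.1),
                                 n_boot = 60, seed = s, n_lambda = 40,
                                 thr = 1e-7)
      cs_coefficient(res)$value
    }, numeric(1))
    if (!is.unsorted(cs_by_n)) votes <- votes + 1L
  }
  expect_gte(votes, 2L)
})
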