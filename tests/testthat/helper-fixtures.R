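# shared fixtures: small catalogs, latent samplers, seeded weight matrices

binary_catalog <- function(p, prefix = "b", scale = "DEP",
                           community = "affective", cutoff = 4) {
  item_catalog(sprintf("%s%02d", prefix, seq_len(p)), scale, community,
               2L, 1L, cutoff, 0)
}

# n_bin binary affective items + n_ord five-point isolation items
mixed_catalog <- function(n_bin = 10, n_ord = 5) {
  item_catalog(
    sprintf("v%02d", seq_len(n_bin + n_ord)),
    rep(c("DEP", "ISO"), c(n_bin, n_ord)),
    rep(c("affective", "isolation"), c(n_bin, n_ord)),
    rep(c(2L, 5L), c(n_bin, n_ord)),
    rep(c(1L, -1L), c(n_bin, n_ord)),
    rep(c(4, NA), c(n_bin, n_ord)),
    rep(c(0, 1), c(n_bin, n_ord))
  )
}

no_changes <- data.frame(item_i = character(), item_j = character(),
                         delta = numeric())

rmvn <- function(n, Sigma, seed) {
  set.seed(seed)
  matrix(rnorm(n * ncol(Sigma)), n) %*% chol(Sigma)
}

# tridiagonal chain precision with adjacent partials r
chain_precision <- function(p, r = 0.3) {
  K <- diag(p)
  for (i in seq_len(p - 1)) K[i, i + 1] <- K[i + 1, i] <- -r
  K
}

# equal-mass discretization into n_categories ordinal levels
discretize_cols <- function(Z, n_categories = 5L) {
  cuts <- qnorm(seq_len(n_categories - 1L) / n_categories)
  apply(Z, 2, findInterval, vec = cuts)
}

# seeded random PD correlation matrix
random_corr <- function(p, seed) {
  set.seed(seed)
  A <- crossprod(matrix(rnorm(2 * p * p), 2 * p, p)) / (2 * p)
  cov2cor(A)
}

# seeded sparse symmetric weight matrix in (-0.8, 0.8), zero diagonal
random_weights <- function(p, seed, density = 0.4) {
  set.seed(seed)
  W <- matrix(0, p, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      if (runif(1) < density)
        W[i, j] <- W[j, i] <- runif(1, -0.8, 0.8)
    }
  }
  colnames(W) <- rownames(W) <- sprintf("n%02d", seq_len(p))
  W
}

sim_panel_quiet <- function(truth, config, ...) {
  suppressWarnings(simulate_panel(truth, config, ...))
}

# hand-built stability result from a list of per-level correlation vectors
fake_stability <- function(levels, cors, metric = "edges") {
  structure(list(drop_levels = levels, correlations = cors,
                 n_boot_per_level = lengths(cors),
                 failures = rep(0L, length(levels)),
                 metric_kind = metric, seed = 1L,
                 full_statistics = numeric(0)),
            class = "stability_result")
}
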