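# statistic vector handed to the stability correlations
stat_vector <- function(net, metric, communities = NULL) {
  switch(metric,
         edges = {
           W <- net$weights
           W[upper.tri(W)]
         },
         strength = node_strength(net),
         bridge_strength = bridge_strength(net, communities),
         stop("unknown metric kind: ", metric))
}

#' Case-dropping bootstrap for network stability
#'
#' Repeatedly drops a proportion of subjects, re-estimates the network with
#' identical settings, and records the Pearson correlation between the
#' full-sample statistic vector (edge weights over unique pairs, node
#' strengths, or bridge strengths) and each re-estimate. Bootstraps are
#' divided equally across the drop levels, any remainder going to the
#' shallowest levels; each replicate drops `ceiling(level * n)` subjects
#' uniformly without replacement. Replicates whose re-estimation fails (or
#' whose statistic vector is degenerate, leaving the correlation undefined)
#' are excluded and counted.
#'
#' @param wave_data subjects x items matrix, or a `paired_panel` with
#'   `wave`.
#' @param metric one of `"edges"`, `"strength"`, `"bridge_strength"`.
#' @param drop_levels increasing case-drop proportions in `[0, 1)`; the
#'   default is 10 equally spaced levels from 0.05 to 0.75.
#' @param n_boot total number of bootstrap replicates across all levels.
#' @param seed RNG seed.
#' @param wave wave selector when a panel is supplied.
#' @param communities per-node community labels (needed for
#'   `bridge_strength`).
#' @param ... estimation settings forwarded to [estimate_network()].
#' @return A list of class `stability_result`: per-level correlation
#'   vectors, per-level replicate and failure counts, the metric kind, the
#'   seed, and the full-sample statistics.
#' @export
case_drop_bootstrap <- function(wave_data, metric = c("edges", "strength",
                                                      "bridge_strength"),
                                drop_levels = seq(0.05, 0.75,
                                                  length.out = 10),
                                n_boot = 1000, seed = 1L, wave = 1L,
                                communities = NULL, ...) {
  metric <- match.arg(metric)
  stopifnot(n_boot >= length(drop_levels),
            all(drop_levels >= 0), all(drop_levels < 1),
            !is.unsorted(drop_levels, strictly = TRUE))
  if (inherits(wave_data, "paired_panel")) {
    panel <- wave_data
    if (is.null(communities))
      communities <- stats::setNames(panel$catalog$community,
                                     panel$catalog$item_id)
    wave_data <- if (wave == 1L) panel$wave1 else panel$wave2
  }
  X <- as.matrix(wave_data)
  n <- nrow(X)

  full_net <- estimate_network(X, communities = communities, ...)
  full_stat <- stat_vector(full_net, metric, communities)

  L <- length(drop_levels)
  alloc <- rep(as.integer(n_boot) %/% L, L)
  rem <- as.integer(n_boot) %% L
  if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1L

  set.seed(seed)
  cors <- vector("list", L)
  failures <- integer(L)
  for (l in seq_len(L)) {
    n_drop <- ceiling(drop_levels[l] * n)
    if (n - n_drop < 3)
      stop("drop level ", drop_levels[l], " leaves fewer than 3 subjects")
    rl <- numeric(0)
    for (b in seq_len(alloc[l])) {
      keep <- sample.int(n, n - n_drop)
      r <- tryCatch({
        bnet <- estimate_network(X[keep, , drop = FALSE],
                                 communities = communities, ...)
        suppressWarnings(
          stats::cor(full_stat, stat_vector(bnet, metric, communities)))
      }, error = function(e) NA_real_)
      if (n_drop == 0L) r <- 1.0  # identical sample by construction
      if (is.na(r)) failures[l] <- failures[l] + 1L else rl <- c(rl, r)
    }
    cors[[l]] <- rl
  }
  structure(list(drop_levels = drop_levels, correlations = cors,
                 n_boot_per_level = alloc, failures = failures,
                 metric_kind = metric, seed = seed,
                 full_statistics = full_stat),
            class = "stability_result")
}

#' Correlation-stability (CS) coefficient
#'
#' A drop level *passes* when at least `probability` of its bootstrap
#' correlations reach `threshold` (equivalently, its empirical 5th
#' percentile is at or above the threshold at the defaults). The CS
#' coefficient is the largest level all of whose shallower levels also pass;
#' it is 0 when the shallowest level already fails. Values of at least 0.25
#' are conventionally required for interpretability, and 0.50 is preferred.
#'
#' @param result a [case_drop_bootstrap()] result.
#' @param threshold correlation threshold (default 0.70).
#' @param probability required probability of clearing the threshold
#'   (default 0.95).
#' @return A list of class `cs_coefficient`: `value`, the pass table, and
#'   the rule parameters.
#' @export
cs_coefficient <- function(result, threshold = 0.70, probability = 0.95) {
  stopifnot(inherits(result, "stability_result"),
            length(result$drop_levels) >= 1)
  empty <- vapply(result$correlations, length, integer(1)) == 0
  if (any(empty))
    stop("no usable bootstrap correlations at drop level(s): ",
         paste(result$drop_levels[empty], collapse = ", "))
  pass <- vapply(result$correlations,
                 function(r) mean(r >= threshold) >= probability,
                 logical(1))
  value <- 0
  for (l in seq_along(pass)) {
    if (!pass[l]) break
    value <- result$drop_levels[l]
  }
  tab <- data.frame(
    level = result$drop_levels,
    n_used = vapply(result$correlations, length, integer(1)),
    mean_cor = vapply(result$correlations, mean, numeric(1)),
    q05 = vapply(result$correlations, stats::quantile, numeric(1),
                 probs = 1 - probability, names = FALSE),
    pass = pass
  )
  structure(list(value = value, threshold_correlation = threshold,
                 probability = probability, metric_kind = result$metric_kind,
                 table = tab),
            class = "cs_coefficient")
}

#' @export
print.cs_coefficient <- function(x, ...) {
  cat(sprintf("CS(cor = %.2f) = %.3g for %s\n", x$threshold_correlation,
              x$value, x$metric_kind))
  print(x$table, digits = 3)
  invisible(x)
}
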