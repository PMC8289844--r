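#' Permute a paired panel by swapping waves within subjects
#'
#' Independently for each subject, the wave-1 and wave-2 response vectors
#' are exchanged with probability `prob`. This is the resampling scheme of
#' the paired network-comparison test: under the null hypothesis that the
#' two waves are exchangeable, swapping is distribution-preserving.
#'
#' @param panel a `paired_panel`.
#' @param prob per-subject swap probability (1/2 for the permutation null;
#'   0 and 1 give the identity and the full exchange).
#' @param seed optional RNG seed; when `NULL` the current RNG stream is
#'   used.
#' @return The permuted `paired_panel`, with the swap indicator attached as
#'   attribute `"swapped"`.
#' @export
paired_permute <- function(panel, prob = 0.5, seed = NULL) {
  stopifnot(inherits(panel, "paired_panel"), prob >= 0, prob <= 1)
  if (!identical(dim(panel$wave1), dim(panel$wave2)) ||
      !identical(rownames(panel$wave1), rownames(panel$wave2)))
    stop("panel waves are misaligned")
  if (!is.null(seed)) set.seed(seed)
  n <- length(panel$subject_ids)
  swap <- runif(n) < prob
  w1 <- panel$wave1
  w2 <- panel$wave2
  w1[swap, ] <- panel$wave2[swap, , drop = FALSE]
  w2[swap, ] <- panel$wave1[swap, , drop = FALSE]
  out <- panel
  out$wave1 <- w1
  out$wave2 <- w2
  attr(out, "swapped") <- swap
  out
}

# weights-only re-estimation used inside the permutation loop;
# settings mirror estimate_network exactly
estimate_weights_only <- function(X, gamma, n_lambda, lambda_min_ratio,
                                  thr, maxit) {
  C <- nearest_pd_repair(spearman_matrix(X))
  fit_ebic_path(C$values, n = nrow(X), gamma = gamma, n_lambda = n_lambda,
                lambda_min_ratio = lambda_min_ratio, thr = thr,
                maxit = maxit)$weights
}

nct_statistics <- function(W1, W2, cross, edge_idx) {
  D <- W2 - W1
  absW1 <- abs(W1)
  absW2 <- abs(W2)
  ut <- upper.tri(D)
  list(
    global = sum(absW2[ut]) - sum(absW1[ut]),
    max_edge = max(abs(D[ut])),
    edges = D[edge_idx],
    strength = colSums(absW2) - colSums(absW1),
    bridge = colSums(absW2 * cross) - colSums(absW1 * cross)
  )
}

#' Paired permutation network-comparison test
#'
#' Estimates one network per wave with identical settings and tests, against
#' the within-subject wave-swap permutation null: the global-strength
#' difference, the network-structure statistic (maximum absolute edge
#' difference), each edge difference over the union of edges nonzero in
#' either observed network, and each node's strength and bridge-strength
#' differences. Every permutation re-runs the full estimation (Spearman, PD
#' repair, glasso path, EBIC selection) on both permuted waves so that
#' model-selection variability propagates into the null distribution.
#' P-values use the add-one convention
#' `p = (1 + #permuted |stat| >= observed |stat|) / (1 + B)` and are
#' reported uncorrected unless `holm = TRUE`.
#'
#' @param panel a `paired_panel`.
#' @param n_permutations number of permutation iterations.
#' @param gamma,n_lambda,lambda_min_ratio,thr,maxit estimation settings,
#'   applied identically to observed and permuted fits.
#' @param edge_set `"union"` tests the edges nonzero in either observed
#'   network; `"all"` tests every node pair.
#' @param holm also report Holm-adjusted p-values for the edge and
#'   centrality families.
#' @param seed RNG seed.
#' @return A list of class `nct_result` with observed statistics, p-values,
#'   the tested edge set, permutation bookkeeping, and the two estimated
#'   networks.
#' @export
nct_paired <- function(panel, n_permutations = 5000, gamma = 0.5,
                       n_lambda = 100, lambda_min_ratio = 0.01,
                       edge_set = c("union", "all"), holm = FALSE,
                       seed = 1L, thr = 1e-8, maxit = 500) {
  stopifnot(inherits(panel, "paired_panel"), n_permutations >= 1)
  edge_set <- match.arg(edge_set)
  catalog <- panel$catalog
  communities <- stats::setNames(catalog$community, catalog$item_id)

  net1 <- estimate_network(panel, wave = 1L, gamma = gamma,
                           n_lambda = n_lambda,
                           lambda_min_ratio = lambda_min_ratio,
                           communities = communities, thr = thr,
                           maxit = maxit)
  net2 <- estimate_network(panel, wave = 2L, gamma = gamma,
                           n_lambda = n_lambda,
                           lambda_min_ratio = lambda_min_ratio,
                           communities = communities, thr = thr,
                           maxit = maxit)
  W1 <- net1$weights
  W2 <- net2$weights
  labels <- colnames(W1)
  p <- ncol(W1)
  comm <- communities[labels]
  cross <- outer(comm, comm, FUN = "!=")

  ut <- upper.tri(W1)
  edge_idx <- if (edge_set == "union") which(ut & (W1 != 0 | W2 != 0))
              else which(ut)
  idx_rc <- arrayInd(edge_idx, dim(W1))
  tested_edges <- data.frame(node_i = labels[idx_rc[, 1]],
                             node_j = labels[idx_rc[, 2]],
                             stringsAsFactors = FALSE)

  obs <- nct_statistics(W1, W2, cross, edge_idx)

  set.seed(seed)
  count_global <- 0L
  count_max <- 0L
  count_edges <- integer(length(edge_idx))
  count_strength <- integer(p)
  count_bridge <- integer(p)
  n_failed <- 0L
  n_done <- 0L
  w1m <- panel$wave1
  w2m <- panel$wave2
  n <- nrow(w1m)

  for (b in seq_len(n_permutations)) {
    swap <- runif(n) < 0.5
    X1 <- w1m
    X2 <- w2m
    X1[swap, ] <- w2m[swap, , drop = FALSE]
    X2[swap, ] <- w1m[swap, , drop = FALSE]
    perm <- tryCatch({
      P1 <- estimate_weights_only(X1, gamma, n_lambda, lambda_min_ratio,
                                  thr, maxit)
      P2 <- estimate_weights_only(X2, gamma, n_lambda, lambda_min_ratio,
                                  thr, maxit)
      nct_statistics(P1, P2, cross, edge_idx)
    }, error = function(e) NULL)
    if (is.null(perm)) {
      n_failed <- n_failed + 1L
      next
    }
    n_done <- n_done + 1L
    if (abs(perm$global) >= abs(obs$global)) count_global <- count_global + 1L
    if (perm$max_edge >= obs$max_edge) count_max <- count_max + 1L
    count_edges <- count_edges + (abs(perm$edges) >= abs(obs$edges))
    count_strength <- count_strength + (abs(perm$strength) >= abs(obs$strength))
    count_bridge <- count_bridge + (abs(perm$bridge) >= abs(obs$bridge))
  }
  if (n_failed > 0.01 * n_permutations)
    stop("more than 1% of permutation re-estimations failed (",
         n_failed, " of ", n_permutations, ")")

  addone <- function(k) (1 + k) / (1 + n_done)
  p_values <- list(
    global_strength = addone(count_global),
    max_edge = addone(count_max),
    edges = stats::setNames(addone(count_edges),
                            paste(tested_edges$node_i, tested_edges$node_j,
                                  sep = "--")),
    strength = stats::setNames(addone(count_strength), labels),
    bridge_strength = stats::setNames(addone(count_bridge), labels)
  )
  if (holm) {
    p_values$edges_holm <- stats::p.adjust(p_values$edges, method = "holm")
    p_values$strength_holm <- stats::p.adjust(p_values$strength,
                                              method = "holm")
    p_values$bridge_strength_holm <-
      stats::p.adjust(p_values$bridge_strength, method = "holm")
  }

  structure(list(
    observed = list(
      global_strength_diff = obs$global,
      max_edge_diff = obs$max_edge,
      edge_diffs = stats::setNames(obs$edges, names(p_values$edges)),
      strength_diffs = stats::setNames(obs$strength, labels),
      bridge_strength_diffs = stats::setNames(obs$bridge, labels)
    ),
    p_values = p_values,
    tested_edge_set = tested_edges,
    n_permutations = n_permutations,
    n_completed = n_done,
    n_failed = n_failed,
    seed = seed,
    networks = list(wave1 = net1, wave2 = net2)
  ), class = "nct_result")
}

#' Edges with significant change between waves
#'
#' @param result an [nct_paired()] result.
#' @param alpha significance level.
#' @param adjusted use Holm-adjusted edge p-values when available.
#' @return Data frame of tested edges with their observed differences and
#'   p-values, restricted to `p < alpha`.
#' @export
significant_edges <- function(result, alpha = 0.05, adjusted = FALSE) {
  stopifnot(inherits(result, "nct_result"))
  pv <- if (adjusted && !is.null(result$p_values$edges_holm))
    result$p_values$edges_holm else result$p_values$edges
  df <- cbind(result$tested_edge_set,
              diff = unname(result$observed$edge_diffs),
              p = unname(pv))
  df <- df[df$p < alpha, , drop = FALSE]
  df[order(df$p, -abs(df$diff)), , drop = FALSE]
}

#' @export
print.nct_result <- function(x, ...) {
  cat("paired network comparison test (", x$n_completed, "of",
      x$n_permutations, "permutations )\n")
  cat(sprintf("  global strength diff = %.4f (p = %.4f)\n",
              x$observed$global_strength_diff, x$p_values$global_strength))
  cat(sprintf("  max edge diff        = %.4f (p = %.4f)\n",
              x$observed$max_edge_diff, x$p_values$max_edge))
  cat("  tested edges:", nrow(x$tested_edge_set), "; significant at 0.05:",
      sum(x$p_values$edges < 0.05), "\n")
  invisible(x)
}
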