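#' Pairwise-complete Spearman correlation matrix
#'
#' Each entry is the Spearman rank correlation computed over the subjects
#' observed on *both* items of the pair (pairwise deletion), with ties
#' handled by average ranks. The number of complete pairs per entry is
#' recorded alongside.
#'
#' @param wave_data numeric/integer subjects x items matrix, `NA` = missing.
#' @return A list of class `correlation_matrix` with elements `values`
#'   (symmetric, unit diagonal), `pairwise_n`, and `repaired = FALSE`.
#' @export
spearman_matrix <- function(wave_data) {
  X <- as.matrix(wave_data)
  storage.mode(X) <- "double"
  p <- ncol(X)
  items <- colnames(X)
  if (is.null(items)) items <- paste0("V", seq_len(p))

  obs <- !is.na(X)
  pair_n <- crossprod(obs)
  storage.mode(pair_n) <- "integer"
  if (any(pair_n < 3)) {
    bad <- which(pair_n < 3, arr.ind = TRUE)
    bad <- bad[bad[, 1] <= bad[, 2], , drop = FALSE][1, ]
    stop("fewer than 3 complete pairs for items ", items[bad[1]],
         " and ", items[bad[2]])
  }
  item_var <- vapply(seq_len(p), function(j) stats::var(X[obs[, j], j]),
                     numeric(1))
  if (any(item_var == 0))
    stop("zero variance on complete cases for item(s): ",
         paste(items[item_var == 0], collapse = ", "))

  if (!anyNA(X)) {
    # complete data: rank once, then Pearson on ranks
    R <- apply(X, 2, rank)
    V <- stats::cor(R)
  } else {
    V <- suppressWarnings(
      stats::cor(X, method = "spearman", use = "pairwise.complete.obs"))
    if (anyNA(V)) {
      bad <- which(is.na(V), arr.ind = TRUE)[1, ]
      # an item constant on the pair's complete cases
      keep <- obs[, bad[1]] & obs[, bad[2]]
      culprit <- if (stats::var(X[keep, bad[1]]) == 0) bad[1] else bad[2]
      stop("zero variance on complete cases for item(s): ", items[culprit])
    }
  }
  V <- (V + t(V)) / 2
  diag(V) <- 1
  dimnames(V) <- dimnames(pair_n) <- list(items, items)
  structure(list(values = V, pairwise_n = pair_n, repaired = FALSE),
            class = "correlation_matrix")
}

cor_values <- function(C) {
  if (inherits(C, "correlation_matrix")) C$values else as.matrix(C)
}

#' Repair a correlation matrix to positive definiteness
#'
#' Eigenvalues are clipped at `1e-8` and the matrix rescaled back to unit
#' diagonal, iterating until the minimum eigenvalue clears the floor. Leaves
#' already positive-definite input untouched; idempotent.
#'
#' @param C a `correlation_matrix` or plain symmetric unit-diagonal matrix.
#' @param floor eigenvalue floor.
#' @return A `correlation_matrix` with the `repaired` flag set iff any
#'   clipping occurred.
#' @export
nearest_pd_repair <- function(C, floor = 1e-8) {
  V <- cor_values(C)
  pair_n <- if (inherits(C, "correlation_matrix")) C$pairwise_n else NULL
  clipped_any <- FALSE
  for (pass in 1:100) {
    out <- pd_clip(V, floor = floor)
    V <- out$mat
    clipped_any <- clipped_any || out$clipped
    if (!out$clipped) break
  }
  diag(V) <- 1
  structure(list(values = V, pairwise_n = pair_n, repaired = clipped_any),
            class = "correlation_matrix")
}

#' Graphical lasso fit at a single penalty
#'
#' Maximizes `log det K - tr(C K) - lambda * sum_{i != j} |K_ij|` (penalty on
#' off-diagonal entries only) by blockwise coordinate descent, returning a
#' precision matrix with exact zeros.
#'
#' @param C positive-definite correlation matrix (or `correlation_matrix`).
#' @param lambda penalty level, >= 0.
#' @param thr relative convergence threshold.
#' @param maxit maximum outer sweeps.
#' @return A list of class `precision_matrix` with `values` and `lambda`.
#' @export
glasso_fit <- function(C, lambda, thr = 1e-8, maxit = 500) {
  stopifnot(lambda >= 0)
  S <- cor_values(C)
  fit <- glasso_path_cpp(S, lambda, thr = thr, maxit = maxit)
  if (!fit$converged[1])
    stop("glasso did not converge at lambda = ", lambda, " within ",
         fit$iterations[1], " sweeps")
  K <- matrix(fit$K[, , 1], nrow(S), ncol(S), dimnames = dimnames(S))
  structure(list(values = K, lambda = lambda), class = "precision_matrix")
}

precision_values <- function(K) {
  if (inherits(K, "precision_matrix")) K$values else as.matrix(K)
}

#' Extended BIC of a fitted precision matrix
#'
#' `EBIC = -2 L + E log(n) + 4 E gamma log(p)` where
#' `L = (n/2) (log det K - tr(C K))` and `E` counts the nonzero
#' upper-triangular off-diagonal entries of `K`. At `gamma = 0` this is the
#' ordinary BIC.
#'
#' @param K fitted precision (`precision_matrix` or matrix); must be PD.
#' @param C the correlation matrix the model was fit to.
#' @param n sample size (>= 2).
#' @param gamma EBIC hyperparameter (>= 0).
#' @return The EBIC score (smaller is better).
#' @export
ebic_score <- function(K, C, n, gamma = 0.5) {
  stopifnot(n >= 2, gamma >= 0)
  Kv <- precision_values(K)
  Cv <- cor_values(C)
  ch <- tryCatch(chol(Kv), error = function(e) NULL)
  if (is.null(ch)) stop("precision matrix is not positive-definite")
  p <- ncol(Kv)
  L <- (n / 2) * (2 * sum(log(diag(ch))) - sum(Cv * Kv))
  E <- sum(Kv[upper.tri(Kv)] != 0)
  -2 * L + E * log(n) + 4 * E * gamma * log(p)
}

#' Check the glasso subgradient (KKT) conditions
#'
#' At the solution, with `W = K^-1`: zero entries must satisfy
#' `|C_ij - W_ij| <= lambda + tol` and nonzero entries
#' `C_ij - W_ij = -lambda * sign(K_ij)` within `tol`.
#'
#' @param K fitted precision.
#' @param C the input correlation matrix.
#' @param lambda the penalty used.
#' @param tol tolerance.
#' @return A list with `ok` (logical) and the worst violations on the zero
#'   and nonzero patterns.
#' @export
check_glasso_kkt <- function(K, C, lambda, tol = 1e-4) {
  Kv <- precision_values(K)
  Cv <- cor_values(C)
  W <- solve(Kv)
  D <- Cv - W
  off <- upper.tri(Kv)
  zero <- off & Kv == 0
  nonzero <- off & Kv != 0
  viol_zero <- if (any(zero)) max(abs(D[zero]) - lambda) else -Inf
  viol_nonzero <- if (any(nonzero))
    max(abs(D[nonzero] + lambda * sign(Kv[nonzero]))) else -Inf
  list(ok = viol_zero <= tol && viol_nonzero <= tol,
       max_violation_zero = viol_zero,
       max_violation_nonzero = viol_nonzero)
}

# EBIC-selected glasso over a descending log-spaced lambda path.
# Returns the selected precision/partials plus the full (lambda, EBIC, E)
# path. Ties in EBIC resolve to the larger lambda (sparser model) because
# the path is descending and which.min takes the first minimum.
fit_ebic_path <- function(S, n, gamma, n_lambda, lambda_min_ratio,
                          thr = 1e-8, maxit = 500) {
  p <- ncol(S)
  off <- abs(S[upper.tri(S)])
  lambda_max <- if (length(off)) max(off) else 0
  if (lambda_max < 1e-10) {
    K <- diag(p)
    dimnames(K) <- dimnames(S)
    return(list(
      K = K, weights = partials_from_precision(K),
      selected_lambda = Inf,
      ebic_path = data.frame(lambda = numeric(), ebic = numeric(),
                             n_edges = integer())
    ))
  }
  lambdas <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                     length.out = n_lambda))
  fit <- glasso_path_cpp(S, lambdas, thr = thr, maxit = maxit)
  if (any(!fit$converged)) {
    bad <- which(!fit$converged)[1]
    stop("glasso did not converge at lambda = ", lambdas[bad], " within ",
         fit$iterations[bad], " sweeps")
  }
  ebic <- -n * (fit$logdet - fit$trSK) + fit$n_edges * log(n) +
    4 * fit$n_edges * gamma * log(p)
  sel <- which.min(ebic)
  K <- fit$K[, , sel]
  dimnames(K) <- dimnames(S)
  list(K = K, weights = partials_from_precision(K),
       selected_lambda = lambdas[sel],
       ebic_path = data.frame(lambda = lambdas, ebic = ebic,
                              n_edges = fit$n_edges))
}

#' Estimate a regularized partial-correlation network for one wave
#'
#' Pipeline: pairwise-complete Spearman correlations, positive-definite
#' repair, graphical lasso over a descending log-spaced penalty path from
#' `lambda_max` (the largest absolute off-diagonal correlation) down to
#' `lambda_max * lambda_min_ratio`, EBIC model selection with hyperparameter
#' `gamma` (ties resolve to the sparser model), and conversion of the
#' selected precision to partial correlations
#' `omega_ij = -K_ij / sqrt(K_ii K_jj)`.
#'
#' @param wave_data subjects x items response matrix (`NA` = missing), or a
#'   `paired_panel` together with `wave`.
#' @param gamma EBIC hyperparameter; 0.5 is the conventional default.
#' @param n_lambda number of penalty values on the path.
#' @param lambda_min_ratio ratio of the smallest to the largest penalty.
#' @param wave which wave to use when `wave_data` is a `paired_panel`.
#' @param communities optional per-node community labels (taken from the
#'   panel catalog when available).
#' @param n_method sample size handed to EBIC under pairwise deletion:
#'   number of subjects (default) or the minimum pairwise-complete count.
#' @param thr,maxit solver convergence controls.
#' @return A list of class `item_network`: `weights` (partial correlations,
#'   zero diagonal), `precision`, `selected_lambda`, `gamma`, `ebic_path`,
#'   `n_used`, `node_labels`, `communities`, `correlation` (the repaired
#'   input), and the path settings.
#' @export
estimate_network <- function(wave_data, gamma = 0.5, n_lambda = 100,
                             lambda_min_ratio = 0.01, wave = 1L,
                             communities = NULL,
                             n_method = c("subjects", "min_pairwise"),
                             thr = 1e-8, maxit = 500) {
  n_method <- match.arg(n_method)
  if (inherits(wave_data, "paired_panel")) {
    panel <- wave_data
    wave_data <- if (wave == 1L) panel$wave1 else panel$wave2
    if (is.null(communities))
      communities <- stats::setNames(panel$catalog$community,
                                     panel$catalog$item_id)
  }
  X <- as.matrix(wave_data)
  C <- nearest_pd_repair(spearman_matrix(X))
  n_used <- switch(n_method,
                   subjects = nrow(X),
                   min_pairwise = min(C$pairwise_n))
  sel <- fit_ebic_path(C$values, n = n_used, gamma = gamma,
                       n_lambda = n_lambda,
                       lambda_min_ratio = lambda_min_ratio,
                       thr = thr, maxit = maxit)
  labels <- colnames(C$values)
  if (!is.null(communities)) communities <- communities[labels]
  structure(list(
    weights = sel$weights,
    precision = sel$K,
    selected_lambda = sel$selected_lambda,
    gamma = gamma,
    ebic_path = sel$ebic_path,
    n_used = n_used,
    node_labels = labels,
    communities = communities,
    correlation = C,
    repaired = C$repaired,
    settings = list(n_lambda = n_lambda,
                    lambda_min_ratio = lambda_min_ratio,
                    n_method = n_method, thr = thr, maxit = maxit)
  ), class = "item_network")
}

#' Wrap a weight matrix as a network object
#'
#' Mainly for constructing hand-built networks when computing descriptive
#' statistics on known weights.
#'
#' @param weights symmetric partial-correlation matrix with zero diagonal.
#' @param communities optional named per-node community labels.
#' @return An `item_network`.
#' @export
network_from_weights <- function(weights, communities = NULL) {
  W <- as.matrix(weights)
  if (is.null(colnames(W)))
    colnames(W) <- rownames(W) <- paste0("V", seq_len(ncol(W)))
  if (max(abs(W - t(W))) > 1e-12) stop("weights must be symmetric")
  if (any(diag(W) != 0)) stop("weights must have a zero diagonal")
  if (any(abs(W[upper.tri(W)]) >= 1)) stop("weights must lie in (-1, 1)")
  if (!is.null(communities)) communities <- communities[colnames(W)]
  structure(list(weights = W, precision = NULL, selected_lambda = NA_real_,
                 gamma = NA_real_, ebic_path = NULL, n_used = NA_integer_,
                 node_labels = colnames(W), communities = communities,
                 correlation = NULL, repaired = FALSE, settings = list()),
            class = "item_network")
}

#' @export
print.item_network <- function(x, ...) {
  E <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat("item_network:", ncol(x$weights), "nodes,", E, "nonzero edges")
  if (!is.na(x$selected_lambda))
    cat(sprintf(", lambda = %.4g (gamma = %.2g, n = %d)",
                x$selected_lambda, x$gamma, x$n_used))
  cat("\n")
  invisible(x)
}
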