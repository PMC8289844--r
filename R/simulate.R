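#' Simulation configuration for paired two-wave item panels
#'
#' Bundles everything the synthetic-data generator needs: the item catalog,
#' sample size, block edge densities of the true partial-correlation graph,
#' the range of nonzero true partials, per-item endorsement probabilities at
#' each wave, the per-item latent test-retest correlation coupling the two
#' waves, the missing-completely-at-random cell rate, and the RNG seed.
#'
#' `weight_range` applies to the *target* partials drawn before the
#' positive-definite repair; the realized truth stored after repair is
#' attenuated (largest realized partials around 0.3 at the defaults, in line
#' with the strongest edges such item networks exhibit).
#'
#' Default prevalences reproduce a realistic geriatric battery: rare
#' depressive/anxious endorsements at wave 1 that worsen at wave 2, and
#' social-isolation items that deteriorate slightly (on the keyed,
#' higher-is-worse latent scale). The default missing rate of 24/34,358
#' yields about 24 missing cells on the default 419 x 41 x 2 panel.
#'
#' @param n_subjects number of subjects completing both waves.
#' @param catalog an [item_catalog()].
#' @param within_density probability of a true edge between two items of the
#'   same scale.
#' @param between_density probability of a true edge between items of
#'   different scales.
#' @param weight_range interval (within (0, 1)) for nonzero true partials.
#' @param prevalence_w1,prevalence_w2 per-item endorsement probabilities on
#'   the keyed (higher = worse) scale; either a named vector over items, a
#'   named vector over scales, or `NULL` for the package defaults.
#' @param cross_wave_rho per-item latent correlation between waves, in
#'   `[0, 1)`; scalar or named vector over items.
#' @param missing_rate per-cell MCAR masking probability in `[0, 1)`.
#' @param planted_changes optional data frame with columns `item_i`,
#'   `item_j`, `delta` describing wave-2 edge perturbations; `NULL` selects
#'   the default plan (strengthen affective--isolation edges by +0.10 and
#'   within-ISO edges by +0.05).
#' @param seed integer RNG seed driving both truth construction and panel
#'   simulation.
#'
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 419,
                              catalog = default_item_catalog(),
                              within_density = 0.10,
                              between_density = 0.015,
                              weight_range = c(0.4, 0.6),
                              prevalence_w1 = NULL,
                              prevalence_w2 = NULL,
                              cross_wave_rho = 0.5,
                              missing_rate = 24 / 34358,
                              planted_changes = NULL,
                              seed = 1L) {
  catalog <- validate_item_catalog(catalog)
  stopifnot(
    n_subjects >= 1,
    within_density >= 0, within_density <= 1,
    between_density >= 0, between_density <= 1,
    length(weight_range) == 2, all(weight_range > 0), all(weight_range < 1),
    weight_range[1] <= weight_range[2],
    missing_rate >= 0, missing_rate < 1
  )
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    catalog = catalog,
    within_density = within_density,
    between_density = between_density,
    weight_range = weight_range,
    prevalence_w1 = expand_prevalence(prevalence_w1, catalog, wave = 1L),
    prevalence_w2 = expand_prevalence(prevalence_w2, catalog, wave = 2L),
    cross_wave_rho = expand_item_scalar(cross_wave_rho, catalog,
                                        "cross_wave_rho"),
    missing_rate = missing_rate,
    planted_changes = planted_changes,
    seed = as.integer(seed)
  )
  stopifnot(all(cfg$prevalence_w1 > 0 & cfg$prevalence_w1 < 1),
            all(cfg$prevalence_w2 > 0 & cfg$prevalence_w2 < 1),
            all(cfg$cross_wave_rho >= 0 & cfg$cross_wave_rho < 1))
  class(cfg) <- "simulation_config"
  cfg
}

# Table-1-anchored per-scale endorsement defaults on the keyed scale
# (wave 1: GDS 1.02/15, GAI 1.12/20, TFS keyed (5 - 25.51/6)/4;
#  wave 2: GDS 2.11/15, GAI 1.38/20, TFS keyed (5 - 24.70/6)/4)
default_prevalence <- function(wave) {
  if (wave == 1L) c(DEP = 1.02 / 15, ANX = 1.12 / 20,
                    ISO = (5 - 25.51 / 6) / 4)
  else            c(DEP = 2.11 / 15, ANX = 1.38 / 20,
                    ISO = (5 - 24.70 / 6) / 4)
}

expand_prevalence <- function(prev, catalog, wave) {
  if (is.null(prev)) {
    by_scale <- default_prevalence(wave)
    missing_scales <- setdiff(unique(catalog$scale), names(by_scale))
    if (length(missing_scales)) {
      by_scale <- c(by_scale,
                    stats::setNames(rep(0.5, length(missing_scales)),
                                    missing_scales))
    }
    return(stats::setNames(by_scale[catalog$scale], catalog$item_id))
  }
  if (!is.null(names(prev)) && all(names(prev) %in% catalog$scale) &&
      length(prev) == length(unique(catalog$scale))) {
    return(stats::setNames(prev[catalog$scale], catalog$item_id))
  }
  if (length(prev) == 1L)
    return(stats::setNames(rep(prev, nrow(catalog)), catalog$item_id))
  if (length(prev) != nrow(catalog))
    stop("prevalence must be scalar, per-scale named, or per-item")
  if (!is.null(names(prev))) prev <- prev[catalog$item_id]
  stats::setNames(as.numeric(prev), catalog$item_id)
}

expand_item_scalar <- function(x, catalog, what) {
  if (length(x) == 1L)
    return(stats::setNames(rep(x, nrow(catalog)), catalog$item_id))
  if (length(x) != nrow(catalog))
    stop(what, " must be scalar or one value per item")
  if (!is.null(names(x))) x <- x[catalog$item_id]
  stats::setNames(as.numeric(x), catalog$item_id)
}

#' Convert a precision matrix to partial correlations
#'
#' `omega_ij = -K_ij / sqrt(K_ii K_jj)` with a zero diagonal.
#'
#' @param K symmetric positive-definite precision matrix.
#' @return Symmetric partial-correlation matrix with zero diagonal.
#' @export
partials_from_precision <- function(K) {
  d <- sqrt(diag(K))
  P <- -K / tcrossprod(d)
  diag(P) <- 0
  dimnames(P) <- dimnames(K)
  P
}

# Latent cutpoints for an item: C-1 strictly increasing thresholds on the
# standard-normal severity scale. For binary items P(keyed = 1) = prevalence
# exactly; for C > 2 the equal-mass base grid is shifted so that raising
# prevalence monotonically shifts mass toward worse categories.
item_thresholds <- function(n_categories, prevalence) {
  k <- seq_len(n_categories - 1L)
  qnorm(k / n_categories) + qnorm(1 - prevalence)
}

# smallest ridge delta on a fixed grid making min eigenvalue >= 0.05
ridge_to_pd <- function(K, target = 0.05, grid = seq(0, 2, by = 0.01)) {
  for (delta in grid) {
    ev <- eigen(K + delta * diag(nrow(K)), symmetric = TRUE,
                only.values = TRUE)$values
    if (min(ev) >= target) return(delta)
  }
  stop("positive-definite repair failed: ridge grid exhausted ",
       "(min eigenvalue ", signif(min(ev), 3), " at delta = ",
       max(grid), ")")
}

#' Build the true paired-wave network
#'
#' Draws a sparse symmetric target partial-correlation matrix with
#' block-structured density (within-scale vs between-scale pairs), forms the
#' precision `K = I - P`, repairs it to positive definiteness by adding the
#' smallest ridge `delta * I` on a 0.01-spaced grid such that the minimum
#' eigenvalue is at least 0.05, rescales to unit diagonal, and stores the
#' *realized* partials recomputed from the repaired precision. Wave 2 starts
#' from the wave-1 target with the planted edge perturbations applied before
#' its own repair, so the planted differences survive into the realized
#' truth (attenuated by the repair).
#'
#' @param config a [simulation_config()].
#' @return A list of class `ground_truth` with per-wave realized partials,
#'   correlation-scale precisions, item thresholds, the cross-wave coupling,
#'   and the planted changes actually applied.
#' @export
build_true_network <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  catalog <- config$catalog
  p <- nrow(catalog)
  items <- catalog$item_id
  set.seed(config$seed)

  # wave-1 target partials
  P1 <- matrix(0, p, p, dimnames = list(items, items))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      dens <- if (catalog$scale[i] == catalog$scale[j])
        config$within_density else config$between_density
      if (dens > 0 && runif(1) < dens) {
        w <- runif(1, config$weight_range[1], config$weight_range[2])
        P1[i, j] <- P1[j, i] <- w
      }
    }
  }

  planted <- config$planted_changes
  if (is.null(planted)) planted <- default_planted_changes(P1, catalog)
  unknown <- setdiff(unique(c(planted$item_i, planted$item_j)), items)
  if (length(unknown))
    stop("planted change references unknown item(s): ",
         paste(unknown, collapse = ", "))

  P2 <- P1
  if (nrow(planted)) {
    for (r in seq_len(nrow(planted))) {
      i <- match(planted$item_i[r], items)
      j <- match(planted$item_j[r], items)
      if (i == j) stop("planted change on the diagonal: ", planted$item_i[r])
      P2[i, j] <- P2[i, j] + planted$delta[r]
      P2[j, i] <- P2[i, j]
    }
  }

  finalize <- function(P) {
    K <- diag(p) - P
    delta <- ridge_to_pd(K)
    K <- K + delta * diag(p)
    K <- stats::cov2cor(K)
    dimnames(K) <- list(items, items)
    list(K = K, delta = delta)
  }
  w1 <- finalize(P1)
  w2 <- finalize(P2)

  thr <- function(prev) {
    stats::setNames(lapply(seq_len(p), function(i)
      item_thresholds(catalog$n_categories[i], prev[[items[i]]])), items)
  }

  structure(list(
    partials_w1 = partials_from_precision(w1$K),
    partials_w2 = partials_from_precision(w2$K),
    precisions_w1 = w1$K,
    precisions_w2 = w2$K,
    target_w1 = P1,
    target_w2 = P2,
    ridge_delta = c(w1 = w1$delta, w2 = w2$delta),
    thresholds_w1 = thr(config$prevalence_w1),
    thresholds_w2 = thr(config$prevalence_w2),
    cross_wave_rho = config$cross_wave_rho,
    planted_changes = planted,
    catalog = catalog
  ), class = "ground_truth")
}

# default wave-2 perturbation plan derived from the wave-1 target:
# +0.10 on every existing affective--isolation edge, +0.05 within ISO
default_planted_changes <- function(P1, catalog) {
  items <- catalog$item_id
  out <- list()
  p <- length(items)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      if (P1[i, j] == 0) next
      cross <- catalog$community[i] != catalog$community[j]
      within_iso <- catalog$scale[i] == "ISO" && catalog$scale[j] == "ISO"
      if (cross) {
        out[[length(out) + 1L]] <-
          data.frame(item_i = items[i], item_j = items[j], delta = 0.10)
      } else if (within_iso) {
        out[[length(out) + 1L]] <-
          data.frame(item_i = items[i], item_j = items[j], delta = 0.05)
      }
    }
  }
  if (!length(out))
    return(data.frame(item_i = character(), item_j = character(),
                      delta = numeric()))
  do.call(rbind, out)
}

# eigenvalue clipping to PD with unit-diagonal rescale; reports whether any
# clipping happened and the largest entry change it caused
pd_clip <- function(M, floor = 1e-8) {
  e <- eigen(M, symmetric = TRUE)
  clipped <- any(e$values < floor)
  if (clipped) {
    vals <- pmax(e$values, floor)
    M2 <- e$vectors %*% (vals * t(e$vectors))
    M2 <- (M2 + t(M2)) / 2
    M2 <- stats::cov2cor(M2)
    dimnames(M2) <- dimnames(M)
  } else {
    M2 <- M
  }
  list(mat = M2, clipped = clipped, max_change = max(abs(M2 - M)))
}

#' Simulate a paired two-wave item panel from known truth
#'
#' Each subject receives a `2p`-dimensional latent normal whose per-wave
#' blocks are the correlation-scale inverses of the true precisions and whose
#' cross-wave block is diagonal with the per-item coupling `cross_wave_rho`.
#' The joint covariance is repaired to positive definiteness by eigenvalue
#' clipping at `1e-8` with a unit-diagonal rescale (a warning is raised if
#' the repair moves any entry by more than 0.05). Latents are discretized
#' through each item's wave-specific cutpoints; binary/keyed items are
#' emitted on the keyed scale (higher = worse) while `keyed_direction = -1`
#' items are emitted raw (higher = better). MCAR masking is applied at
#' `config$missing_rate`.
#'
#' @param truth a [build_true_network()] result.
#' @param config the same [simulation_config()] used to build the truth.
#' @param keep_latents if `TRUE`, attach the simulated latent matrix as
#'   attribute `"latents"` (an `n x 2p` matrix, wave-1 columns first).
#' @return A `paired_panel`: list with `subject_ids`, integer matrices
#'   `wave1` and `wave2` (`NA` = missing), and the catalog.
#' @export
simulate_panel <- function(truth, config, keep_latents = FALSE) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(config, "simulation_config"))
  catalog <- config$catalog
  p <- nrow(catalog)
  if (!identical(dim(truth$precisions_w1), c(p, p)))
    stop("truth and config dimensions disagree")
  n <- config$n_subjects

  sigma_w <- function(K) stats::cov2cor(solve(K))
  S1 <- sigma_w(truth$precisions_w1)
  S2 <- sigma_w(truth$precisions_w2)
  R <- diag(truth$cross_wave_rho, p)
  joint <- rbind(cbind(S1, R), cbind(R, S2))
  repair <- pd_clip(joint)
  if (repair$max_change > 0.05)
    warning("joint covariance repair moved an entry by ",
            signif(repair$max_change, 3), " (> 0.05)")
  joint <- repair$mat

  set.seed(config$seed)
  L <- chol(joint)
  Z <- matrix(rnorm(n * 2L * p), nrow = n) %*% L

  discretize <- function(zcols, thresholds) {
    out <- matrix(0L, n, p, dimnames = list(NULL, catalog$item_id))
    for (i in seq_len(p)) {
      keyed <- findInterval(zcols[, i], thresholds[[i]])
      if (catalog$keyed_direction[i] == -1L)
        keyed <- (catalog$n_categories[i] - 1L) - keyed
      out[, i] <- as.integer(keyed)
    }
    out
  }
  w1 <- discretize(Z[, seq_len(p), drop = FALSE], truth$thresholds_w1)
  w2 <- discretize(Z[, p + seq_len(p), drop = FALSE], truth$thresholds_w2)

  panel <- new_paired_panel(
    subject_ids = sprintf("s%04d", seq_len(n)),
    wave1 = w1, wave2 = w2, catalog = catalog
  )
  if (config$missing_rate > 0)
    panel <- apply_missingness(panel, config$missing_rate,
                               seed = config$seed)
  if (keep_latents) attr(panel, "latents") <- Z
  panel
}

new_paired_panel <- function(subject_ids, wave1, wave2, catalog) {
  stopifnot(nrow(wave1) == length(subject_ids),
            identical(dim(wave1), dim(wave2)),
            identical(colnames(wave1), catalog$item_id),
            identical(colnames(wave2), catalog$item_id))
  rownames(wave1) <- rownames(wave2) <- subject_ids
  structure(list(subject_ids = subject_ids, wave1 = wave1, wave2 = wave2,
                 catalog = catalog),
            class = "paired_panel")
}

#' Mask panel cells completely at random
#'
#' Every observed cell in either wave is independently set to missing with
#' probability `rate`. Subject and item structure are untouched.
#'
#' @param panel a `paired_panel`.
#' @param rate masking probability in `[0, 1)`.
#' @param seed RNG seed.
#' @return The masked `paired_panel`.
#' @export
apply_missingness <- function(panel, rate, seed = 1L) {
  stopifnot(inherits(panel, "paired_panel"))
  if (rate >= 1) stop("missing rate must be < 1")
  if (rate < 0) stop("missing rate must be non-negative")
  if (rate == 0) return(panel)
  set.seed(seed)
  mask_one <- function(m) {
    keep <- !is.na(m)
    hit <- matrix(runif(length(m)) < rate, nrow(m), ncol(m))
    m[keep & hit] <- NA_integer_
    m
  }
  panel$wave1 <- mask_one(panel$wave1)
  panel$wave2 <- mask_one(panel$wave2)
  panel
}

#' @export
print.paired_panel <- function(x, ...) {
  n_miss <- sum(is.na(x$wave1)) + sum(is.na(x$wave2))
  cat("paired_panel:", length(x$subject_ids), "subjects x",
      ncol(x$wave1), "items x 2 waves (",
      n_miss, "missing cells of", 2L * length(x$wave1), ")\n")
  invisible(x)
}
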