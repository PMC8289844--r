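#' Score scale totals for both waves
#'
#' Item responses are scored per the catalog (per-item `score_offset` added,
#' e.g. five-point items stored 0--4 score 1--5) and summed within each
#' scale. A subject-scale total is valid only when at least 80% of the
#' scale's items are observed; missing items are then imputed with the
#' subject's mean over the scale's observed items (proration, i.e. total =
#' observed sum x n_items / n_observed) and the total rounded to 2 decimals.
#' Invalid totals are `NA` and drop out of paired tests pairwise.
#'
#' @param panel a `paired_panel`.
#' @param catalog item catalog; defaults to the panel's own.
#' @param min_prop minimum proportion of items observed for a valid total.
#' @return Long data frame with columns `subject_id`, `scale`, `wave`,
#'   `total`, `valid`.
#' @export
score_scales <- function(panel, catalog = NULL, min_prop = 0.8) {
  stopifnot(inherits(panel, "paired_panel"))
  if (is.null(catalog)) catalog <- panel$catalog
  catalog <- validate_item_catalog(catalog)
  missing_items <- setdiff(colnames(panel$wave1), catalog$item_id)
  if (length(missing_items))
    stop("item(s) missing from catalog: ",
         paste(missing_items, collapse = ", "))

  scales <- unique(catalog$scale)
  score_wave <- function(m, wave) {
    out <- lapply(scales, function(sc) {
      items <- catalog$item_id[catalog$scale == sc]
      offs <- catalog$score_offset[catalog$scale == sc]
      scored <- sweep(m[, items, drop = FALSE], 2, offs, "+")
      n_obs <- rowSums(!is.na(scored))
      valid <- n_obs >= min_prop * length(items)
      total <- rowSums(scored, na.rm = TRUE) * length(items) / n_obs
      total[n_obs == 0] <- NA_real_
      total <- round(total, 2)
      total[!valid] <- NA_real_
      data.frame(subject_id = panel$subject_ids, scale = sc, wave = wave,
                 total = total, valid = valid, row.names = NULL,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  rbind(score_wave(panel$wave1, 1L), score_wave(panel$wave2, 2L))
}

#' Paired t-test with Cohen's d
#'
#' `t = mean(diff) / (sd(diff) / sqrt(n))` on the pairwise-valid pairs,
#' `df = n - 1`, two-sided p from the t distribution, and the paired-design
#' effect size `d = mean(diff) / sd(diff)`, which satisfies
#' `d = t / sqrt(n)` identically.
#'
#' @param scores_w1,scores_w2 numeric vectors of totals, aligned by subject
#'   (`NA` allowed; incomplete pairs are dropped).
#' @return A list of class `paired_test`: `t`, `df`, `p`, `d`, `n_pairs`.
#' @export
paired_t <- function(scores_w1, scores_w2) {
  stopifnot(length(scores_w1) == length(scores_w2))
  ok <- !is.na(scores_w1) & !is.na(scores_w2)
  d <- scores_w2[ok] - scores_w1[ok]
  n <- length(d)
  if (n < 2) stop("need at least 2 valid pairs")
  s <- sd(d)
  if (s == 0) {
    if (all(d == 0))  # identical waves: degenerate but well-defined
      return(structure(list(t = 0, df = n - 1L, p = 1, d = 0, n_pairs = n),
                       class = "paired_test"))
    stop("zero variance of paired differences")
  }
  t <- mean(d) / (s / sqrt(n))
  structure(list(t = t, df = n - 1L, p = 2 * pt(-abs(t), df = n - 1),
                 d = mean(d) / s, n_pairs = n),
            class = "paired_test")
}

#' Cohen's d from a paired t statistic
#'
#' For the paired design, `d = t / sqrt(n_pairs)`.
#'
#' @param t paired t statistic.
#' @param n_pairs number of pairs (>= 2).
#' @return Cohen's d (unrounded).
#' @export
cohens_d_from_t <- function(t, n_pairs) {
  if (n_pairs < 2) stop("n_pairs must be at least 2")
  t / sqrt(n_pairs)
}

#' Count subjects exceeding a scale's clinical cutoff
#'
#' Counts valid totals strictly above the scale's lower cutoff bound (the
#' "4/5" convention: a cutoff recorded as 4 counts totals of 5 and above).
#'
#' @param scores output of [score_scales()].
#' @param scale scale label.
#' @param wave wave (1 or 2).
#' @param catalog catalog carrying the cutoffs.
#' @return Integer count.
#' @export
cutoff_counts <- function(scores, scale, wave, catalog) {
  catalog <- validate_item_catalog(catalog)
  cut <- unique(catalog$cutoff[catalog$scale == scale])
  cut <- cut[!is.na(cut)]
  if (length(cut) != 1) stop("no clinical cutoff defined for scale ", scale)
  tot <- scores$total[scores$scale == scale & scores$wave == wave]
  sum(tot > cut, na.rm = TRUE)
}

#' Descriptive summary of a paired panel
#'
#' The descriptive layer of the pipeline: per-scale per-wave means and
#' standard deviations of the valid totals, paired t-tests with Cohen's d on
#' the wave change, and clinical-cutoff counts where a cutoff is defined.
#'
#' @param panel a `paired_panel`.
#' @param catalog optional catalog override.
#' @return A list of class `panel_description` with elements `summary`
#'   (scale, wave, n_valid, mean, sd), `tests` (scale, t, df, p, d,
#'   n_pairs), and `cutoffs` (scale, wave, n_above).
#' @export
describe_panel <- function(panel, catalog = NULL) {
  if (is.null(catalog)) catalog <- panel$catalog
  scores <- score_scales(panel, catalog)
  scales <- unique(catalog$scale)

  summ <- do.call(rbind, lapply(scales, function(sc) {
    do.call(rbind, lapply(1:2, function(w) {
      tot <- scores$total[scores$scale == sc & scores$wave == w]
      data.frame(scale = sc, wave = w, n_valid = sum(!is.na(tot)),
                 mean = mean(tot, na.rm = TRUE), sd = sd(tot, na.rm = TRUE))
    }))
  }))

  tests <- do.call(rbind, lapply(scales, function(sc) {
    s1 <- scores$total[scores$scale == sc & scores$wave == 1]
    s2 <- scores$total[scores$scale == sc & scores$wave == 2]
    tt <- paired_t(s1, s2)
    data.frame(scale = sc, t = tt$t, df = tt$df, p = tt$p, d = tt$d,
               n_pairs = tt$n_pairs)
  }))

  with_cut <- scales[vapply(scales, function(sc)
    any(!is.na(catalog$cutoff[catalog$scale == sc])), logical(1))]
  cutoffs <- if (length(with_cut)) {
    do.call(rbind, lapply(with_cut, function(sc) {
      do.call(rbind, lapply(1:2, function(w) {
        data.frame(scale = sc, wave = w,
                   n_above = cutoff_counts(scores, sc, w, catalog))
      }))
    }))
  } else {
    data.frame(scale = character(), wave = integer(), n_above = integer())
  }

  structure(list(summary = summ, tests = tests, cutoffs = cutoffs,
                 scores = scores),
            class = "panel_description")
}

#' @export
print.panel_description <- function(x, ...) {
  cat("scale totals by wave:\n")
  print(x$summary, digits = 3, row.names = FALSE)
  cat("\npaired t-tests (wave 2 - wave 1):\n")
  print(x$tests, digits = 3, row.names = FALSE)
  if (nrow(x$cutoffs)) {
    cat("\nsubjects above clinical cutoff:\n")
    print(x$cutoffs, row.names = FALSE)
  }
  invisible(x)
}
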