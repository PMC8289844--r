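#' Configuration for a full pipeline run
#'
#' @param panel a `paired_panel` (or `NULL` to simulate one from
#'   `sim_config`).
#' @param sim_config a [simulation_config()] used when no panel is given.
#' @param out_dir output directory for all artifacts.
#' @param gamma,n_lambda,lambda_min_ratio estimation settings.
#' @param drop_levels,n_boot stability settings.
#' @param n_permutations,alpha,holm comparison settings; `n_permutations =
#'   0` skips the comparison stage.
#' @param seed seed for every stochastic stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(panel = NULL, sim_config = NULL, out_dir = ".",
                       gamma = 0.5, n_lambda = 100, lambda_min_ratio = 0.01,
                       drop_levels = seq(0.05, 0.75, length.out = 10),
                       n_boot = 1000, n_permutations = 5000, alpha = 0.05,
                       holm = FALSE, seed = 1L) {
  stopifnot(gamma >= 0, n_lambda >= 1,
            lambda_min_ratio > 0, lambda_min_ratio <= 1,
            n_boot >= length(drop_levels), n_permutations >= 0,
            alpha > 0, alpha < 1)
  if (is.null(panel) && is.null(sim_config))
    sim_config <- simulation_config(seed = seed)
  structure(list(panel = panel, sim_config = sim_config, out_dir = out_dir,
                 gamma = gamma, n_lambda = n_lambda,
                 lambda_min_ratio = lambda_min_ratio,
                 drop_levels = drop_levels, n_boot = n_boot,
                 n_permutations = n_permutations, alpha = alpha,
                 holm = holm, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full two-wave network pipeline
#'
#' Executes, in order: descriptives (scale totals, paired t-tests, cutoff
#' counts), per-wave network estimation, centrality and block summaries,
#' case-dropping edge stability per wave with CS coefficients, and the
#' paired permutation comparison. All artifacts are written under
#' `config$out_dir` along with a machine-readable run manifest (settings,
#' seed, package version, stage timings, warnings). Identical configuration
#' and seed reproduce identical artifact payloads (timings aside).
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  manifest <- list(
    package_version = as.character(utils::packageVersion("longnet")),
    seed = config$seed,
    settings = config[c("gamma", "n_lambda", "lambda_min_ratio",
                        "drop_levels", "n_boot", "n_permutations",
                        "alpha", "holm")],
    stages = list(), warnings = character()
  )
  warn <- function(w) {
    manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)),
      warning = warn)
    manifest$stages[[name]] <<- list(elapsed_s = proc.time()[["elapsed"]] - t0)
    res
  }

  panel <- config$panel
  truth <- NULL
  if (is.null(panel)) {
    truth <- timed("simulate_truth", build_true_network(config$sim_config))
    panel <- timed("simulate_panel", simulate_panel(truth, config$sim_config))
    write_ground_truth(truth, out("ground_truth.json"))
    write_panel(panel, out("panel.csv"))
  }
  catalog <- panel$catalog
  communities <- stats::setNames(catalog$community, catalog$item_id)
  scales <- stats::setNames(catalog$scale, catalog$item_id)

  desc <- timed("descriptives", describe_panel(panel))
  write.csv(desc$summary, out("scale_summary.csv"), row.names = FALSE)
  write.csv(desc$tests, out("paired_tests.csv"), row.names = FALSE)
  write.csv(desc$cutoffs, out("cutoff_counts.csv"), row.names = FALSE)

  nets <- list()
  for (w in 1:2) {
    nets[[w]] <- timed(paste0("estimate_wave", w),
                       estimate_network(panel, wave = w,
                                        gamma = config$gamma,
                                        n_lambda = config$n_lambda,
                                        lambda_min_ratio =
                                          config$lambda_min_ratio,
                                        communities = communities))
    write_network(nets[[w]], out(sprintf("network_w%d.json", w)))
    write_edge_list(nets[[w]], out(sprintf("edges_w%d.csv", w)))
    cent <- centrality_table(nets[[w]])
    write.csv(cent, out(sprintf("centrality_w%d.csv", w)),
              row.names = FALSE)
    bs <- block_summary(nets[[w]], scales)
    write.csv(as.data.frame(unclass(bs)),
              out(sprintf("block_summary_w%d.csv", w)))
    write.csv(top_edges(nets[[w]], 10),
              out(sprintf("top_edges_w%d.csv", w)), row.names = FALSE)
  }

  stab <- list()
  for (w in 1:2) {
    stab[[w]] <- timed(paste0("stability_wave", w),
                       case_drop_bootstrap(panel, metric = "edges",
                                           drop_levels = config$drop_levels,
                                           n_boot = config$n_boot,
                                           seed = config$seed, wave = w,
                                           gamma = config$gamma,
                                           n_lambda = config$n_lambda,
                                           lambda_min_ratio =
                                             config$lambda_min_ratio))
    cs <- cs_coefficient(stab[[w]])
    jsonlite::write_json(
      list(metric = stab[[w]]$metric_kind, seed = stab[[w]]$seed,
           drop_levels = stab[[w]]$drop_levels,
           correlations = stab[[w]]$correlations,
           failures = stab[[w]]$failures,
           cs = cs$value, cs_table = cs$table),
      out(sprintf("stability_w%d.json", w)),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  comparison <- NULL
  if (config$n_permutations > 0) {
    comparison <- timed("comparison",
                        nct_paired(panel,
                                   n_permutations = config$n_permutations,
                                   gamma = config$gamma,
                                   n_lambda = config$n_lambda,
                                   lambda_min_ratio =
                                     config$lambda_min_ratio,
                                   holm = config$holm, seed = config$seed))
    jsonlite::write_json(
      list(observed = comparison$observed, p_values = comparison$p_values,
           tested_edge_set = comparison$tested_edge_set,
           n_permutations = comparison$n_permutations,
           n_completed = comparison$n_completed,
           n_failed = comparison$n_failed, seed = comparison$seed),
      out("comparison.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.csv(significant_edges(comparison, config$alpha),
              out("significant_edges.csv"), row.names = FALSE)
  } else {
    manifest$stages[["comparison"]] <- list(skipped = TRUE,
                                            reason = "n_permutations = 0")
  }

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(panel = panel, truth = truth, descriptives = desc,
                 networks = nets, stability = stab,
                 comparison = comparison, manifest = manifest))
}
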