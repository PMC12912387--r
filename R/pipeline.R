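## End-to-end orchestration with a single config, a fixed seed and a
## machine-readable manifest.

#' Run the full saliva circadian pipeline
#'
#' Executes the enabled stages in order — simulate (or load input files),
#' quantify (delta-delta-CT), fit (harmonic regressions + summaries),
#' repro (day-pairing, error metrics, paired Wilcoxon), associate
#' (feature table + Spearman matrix), design (sampling-design screen) —
#' and writes one TSV per result table plus a JSON manifest via
#' [writeResults()]. Identical config and seed give byte-identical
#' outputs.
#'
#' @param config either a YAML file path or a list with elements:
#'   `simulate` (a [cohortConfig()] list, or arguments for it) *or*
#'   `inputs` (list with `ct_table` and optional `hormone_table` file
#'   paths); `stages` (character subset of
#'   `c("quantify","fit","repro","associate","design")`, default all);
#'   `seed` (mandatory when simulating); `out_dir`; and optional stage
#'   parameter lists `fit` (`lrt_method`), `design` (`points_per_day`,
#'   `n_days`, `noise_sd`, `n_replicates`, thresholds).
#' @return invisibly, a list of all result tables (also written to
#'   `out_dir` when given).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- config$stages %||% c("quantify", "fit", "repro", "associate", "design")
  results <- list()

  if (!is.null(config$simulate) && !is.null(config$inputs))
    stop("config must set exactly one of 'simulate' and 'inputs'")
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    if (is.null(sim_args$seed)) stop("a seed is mandatory when simulating")
    cc <- do.call(cohortConfig, sim_args)
    cohort <- generateCohort(cc)
    results$truth <- cohort$truth
    results$participants <- cohort$participants
    message(sprintf("simulate: %d participants, %d CT records",
                    cc$n_participants, nrow(ctData(cohort$ct))))
  } else if (!is.null(config$inputs)) {
    cohort <- list(ct = readCtTable(config$inputs$ct_table),
                   hormones = if (!is.null(config$inputs$hormone_table))
                     readHormoneTable(config$inputs$hormone_table),
                   cells = NULL, participants = NULL)
    message(sprintf("load: %d CT records", nrow(ctData(cohort$ct))))
  } else stop("config must set one of 'simulate' and 'inputs'")

  series <- NULL
  if ("quantify" %in% stages) {
    series <- deltaDeltaCt(cohort$ct,
                           reference_gene = config$reference_gene %||% "GAPDH")
    results$expression <- seriesPoints(series)
    message(sprintf("quantify: %d expression points, %d exclusions",
                    nrow(results$expression), nrow(exclusionLog(series))))
  }
  if ("fit" %in% stages && !is.null(series)) {
    results$fits <- fitCohortRhythms(series,
                                     lrt_method = config$fit$lrt_method %||% "ftest")
    message(sprintf("fit: %d series fitted", nrow(results$fits)))
  }
  if ("repro" %in% stages && !is.null(series)) {
    pairs <- pairDays(series)
    results$paired_days <- pairs
    if (nrow(pairs)) {
      em <- errorMetrics(pairs)
      results$error_metrics <- data.frame(metric = c("mae", "mse", "rmse", "mbe"),
                                          value = c(em$mae, em$mse, em$rmse, em$mbe))
      results$wilcoxon <- wilcoxonBonferroni(pairs)
      message(sprintf("repro: %d pairs, MAE %.4g", em$n, em$mae))
    }
  }
  if ("associate" %in% stages && !is.null(series)) {
    feats <- cohortFeatures(series, hormones = cohort$hormones,
                            participants = cohort$participants,
                            cells = cohort$cells)
    results$features <- feats
    results$spearman <- spearmanMatrix(feats,
                                       circular = attr(feats, "circular_columns"),
                                       circular_cut = config$associate$circular_cut %||% 4)
    message(sprintf("associate: %d participants x %d features",
                    nrow(feats), ncol(feats) - 1L))
  }
  if ("design" %in% stages) {
    dp <- config$design %||% list()
    ks <- dp$points_per_day %||% 3:6
    gp <- geneParams(dp$gene %||% "ARNTL1", mesor = dp$mesor %||% 1,
                     rel_amplitude = dp$rel_amplitude %||% 0.4,
                     acrophase_h = dp$acrophase_h %||% 18)
    evals <- do.call(rbind, lapply(ks, function(k)
      evaluateDesign(gp, spanDesign(k, n_days = dp$n_days %||% 1L),
                     noise_sd = dp$noise_sd %||% 0.1,
                     n_replicates = dp$n_replicates %||% 200L,
                     seed = (config$seed %||% 1L) + k)))
    results$design_evaluations <- evals
    results$minimal_design <- minimalSufficientDesign(evals)
    message(sprintf("design: minimal sufficient points/day = %s",
                    paste(results$minimal_design$min_points_per_day, collapse = ",")))
  }
  if (!is.null(config$out_dir))
    writeResults(results, config$out_dir, config = config, seed = config$seed)
  invisible(results)
}
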