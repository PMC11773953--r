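#' Run the full prediction pipeline on simulated data
#'
#' Executes the stages in study order: simulate multi-cohort panels with
#' planted effects, build the per-cohort correlation feature table, label
#' pairs from the planted training tier, train the downsampling consensus
#' ensemble, and validate the significant calls against the planted
#' held-out tier. When `config$out_dir` is set, every intermediate
#' artifact is written as TSV together with a seed/parameter manifest and
#' a human-readable summary.
#'
#' @param config A `pipeline_config` (see [pipeline_config()] /
#'   [read_pipeline_config()]).
#' @return A `pipeline_result`: the simulated `truth`, `features`,
#'   `labels`, `consensus`, `metric_summary`, the per rate x threshold
#'   `significant_grid` (count and held-out validation percentage), and
#'   `validation` for the reporting rate/threshold (validation rate plus
#'   the background prevalence of held-out pairs among all negatives and
#'   the resulting enrichment).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))

  sim <- simulate_panels(config$simulation)
  features <- build_feature_table(sim$panels)
  train_db <- truth_tier_db(sim$truth, "training", role = "training")
  heldout_db <- truth_tier_db(sim$truth, "heldout", role = "validation")
  labels <- assign_labels(features, list(train_db))
  consensus <- run_suite(features, labels, config$ensemble)

  rate <- config$validation$rate %||% max(consensus$rates)
  freq_threshold <- config$validation$freq_threshold %||% max(consensus$freq_thresholds)

  heldout_only <- setdiff(heldout_db$keys, train_db$keys)
  background <- 100 * mean(consensus$keys %in% heldout_only)

  grid <- expand.grid(rate = consensus$rates,
                      freq_threshold = consensus$freq_thresholds)
  grid$n_significant <- NA_integer_
  grid$validation_pct <- NA_real_
  for (i in seq_len(nrow(grid))) {
    sig <- call_significant(consensus, grid$rate[i], grid$freq_threshold[i])
    grid$n_significant[i] <- length(sig)
    if (length(sig) > 0L)
      grid$validation_pct[i] <-
        validation_rate(sig, list(heldout_db), list(train_db))$percentage
  }

  sig <- call_significant(consensus, rate, freq_threshold)
  val <- if (length(sig) > 0L)
    validation_rate(sig, list(heldout_db), list(train_db))
  else list(n_significant = 0L, n_validated = 0L, percentage = NA_real_)

  result <- structure(list(
    truth = sim$truth,
    features = features,
    labels = labels,
    consensus = consensus,
    metric_summary = suite_metric_summary(consensus),
    significant_grid = grid,
    validation = c(val, list(
      rate = rate, freq_threshold = freq_threshold,
      background_pct = round(background, 2),
      enrichment = if (is.na(val$percentage) || background == 0) NA_real_
                   else val$percentage / background))),
    class = "pipeline_result")

  if (!is.null(config$out_dir))
    write_pipeline_artifacts(result, sim$panels, config)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  print(x$labels)
  cat(sprintf("  reporting rate %s, frequency threshold %d: %d significant pairs\n",
              x$validation$rate, x$validation$freq_threshold, x$validation$n_significant))
  cat(sprintf("  held-out validation rate %.2f%% (background %.2f%%, enrichment %.1fx)\n",
              x$validation$percentage, x$validation$background_pct,
              x$validation$enrichment))
  invisible(x)
}

write_pipeline_artifacts <- function(result, panels, config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_fixtures(panels, result$truth, out_dir = file.path(out, "panels"))
  write_feature_tsv(result$features, file.path(out, "features.tsv"))
  write_labels_tsv(result$labels, file.path(out, "labels.tsv"))
  data.table::fwrite(
    cbind(data.table::data.table(pair = result$consensus$keys),
          data.table::as.data.table(result$consensus$counts)),
    file.path(out, "consensus_counts.tsv"), sep = "\t")
  data.table::fwrite(result$consensus$metrics,
                     file.path(out, "model_metrics.tsv"), sep = "\t")
  data.table::fwrite(result$significant_grid,
                     file.path(out, "significant_grid.tsv"), sep = "\t", na = "NA")

  manifest <- list(
    global_seed = config$seed,
    simulation_seed = config$simulation$seed,
    ensemble_base_seed = config$ensemble$base_seed,
    n_cohorts = config$simulation$n_cohorts,
    n_mirnas = config$simulation$n_mirnas,
    n_genes = config$simulation$n_genes,
    downsample_rates = config$ensemble$downsample_rates,
    n_models = config$ensemble$n_models,
    freq_thresholds = config$ensemble$freq_thresholds,
    positive_threshold = config$ensemble$positive_threshold,
    reporting_rate = result$validation$rate,
    reporting_freq_threshold = result$validation$freq_threshold)
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))

  summary_lines <- c(
    "Pan-cancer correlation consensus pipeline summary",
    sprintf("pairs retained: %d of %d", result$features$n_retained,
            result$features$n_total_pairs),
    sprintf("labels: %d positive / %d negative (%.2f%%)",
            result$labels$n_positive, result$labels$n_negative,
            result$labels$positive_pct),
    sprintf("significant at rate %s, threshold %d: %d pairs",
            result$validation$rate, result$validation$freq_threshold,
            result$validation$n_significant),
    sprintf("held-out validation rate: %.2f%% (background %.2f%%)",
            result$validation$percentage, result$validation$background_pct))
  writeLines(summary_lines, file.path(out, "summary.txt"))
  invisible(out)
}

#' @importFrom stats setNames
#' @importFrom utils write.table
NULL
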