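#' Configuration for the downsampling consensus ensemble
#'
#' At each negative-class downsampling rate, `n_models` gradient-boosted
#' classifiers are trained on independent downsamples of the negatives
#' combined with all positives; every model then scores every
#' negative-labeled pair, and pairs called positive by at least a frequency
#' threshold of models are "significant".
#'
#' @param downsample_rates Fractions of the negative class to sample
#'   (without replacement) for each training set.
#' @param n_models Models per rate.
#' @param train_fraction Fraction of each training set used for fitting
#'   (the rest is the test split; stratified by class).
#' @param positive_threshold Classifier score at or above which a pair is
#'   called positive.
#' @param freq_thresholds Consensus counts at which significant sets are
#'   reported; each must be `<= n_models`.
#' @param base_seed Seed from which every per-model seed is derived.
#' @param learner_params Named list of xgboost parameters overriding the
#'   defaults (`max_depth = 4`, `eta = 0.3`, `nrounds = 30`,
#'   single-threaded).
#' @return An `ensemble_config`.
#' @export
ensemble_config <- function(downsample_rates = c(0.01, 0.05, 0.1, 0.5, 1.0),
                            n_models = 50,
                            train_fraction = 0.8,
                            positive_threshold = 0.5,
                            freq_thresholds = NULL,
                            base_seed = 1L,
                            learner_params = list()) {
  if (any(downsample_rates <= 0) || any(downsample_rates > 1))
    stop("downsample rates must lie in (0, 1]", call. = FALSE)
  n_models <- check_count(n_models, "n_models")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  if (is.null(freq_thresholds))
    freq_thresholds <- unique(pmax(1L, round(n_models * c(0.7, 0.8, 0.9, 0.95))))
  if (any(freq_thresholds > n_models) || any(freq_thresholds < 0))
    stop("freq_thresholds must lie in [0, n_models]", call. = FALSE)
  structure(list(downsample_rates = downsample_rates,
                 n_models = n_models,
                 train_fraction = train_fraction,
                 positive_threshold = check_prob(positive_threshold, "positive_threshold"),
                 freq_thresholds = sort(freq_thresholds),
                 base_seed = check_count(base_seed, "base_seed", min = 0),
                 learner_params = learner_params),
            class = "ensemble_config")
}

#' Downsample the negative class
#'
#' @param labels A `label_set`.
#' @param rate Fraction of negatives to keep, in (0, 1].
#' @param seed Integer seed.
#' @return Integer indices (into the label set / feature table rows) of a
#'   uniform without-replacement sample of `round(rate * n_negative)`
#'   negatives.
#' @export
downsample_negatives <- function(labels, rate, seed) {
  stopifnot(inherits(labels, "label_set"))
  if (rate <= 0 || rate > 1) stop("rate must lie in (0, 1]", call. = FALSE)
  neg <- which(!labels$positive)
  k <- round(rate * length(neg))
  if (k < 1L)
    stop(sprintf("rate %g yields zero negatives out of %d", rate, length(neg)),
         call. = FALSE)
  set.seed(seed)
  sort(sample(neg, k))
}

fit_xgb <- function(x, y, learner_params = list(), seed = 1L) {
  nrounds <- learner_params$nrounds %||% 30
  learner_params$nrounds <- NULL
  params <- modifyList(
    list(objective = "binary:logistic", max_depth = 4, eta = 0.3,
         nthread = 1, seed = seed, eval_metric = "logloss"),
    learner_params)
  dtrain <- xgboost::xgb.DMatrix(x, label = y, missing = NA)
  xgboost::xgb.train(params = params, data = dtrain, nrounds = nrounds, verbose = 0)
}

score_xgb <- function(model, x) {
  as.numeric(predict(model, xgboost::xgb.DMatrix(x, missing = NA)))
}

#' Train one classifier on a labeled subset
#'
#' Splits the subset `train_fraction`/rest stratified by class, fits an
#' xgboost binary scorer on the training part (missing correlation values
#' are handled natively by the trees), and evaluates the held-out part:
#' recall on positives, specificity on negatives (at
#' `positive_threshold`) and AUC.
#'
#' @param table A `feature_table` (the correlation features).
#' @param labels A `label_set` aligned to `table`.
#' @param subset Integer row indices to train/test on; must contain both
#'   classes.
#' @param split_seed Seed for the stratified split (also seeds the
#'   learner).
#' @param train_fraction Training share of the subset (default 0.8).
#' @param positive_threshold Score cutoff for a positive call (default
#'   0.5).
#' @param learner_params Passed to the learner as in [ensemble_config()].
#' @return List with `model` (scorer usable via `predict_pairs()`) and
#'   `metrics` (`recall_positive`, `specificity_negative`, `auc`).
#' @export
train_one <- function(table, labels, subset, split_seed,
                      train_fraction = 0.8, positive_threshold = 0.5,
                      learner_params = list()) {
  stopifnot(inherits(table, "feature_table"), inherits(labels, "label_set"))
  y <- as.integer(labels$positive[subset])
  if (length(unique(y)) < 2L)
    stop("training subset must contain both classes", call. = FALSE)
  set.seed(split_seed)
  in_train <- logical(length(subset))
  for (cls in c(0L, 1L)) {
    idx <- which(y == cls)
    n_tr <- max(1L, round(train_fraction * length(idx)))
    in_train[sample(idx, n_tr)] <- TRUE
  }
  if (all(in_train)) in_train[sample(length(subset), 1L)] <- FALSE
  x <- table$values[subset, , drop = FALSE]
  model <- fit_xgb(x[in_train, , drop = FALSE], y[in_train],
                   learner_params, seed = split_seed)
  test_scores <- score_xgb(model, x[!in_train, , drop = FALSE])
  y_test <- y[!in_train]
  metrics <- c(
    recall_positive = if (any(y_test == 1)) mean(test_scores[y_test == 1] >= positive_threshold) else NA_real_,
    specificity_negative = if (any(y_test == 0)) mean(test_scores[y_test == 0] < positive_threshold) else NA_real_,
    auc = auc_score(test_scores, y_test))
  list(model = model, metrics = metrics)
}

#' Score feature-table rows with a fitted model
#' @param model A fitted scorer from [train_one()].
#' @param table A `feature_table`.
#' @param rows Optional integer row subset (default: all rows).
#' @return Numeric scores in `[0, 1]`.
#' @export
predict_pairs <- function(model, table, rows = NULL) {
  x <- table$values
  if (!is.null(rows)) x <- x[rows, , drop = FALSE]
  score_xgb(model, x)
}

#' Run the full downsampling consensus suite
#'
#' For every downsampling rate, trains `n_models` models on independent
#' negative downsamples (each combined with all positives), records each
#' model's test metrics, scores every negative-labeled pair with every
#' model, and counts per pair how many models call it positive.
#'
#' @param table A `feature_table`.
#' @param labels A `label_set` aligned to `table`.
#' @param config An [ensemble_config()].
#' @param exclude_train If `TRUE`, a model does not vote on negatives that
#'   were part of its own training downsample (its count denominator still
#'   is `n_models`); default `FALSE`: models vote on all negatives.
#' @return A `consensus_result`: `pairs`/`keys` of the negative-labeled
#'   pairs, `counts` (negatives x rates matrix of positive-call counts),
#'   `metrics` (one row per rate x model), `rates`, `n_models`,
#'   `freq_thresholds`.
#' @export
run_suite <- function(table, labels, config, exclude_train = FALSE) {
  stopifnot(inherits(table, "feature_table"), inherits(labels, "label_set"),
            inherits(config, "ensemble_config"))
  pos <- which(labels$positive)
  neg <- which(!labels$positive)
  if (length(pos) == 0L || length(neg) == 0L)
    stop("labels must contain both classes", call. = FALSE)

  counts <- matrix(0L, nrow = length(neg), ncol = length(config$downsample_rates),
                   dimnames = list(NULL, as.character(config$downsample_rates)))
  metrics <- vector("list", length(config$downsample_rates) * config$n_models)
  mi <- 0L
  for (ri in seq_along(config$downsample_rates)) {
    rate <- config$downsample_rates[ri]
    for (m in seq_len(config$n_models)) {
      seed_m <- config$base_seed + 10000L * ri + m
      ds <- downsample_negatives(labels, rate, seed = seed_m)
      fit <- train_one(table, labels, subset = c(pos, ds),
                       split_seed = seed_m + 5000L,
                       train_fraction = config$train_fraction,
                       positive_threshold = config$positive_threshold,
                       learner_params = config$learner_params)
      scores <- predict_pairs(fit$model, table, rows = neg)
      call_pos <- scores >= config$positive_threshold
      if (exclude_train) call_pos[neg %in% ds] <- FALSE
      counts[, ri] <- counts[, ri] + call_pos
      mi <- mi + 1L
      metrics[[mi]] <- data.frame(rate = rate, model = m,
                                  recall_positive = fit$metrics[["recall_positive"]],
                                  specificity_negative = fit$metrics[["specificity_negative"]],
                                  auc = fit$metrics[["auc"]])
    }
  }
  structure(list(pairs = table$pairs[neg, , drop = FALSE],
                 keys = labels$keys[neg],
                 counts = counts,
                 metrics = do.call(rbind, metrics),
                 rates = config$downsample_rates,
                 n_models = config$n_models,
                 freq_thresholds = config$freq_thresholds,
                 positive_threshold = config$positive_threshold),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: %d negative pairs x %d rates, %d models/rate\n",
              nrow(x$counts), length(x$rates), x$n_models))
  for (r in as.character(x$rates))
    cat(sprintf("  rate %s: %s significant at thresholds {%s}\n", r,
                paste(vapply(x$freq_thresholds,
                             function(t) sum(x$counts[, r] >= t), integer(1)),
                      collapse = "/"),
                paste(x$freq_thresholds, collapse = ", ")))
  invisible(x)
}

#' Mean test metrics per downsampling rate
#' @param result A `consensus_result`.
#' @return Data frame with one row per rate: mean recall, specificity, AUC.
#' @export
suite_metric_summary <- function(result) {
  stopifnot(inherits(result, "consensus_result"))
  agg <- aggregate(result$metrics[c("recall_positive", "specificity_negative", "auc")],
                   by = list(rate = result$metrics$rate), FUN = mean, na.rm = TRUE)
  agg[order(agg$rate), , drop = FALSE]
}

#' Call significant pairs at a rate and frequency threshold
#'
#' @param result A `consensus_result`.
#' @param rate One of the rates the suite was run at.
#' @param freq_threshold Minimum number of positive calls; must be
#'   `<= n_models`.
#' @return Character vector of significant [pair_key()]s (pairs called
#'   positive by at least `freq_threshold` models).
#' @export
call_significant <- function(result, rate, freq_threshold) {
  stopifnot(inherits(result, "consensus_result"))
  ri <- match(as.character(rate), colnames(result$counts))
  if (is.na(ri)) stop(sprintf("unknown downsampling rate %s", rate), call. = FALSE)
  if (freq_threshold > result$n_models || freq_threshold < 0)
    stop("freq_threshold must lie in [0, n_models]", call. = FALSE)
  result$keys[result$counts[, ri] >= freq_threshold]
}

#' @importFrom stats aggregate predict
NULL
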