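#' Held-out database validation rate of significant pairs
#'
#' The fraction of significant pairs found in the held-out (validation)
#' databases after removing anything also present in a training database,
#' so that the rate measures rediscovery of knowledge the models never saw.
#'
#' @param significant Character vector of significant [pair_key()]s (or a
#'   data frame with mirna/gene columns).
#' @param heldout_dbs List of [interaction_db()] with validation role.
#' @param training_dbs List of [interaction_db()] used for labeling.
#' @return List with `n_significant`, `n_validated`, and `percentage`
#'   (`100 * validated / significant`, rounded to 2 decimals).
#' @examples
#' # 28 of 871 significant pairs found only in held-out databases -> 3.21%
#' @export
validation_rate <- function(significant, heldout_dbs, training_dbs = list()) {
  if (is.data.frame(significant))
    significant <- pair_key(significant$mirna, significant$gene)
  significant <- unique(significant)
  if (length(significant) == 0L)
    stop("the significant set is empty", call. = FALSE)
  if (inherits(heldout_dbs, "interaction_db")) heldout_dbs <- list(heldout_dbs)
  if (inherits(training_dbs, "interaction_db")) training_dbs <- list(training_dbs)
  heldout <- unique(unlist(lapply(heldout_dbs, `[[`, "keys")))
  training <- unique(unlist(lapply(training_dbs, `[[`, "keys")))
  eligible <- setdiff(heldout, training)
  n_val <- sum(significant %in% eligible)
  list(n_significant = length(significant),
       n_validated = n_val,
       percentage = round(100 * n_val / length(significant), 2))
}

#' Per-gene differential expression t-tests for a perturbation dataset
#'
#' Two-sample t-test (Welch by default) of treated vs control for every
#' gene; direction is the sign of the treated-minus-control mean
#' difference. Genes constant in both groups have no defined test and are
#' excluded with a message.
#'
#' @param data A `perturbation_dataset`.
#' @param alpha Significance level for DEG calling (default 0.05; no
#'   multiplicity correction, by design).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return A `deg_result`: data frame `tests` (gene, t, p, direction),
#'   character `degs` (genes with `p < alpha`), `alpha`, and
#'   `n_excluded` constant genes.
#' @export
deg_ttest <- function(data, alpha = 0.05, var_equal = FALSE) {
  stopifnot(inherits(data, "perturbation_dataset"))
  ctrl <- data$control_matrix
  trt <- data$treated_matrix
  if (!identical(colnames(ctrl), colnames(trt)))
    stop("control and treated matrices must share the gene axis", call. = FALSE)
  if (nrow(ctrl) < 2L || nrow(trt) < 2L)
    stop("at least 2 samples per group are required", call. = FALSE)
  genes <- colnames(ctrl)
  const <- apply(ctrl, 2, sd) == 0 & apply(trt, 2, sd) == 0
  if (any(const))
    message(sprintf("%d constant gene(s) excluded from DEG testing", sum(const)))
  usable <- genes[!const]
  res <- vapply(usable, function(g) {
    tt <- t.test(trt[, g], ctrl[, g], var.equal = var_equal)
    c(tt$statistic, tt$p.value, mean(trt[, g]) - mean(ctrl[, g]))
  }, numeric(3))
  tests <- data.frame(gene = usable,
                      t = res[1, ], p = res[2, ],
                      direction = ifelse(res[3, ] > 0, "up", "down"),
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(tests = tests,
                 degs = tests$gene[tests$p < alpha],
                 alpha = alpha,
                 n_excluded = sum(const)),
            class = "deg_result")
}

#' @export
print.deg_result <- function(x, ...) {
  cat(sprintf("deg_result: %d of %d tested genes are DEGs at p < %g\n",
              length(x$degs), nrow(x$tests), x$alpha))
  invisible(x)
}

#' Overlap of a prediction source with DEGs
#'
#' One row of the source-vs-DEG comparison table: how many of a source's
#' genes (predicted targets, or known targets) appear among the DEGs of a
#' perturbation dataset, with the percentage rounded to the nearest
#' integer (the precision such tables are printed at).
#'
#' @param predicted Character vector: the prediction source's gene set.
#' @param known Character vector: known-target gene set (second source).
#' @param degs Character vector of DEG gene ids.
#' @param dataset_id Optional dataset label.
#' @return List with the three set sizes, `overlap_predicted` /
#'   `overlap_known` counts, their integer percentages, and formatted
#'   `"count (pct%)"` strings.
#' @examples
#' # 31 of 569 predicted targets among the DEGs -> "31 (5%)"
#' @export
overlap_stats <- function(predicted, known, degs, dataset_id = NA_character_) {
  predicted <- unique(predicted); known <- unique(known); degs <- unique(degs)
  if (length(predicted) == 0L || length(known) == 0L)
    stop("source gene sets must be non-empty for percentage computation", call. = FALSE)
  ov_p <- sum(predicted %in% degs)
  ov_k <- sum(known %in% degs)
  pct_p <- round(100 * ov_p / length(predicted))
  pct_k <- round(100 * ov_k / length(known))
  list(dataset_id = dataset_id,
       n_degs = length(degs),
       n_predicted = length(predicted), n_known = length(known),
       overlap_predicted = ov_p, overlap_known = ov_k,
       pct_predicted = pct_p, pct_known = pct_k,
       label_predicted = sprintf("%d (%d%%)", ov_p, pct_p),
       label_known = sprintf("%d (%d%%)", ov_k, pct_k))
}

#' Concordance between regulation direction and correlation sign
#'
#' Under miRNA overexpression, a genuine target that goes up should
#' correlate positively with the miRNA in the matched cohort and one that
#' goes down should correlate negatively; under knockdown the expectation
#' is mirrored. Entries whose correlation sign is missing (e.g. the matched
#' cohort's correlation was MISSING) are skipped with a message.
#'
#' @param entries Data frame with columns `direction` (`"up"`/`"down"`),
#'   `corr_sign` (`"positive"`/`"negative"`, may be `NA`), and optionally
#'   `perturbation` (`"overexpression"` default / `"knockdown"`).
#' @return List with `n_concordant`, `n_total` (non-skipped entries),
#'   `n_skipped`, and `percentage` rounded to the nearest integer.
#' @export
direction_concordance <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (nrow(entries) == 0L) stop("no concordance entries provided", call. = FALSE)
  stopifnot(all(c("direction", "corr_sign") %in% names(entries)))
  if (is.null(entries$perturbation)) entries$perturbation <- "overexpression"
  stopifnot(all(entries$direction %in% c("up", "down")),
            all(entries$perturbation %in% c("overexpression", "knockdown")))
  skip <- is.na(entries$corr_sign)
  if (any(skip))
    message(sprintf("%d entr%s without a correlation sign skipped",
                    sum(skip), if (sum(skip) == 1L) "y" else "ies"))
  e <- entries[!skip, , drop = FALSE]
  stopifnot(all(e$corr_sign %in% c("positive", "negative")))
  expected_up <- ifelse(e$perturbation == "overexpression", "positive", "negative")
  concord <- ifelse(e$direction == "up",
                    e$corr_sign == expected_up,
                    e$corr_sign != expected_up)
  list(n_concordant = sum(concord),
       n_total = nrow(e),
       n_skipped = sum(skip),
       percentage = round(100 * sum(concord) / nrow(e)))
}

#' Paired t-test on two vectors of overlap percentages
#'
#' Compares two prediction methods' per-dataset DEG-overlap percentages
#' with a paired-sample t-test. Degenerate inputs follow the natural
#' limits: identical vectors give `t = 0, p = 1`; constant non-zero
#' differences give an infinite statistic with `p = 0`.
#'
#' @param percent_a,percent_b Equal-length numeric vectors (length >= 2).
#' @return List with `t` and two-sided `p`.
#' @export
paired_overlap_ttest <- function(percent_a, percent_b) {
  if (length(percent_a) != length(percent_b))
    stop("percentage vectors must have equal length", call. = FALSE)
  if (length(percent_a) < 2L)
    stop("at least two paired observations are required", call. = FALSE)
  d <- percent_a - percent_b
  if (sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, p = 1))
    return(list(t = sign(mean(d)) * Inf, p = 0))
  }
  tt <- t.test(percent_a, percent_b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Pairwise comparison matrix of method overlap percentages
#'
#' @param percent_table Numeric matrix or data frame, one column per
#'   method, one row per dataset.
#' @return List of symmetric matrices `t` and `p` with `NA` diagonals.
#' @export
overlap_comparison_matrix <- function(percent_table) {
  m <- as.matrix(percent_table)
  k <- ncol(m)
  P <- Tm <- matrix(NA_real_, k, k, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    r <- paired_overlap_ttest(m[, i], m[, j])
    Tm[i, j] <- r$t
    P[i, j] <- r$p
  }
  list(t = Tm, p = P)
}

#' Top-k predictions matched in size to another method
#'
#' Selects the `k` highest-scoring genes from an external tool's scored
#' prediction list so overlap comparisons use equally sized sets. Ties are
#' broken by gene-id lexicographic order.
#'
#' @param scores Data frame with columns `gene` and `score` (one row per
#'   gene).
#' @param k Number of genes to select; must not exceed the scored genes.
#' @return Character vector of `k` gene ids.
#' @export
select_matched_predictions <- function(scores, k) {
  scores <- as.data.frame(scores, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "score") %in% names(scores)))
  if (anyDuplicated(scores$gene))
    stop("scores must contain one row per gene", call. = FALSE)
  k <- check_count(k, "k", min = 0)
  if (k > nrow(scores))
    stop(sprintf("k = %d exceeds the %d scored genes", k, nrow(scores)), call. = FALSE)
  ord <- order(-scores$score, scores$gene)
  scores$gene[ord][seq_len(k)]
}
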