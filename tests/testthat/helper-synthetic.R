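# Shared builders for small in-code fixtures.

tiny_config <- function(...) {
  defaults <- list(n_cohorts = 3, n_mirnas = 8, n_genes = 20,
                   samples_per_cohort = 60, n_planted_training = 6,
                   n_planted_heldout = 3, n_planted_undiscovered = 3,
                   seed = 11L)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

# A panel built from explicit matrices (sample ids generated).
make_panel <- function(mirna_matrix, gene_matrix, cohort_id = "COHX") {
  rn <- sprintf("S%03d", seq_len(nrow(mirna_matrix)))
  rownames(mirna_matrix) <- rownames(gene_matrix) <- rn
  expression_panel(cohort_id, mirna_matrix, gene_matrix)
}

# A feature_table assembled directly from a values matrix (bypassing the
# correlation stage) for learner-focused tests.
make_feature_table <- function(values, mirnas = NULL, genes = NULL) {
  n <- nrow(values)
  if (is.null(mirnas)) mirnas <- sprintf("mir-%03d", seq_len(n))
  if (is.null(genes)) genes <- sprintf("G%04d", seq_len(n))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("COH%02d", seq_len(ncol(values)))
  structure(list(pairs = data.frame(mirna = mirnas, gene = genes,
                                    stringsAsFactors = FALSE),
                 cohorts = colnames(values),
                 values = values,
                 n_missing = rowSums(is.na(values)),
                 n_total_pairs = n, n_retained = n,
                 min_coexpressing = 10L, max_missing = 3L),
            class = "feature_table")
}

make_label_set <- function(table, positive) {
  structure(list(keys = feature_table_keys(table),
                 positive = positive,
                 n_positive = sum(positive), n_negative = sum(!positive),
                 positive_pct = positive_fraction_pct(sum(positive), length(positive)),
                 n_unmatched_db_pairs = 0L),
            class = "label_set")
}

# Separable toy problem: positives carry strong planted-style correlations,
# negatives hover near zero.
separable_problem <- function(n_pos = 60, n_neg = 300, n_cohorts = 6, seed = 5) {
  set.seed(seed)
  vals <- rbind(
    sweep(matrix(runif(n_pos * n_cohorts, 0.7, 0.95), nrow = n_pos),
          1, sample(c(-1, 1), n_pos, TRUE), `*`),
    matrix(rnorm(n_neg * n_cohorts, 0, 0.1), nrow = n_neg))
  ft <- make_feature_table(vals)
  list(table = ft,
       labels = make_label_set(ft, rep(c(TRUE, FALSE), c(n_pos, n_neg))))
}
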