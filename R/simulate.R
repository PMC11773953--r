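#' Configuration for the synthetic multi-cohort simulator
#'
#' Describes a synthetic pan-cancer study: several disease cohorts, each with
#' paired miRNA and gene expression matrices on a non-negative log scale
#' (zero means "not expressed"), plus a set of planted signed miRNA->gene
#' regulatory effects that are active in a subset of cohorts. Planted pairs
#' are split into three disjoint tiers that mirror how interaction knowledge
#' is used downstream: `training` (goes into the label databases),
#' `heldout` (reserved for validation databases) and `undiscovered`
#' (real effects absent from every database).
#'
#' @param n_cohorts Number of cohorts (cancer types).
#' @param n_mirnas,n_genes Feature universe sizes.
#' @param samples_per_cohort Samples per cohort; a single count or a
#'   length-2 range from which each cohort's size is drawn uniformly.
#' @param effect_size_range Length-2 positive range for the absolute slope
#'   `beta` of a planted effect on the log-expression scale.
#' @param noise_sd Standard deviation of the Gaussian residual added to every
#'   gene, in log-expression units.
#' @param dropout_prob Probability that any single matrix entry is zeroed
#'   (non-expression), applied independently after signal generation.
#' @param frac_active_cohorts Fraction of cohorts in which each planted pair
#'   is active (at least one).
#' @param n_planted_training,n_planted_heldout,n_planted_undiscovered Planted
#'   pair counts per tier; the three sets are mutually disjoint.
#' @param frac_positive_sign Probability that a planted effect is positive.
#' @param mirna_mean,mirna_sd Mean/sd of the truncated-Gaussian miRNA
#'   log-expression marginal.
#' @param gene_baseline_mean,gene_baseline_sd Mean/sd of per-gene baseline
#'   log expression.
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return A validated `simulation_config` object.
#' @examples
#' cfg <- simulation_config(n_cohorts = 2, n_mirnas = 5, n_genes = 10,
#'                          samples_per_cohort = 30, n_planted_training = 3,
#'                          n_planted_heldout = 2, n_planted_undiscovered = 2)
#' @export
simulation_config <- function(n_cohorts = 8,
                              n_mirnas = 60,
                              n_genes = 300,
                              samples_per_cohort = 120,
                              effect_size_range = c(0.5, 1.5),
                              noise_sd = 0.5,
                              dropout_prob = 0.1,
                              frac_active_cohorts = 0.75,
                              n_planted_training = 300,
                              n_planted_heldout = 100,
                              n_planted_undiscovered = 100,
                              frac_positive_sign = 0.5,
                              mirna_mean = 4,
                              mirna_sd = 1.5,
                              gene_baseline_mean = 5,
                              gene_baseline_sd = 1,
                              seed = 1L) {
  cfg <- list(
    n_cohorts = check_count(n_cohorts, "n_cohorts"),
    n_mirnas = check_count(n_mirnas, "n_mirnas"),
    n_genes = check_count(n_genes, "n_genes"),
    samples_per_cohort = samples_per_cohort,
    effect_size_range = effect_size_range,
    noise_sd = noise_sd,
    dropout_prob = check_prob(dropout_prob, "dropout_prob"),
    frac_active_cohorts = check_prob(frac_active_cohorts, "frac_active_cohorts"),
    n_planted_training = check_count(n_planted_training, "n_planted_training", min = 0),
    n_planted_heldout = check_count(n_planted_heldout, "n_planted_heldout", min = 0),
    n_planted_undiscovered = check_count(n_planted_undiscovered, "n_planted_undiscovered", min = 0),
    frac_positive_sign = check_prob(frac_positive_sign, "frac_positive_sign"),
    mirna_mean = mirna_mean,
    mirna_sd = mirna_sd,
    gene_baseline_mean = gene_baseline_mean,
    gene_baseline_sd = gene_baseline_sd,
    seed = check_count(seed, "seed", min = 0)
  )
  if (!is.numeric(cfg$samples_per_cohort) ||
      !length(cfg$samples_per_cohort) %in% c(1L, 2L) ||
      any(cfg$samples_per_cohort < 3))
    stop("'samples_per_cohort' must be a count >= 3 or a length-2 range", call. = FALSE)
  if (!is.numeric(cfg$effect_size_range) || length(cfg$effect_size_range) != 2L ||
      any(cfg$effect_size_range < 0) || diff(cfg$effect_size_range) < 0)
    stop("'effect_size_range' must be an ascending non-negative length-2 range", call. = FALSE)
  if (!is.numeric(cfg$noise_sd) || length(cfg$noise_sd) != 1L || cfg$noise_sd < 0)
    stop("'noise_sd' must be a single non-negative number", call. = FALSE)
  n_planted <- cfg$n_planted_training + cfg$n_planted_heldout + cfg$n_planted_undiscovered
  if (n_planted > cfg$n_mirnas * cfg$n_genes)
    stop("planted pair counts exceed the n_mirnas x n_genes universe", call. = FALSE)
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "simulation_config: %d cohorts, %d miRNAs x %d genes, %s samples/cohort\n",
    x$n_cohorts, x$n_mirnas, x$n_genes,
    paste(x$samples_per_cohort, collapse = "-")))
  cat(sprintf("  planted pairs: %d training / %d heldout / %d undiscovered\n",
              x$n_planted_training, x$n_planted_heldout, x$n_planted_undiscovered))
  cat(sprintf("  |beta| in [%.2f, %.2f], noise sd %.2f, dropout %.2f, seed %d\n",
              x$effect_size_range[1], x$effect_size_range[2],
              x$noise_sd, x$dropout_prob, x$seed))
  invisible(x)
}

#' One cohort's paired expression matrices
#'
#' @param cohort_id Cohort name.
#' @param mirna_matrix,gene_matrix Numeric samples x features matrices with
#'   shared rownames (sample ids); non-negative, finite, 0 = not expressed.
#' @return An `expression_panel` object.
#' @export
expression_panel <- function(cohort_id, mirna_matrix, gene_matrix) {
  stopifnot(is.matrix(mirna_matrix), is.matrix(gene_matrix))
  if (nrow(mirna_matrix) != nrow(gene_matrix) ||
      !identical(rownames(mirna_matrix), rownames(gene_matrix)))
    stop("miRNA and gene matrices must share the sample axis", call. = FALSE)
  if (anyNA(mirna_matrix) || anyNA(gene_matrix) ||
      any(!is.finite(mirna_matrix)) || any(!is.finite(gene_matrix)))
    stop("expression matrices must be finite", call. = FALSE)
  if (min(mirna_matrix) < 0 || min(gene_matrix) < 0)
    stop("expression matrices must be non-negative (log scale, 0 = not expressed)",
         call. = FALSE)
  structure(list(cohort_id = cohort_id,
                 samples = rownames(mirna_matrix),
                 mirna_matrix = mirna_matrix,
                 gene_matrix = gene_matrix),
            class = "expression_panel")
}

#' @export
print.expression_panel <- function(x, ...) {
  cat(sprintf("expression_panel '%s': %d samples, %d miRNAs, %d genes\n",
              x$cohort_id, length(x$samples),
              ncol(x$mirna_matrix), ncol(x$gene_matrix)))
  invisible(x)
}

#' Simulate multi-cohort expression panels with planted miRNA-gene effects
#'
#' miRNA log expression is drawn from a truncated (at zero) Gaussian. Each
#' gene's expression is its baseline plus Gaussian noise; for a planted pair
#' `(m, g, sign, beta)` active in a cohort, gene `g` additionally receives
#' `sign * beta * (m - mean(m))` in that cohort, so the pair co-varies with
#' the planted sign while staying near its baseline level. Dropout then
#' zeroes entries independently, and values are clipped at zero.
#'
#' @param config A [simulation_config()].
#' @return A list with `panels` (list of [expression_panel()]) and `truth`
#'   (a `ground_truth` object: data frame of planted pairs with sign, tier
#'   and active-cohort list, plus the id universes).
#' @export
simulate_panels <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  cohorts <- sprintf("COH%02d", seq_len(config$n_cohorts))
  mirnas <- sprintf("mir-%03d", seq_len(config$n_mirnas))
  genes <- sprintf("G%04d", seq_len(config$n_genes))

  n_planted <- config$n_planted_training + config$n_planted_heldout +
    config$n_planted_undiscovered
  cell <- sample.int(config$n_mirnas * config$n_genes, n_planted)
  pairs <- data.frame(
    mirna = mirnas[(cell - 1L) %% config$n_mirnas + 1L],
    gene = genes[(cell - 1L) %/% config$n_mirnas + 1L],
    sign = ifelse(runif(n_planted) < config$frac_positive_sign, 1L, -1L),
    beta = runif(n_planted, config$effect_size_range[1], config$effect_size_range[2]),
    tier = rep(c("training", "heldout", "undiscovered"),
               times = c(config$n_planted_training, config$n_planted_heldout,
                         config$n_planted_undiscovered)),
    stringsAsFactors = FALSE
  )
  n_active <- max(1L, round(config$frac_active_cohorts * config$n_cohorts))
  active <- replicate(n_planted, sort(sample(cohorts, n_active)), simplify = FALSE)

  baseline <- rnorm(config$n_genes, config$gene_baseline_mean, config$gene_baseline_sd)
  gene_idx <- match(pairs$gene, genes)
  mirna_idx <- match(pairs$mirna, mirnas)

  panels <- vector("list", config$n_cohorts)
  for (ci in seq_len(config$n_cohorts)) {
    ns <- if (length(config$samples_per_cohort) == 2L)
      sample(seq(config$samples_per_cohort[1], config$samples_per_cohort[2]), 1L)
    else as.integer(config$samples_per_cohort)
    sample_ids <- sprintf("%s_S%03d", cohorts[ci], seq_len(ns))

    M <- matrix(pmax(rnorm(ns * config$n_mirnas, config$mirna_mean, config$mirna_sd), 0),
                nrow = ns, dimnames = list(sample_ids, mirnas))
    G <- matrix(rep(baseline, each = ns) + rnorm(ns * config$n_genes, 0, config$noise_sd),
                nrow = ns, dimnames = list(sample_ids, genes))
    for (pi in seq_len(n_planted)) {
      if (!cohorts[ci] %in% active[[pi]]) next
      m <- M[, mirna_idx[pi]]
      G[, gene_idx[pi]] <- G[, gene_idx[pi]] +
        pairs$sign[pi] * pairs$beta[pi] * (m - mean(m))
    }
    if (config$dropout_prob > 0) {
      M[runif(length(M)) < config$dropout_prob] <- 0
      G[runif(length(G)) < config$dropout_prob] <- 0
    }
    G <- pmax(G, 0)
    panels[[ci]] <- expression_panel(cohorts[ci], M, G)
  }
  names(panels) <- cohorts

  truth <- structure(list(pairs = pairs, active = active,
                          mirnas = mirnas, genes = genes, cohorts = cohorts,
                          config = config),
                     class = "ground_truth")
  list(panels = panels, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d planted pairs (%s) over %d miRNAs x %d genes, %d cohorts\n",
              nrow(x$pairs),
              paste(sprintf("%s=%d", names(table(x$pairs$tier)), table(x$pairs$tier)),
                    collapse = ", "),
              length(x$mirnas), length(x$genes), length(x$cohorts)))
  invisible(x)
}

#' Planted pairs of one tier as an interaction database
#'
#' Convenience bridge from the simulator's ground truth to the labeling and
#' validation stages: the `training` tier plays the role of the curated
#' training databases, `heldout` the role of the held-out validation
#' databases.
#'
#' @param truth A `ground_truth` object.
#' @param tier One of `"training"`, `"heldout"`, `"undiscovered"`.
#' @param role Database role, `"training"` or `"validation"`.
#' @return An [interaction_db()].
#' @export
truth_tier_db <- function(truth, tier = c("training", "heldout", "undiscovered"),
                          role = if (tier == "training") "training" else "validation") {
  tier <- match.arg(tier)
  stopifnot(inherits(truth, "ground_truth"))
  p <- truth$pairs[truth$pairs$tier == tier, c("mirna", "gene")]
  interaction_db(p, name = paste0("planted_", tier), role = role)
}

#' Simulate a two-group miRNA perturbation experiment
#'
#' Generates control and treated (miRNA-overexpressing or knocked-down)
#' gene expression matrices over the ground truth's gene universe. Planted
#' targets of the perturbed miRNA that are active in `cohort_context` are
#' shifted in the treated group by `sign * shift` log units under
#' overexpression (mirrored under knockdown); all other genes are unshifted.
#'
#' @param truth A `ground_truth` object.
#' @param mirna Perturbed miRNA id (must exist in `truth`).
#' @param cohort_context Cohort whose active planted effects respond.
#' @param n_per_group Samples per group (>= 2).
#' @param shift Perturbation effect size in log units.
#' @param noise_sd Residual sd of the simulated experiment.
#' @param perturbation `"overexpression"` (default) or `"knockdown"`.
#' @param seed Integer seed.
#' @return A `perturbation_dataset` with `control_matrix` and
#'   `treated_matrix` (samples x genes) sharing the gene axis.
#' @export
simulate_perturbation <- function(truth, mirna, cohort_context,
                                  n_per_group = 20, shift = 5, noise_sd = 0.5,
                                  perturbation = c("overexpression", "knockdown"),
                                  seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  perturbation <- match.arg(perturbation)
  if (!mirna %in% truth$mirnas)
    stop(sprintf("unknown miRNA id '%s'", mirna), call. = FALSE)
  n_per_group <- check_count(n_per_group, "n_per_group", min = 2)
  set.seed(check_count(seed, "seed", min = 0))

  genes <- truth$genes
  base <- rnorm(length(genes), 5, 1)
  mk <- function(grp) {
    m <- matrix(rep(base, each = n_per_group) +
                  rnorm(n_per_group * length(genes), 0, noise_sd),
                nrow = n_per_group,
                dimnames = list(sprintf("%s_%02d", grp, seq_len(n_per_group)), genes))
    m
  }
  ctrl <- mk("control")
  trt <- mk("treated")

  hit <- which(truth$pairs$mirna == mirna &
                 vapply(truth$active, function(a) cohort_context %in% a, logical(1)))
  dir_mult <- if (perturbation == "overexpression") 1 else -1
  for (pi in hit) {
    g <- truth$pairs$gene[pi]
    trt[, g] <- trt[, g] + dir_mult * truth$pairs$sign[pi] * shift
  }
  structure(list(mirna_id = mirna, cohort_context = cohort_context,
                 control_matrix = ctrl, treated_matrix = trt,
                 perturbation = perturbation,
                 planted_targets = truth$pairs$gene[hit]),
            class = "perturbation_dataset")
}

#' @export
print.perturbation_dataset <- function(x, ...) {
  cat(sprintf("perturbation_dataset: %s of %s (%s context), %d vs %d samples, %d genes\n",
              x$perturbation, x$mirna_id, x$cohort_context,
              nrow(x$control_matrix), nrow(x$treated_matrix), ncol(x$control_matrix)))
  invisible(x)
}

#' Write simulated panels, databases and perturbation tables to TSV
#'
#' Produces the on-disk layout the readers in this package consume:
#' `<cohort>_mirna.tsv` / `<cohort>_gene.tsv` expression matrices (samples
#' as rows, first column `sample`), one two-column interaction database per
#' planted tier (`db_<tier>.tsv`), and one table per perturbation dataset
#' with a `group` label column.
#'
#' @param panels List of [expression_panel()].
#' @param truth A `ground_truth` object.
#' @param datasets Optional list of `perturbation_dataset` objects.
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of written file paths, invisibly.
#' @export
write_fixtures <- function(panels, truth, datasets = list(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop(sprintf("cannot create output directory '%s'", out_dir), call. = FALSE)
  paths <- character(0)
  for (p in panels) {
    for (what in c("mirna", "gene")) {
      f <- file.path(out_dir, sprintf("%s_%s.tsv", p$cohort_id, what))
      write_expression_tsv(p[[paste0(what, "_matrix")]], f)
      paths[sprintf("%s_%s", p$cohort_id, what)] <- f
    }
  }
  for (tier in c("training", "heldout", "undiscovered")) {
    f <- file.path(out_dir, sprintf("db_%s.tsv", tier))
    tb <- truth$pairs[truth$pairs$tier == tier, c("mirna", "gene")]
    data.table::fwrite(tb, f, sep = "\t")
    paths[paste0("db_", tier)] <- f
  }
  for (d in datasets) {
    f <- file.path(out_dir, sprintf("perturbation_%s_%s.tsv", d$mirna_id, d$cohort_context))
    write_perturbation_tsv(d, f)
    paths[sprintf("perturbation_%s_%s", d$mirna_id, d$cohort_context)] <- f
  }
  invisible(paths)
}
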