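#' Read an expression matrix from TSV
#'
#' Expects a header row of feature ids, a first column of sample ids, and
#' finite non-negative numeric cells; violations are reported with the
#' offending row and column.
#'
#' @param path TSV file path.
#' @return Numeric matrix, samples x features, with dimnames.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path), call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1), data.table = FALSE)
  if (nrow(dt) == 0L || ncol(dt) < 2L)
    stop(sprintf("'%s' has an empty data section", path), call. = FALSE)
  samples <- dt[[1]]
  vals <- dt[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1]
      stop(sprintf("'%s': non-numeric cell at row %d, column %d ('%s')",
                   path, bad, j + 1L, col[bad]), call. = FALSE)
    }
    if (anyNA(col) || any(!is.finite(col)))
      stop(sprintf("'%s': missing or non-finite cell at row %d, column %d",
                   path, which(!is.finite(col) | is.na(col))[1], j + 1L),
           call. = FALSE)
    if (any(col < 0))
      stop(sprintf("'%s': negative value at row %d, column %d",
                   path, which(col < 0)[1], j + 1L), call. = FALSE)
  }
  m <- as.matrix(vals)
  rownames(m) <- samples
  m
}

#' Write an expression matrix to TSV
#' @param mat Numeric matrix with sample rownames and feature colnames.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  dt <- data.table::data.table(sample = rownames(mat))
  dt <- cbind(dt, data.table::as.data.table(mat))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a cohort's paired expression matrices
#' @param dir Directory holding `<cohort>_mirna.tsv` and
#'   `<cohort>_gene.tsv`.
#' @param cohort_id Cohort name.
#' @return An [expression_panel()].
#' @export
read_panel <- function(dir, cohort_id) {
  expression_panel(cohort_id,
                   read_expression_tsv(file.path(dir, paste0(cohort_id, "_mirna.tsv"))),
                   read_expression_tsv(file.path(dir, paste0(cohort_id, "_gene.tsv"))))
}

#' Read every cohort panel in a fixture directory
#' @param dir Directory written by [write_fixtures()].
#' @return Named list of [expression_panel()].
#' @export
read_panels <- function(dir) {
  files <- sort(list.files(dir, pattern = "_mirna\\.tsv$"))
  if (length(files) == 0L)
    stop(sprintf("no '*_mirna.tsv' panels found in '%s'", dir), call. = FALSE)
  cohorts <- sub("_mirna\\.tsv$", "", files)
  stats::setNames(lapply(cohorts, function(cid) read_panel(dir, cid)), cohorts)
}

#' Write a perturbation dataset to TSV
#'
#' Long layout: first column `sample`, second column `group`
#' (`control`/`treated`), remaining columns one per gene.
#'
#' @param data A `perturbation_dataset`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_perturbation_tsv <- function(data, path) {
  stopifnot(inherits(data, "perturbation_dataset"))
  both <- rbind(data$control_matrix, data$treated_matrix)
  dt <- data.table::data.table(
    sample = rownames(both),
    group = rep(c("control", "treated"),
                c(nrow(data$control_matrix), nrow(data$treated_matrix))))
  dt <- cbind(dt, data.table::as.data.table(both))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a perturbation dataset from TSV
#' @param path File written by [write_perturbation_tsv()].
#' @param mirna_id,cohort_context Metadata to attach (not stored in the
#'   table itself).
#' @param perturbation `"overexpression"` or `"knockdown"`.
#' @return A `perturbation_dataset`.
#' @export
read_perturbation_tsv <- function(path, mirna_id = NA_character_,
                                  cohort_context = NA_character_,
                                  perturbation = "overexpression") {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = list(character = 1:2))
  if (!identical(names(dt)[1:2], c("sample", "group")))
    stop(sprintf("'%s' must start with 'sample' and 'group' columns", path),
         call. = FALSE)
  if (!all(dt$group %in% c("control", "treated")))
    stop(sprintf("'%s': group labels must be 'control'/'treated'", path),
         call. = FALSE)
  m <- as.matrix(dt[, -(1:2), drop = FALSE])
  rownames(m) <- dt$sample
  structure(list(mirna_id = mirna_id, cohort_context = cohort_context,
                 control_matrix = m[dt$group == "control", , drop = FALSE],
                 treated_matrix = m[dt$group == "treated", , drop = FALSE],
                 perturbation = perturbation),
            class = "perturbation_dataset")
}

#' Write / read the feature table
#'
#' TSV layout: `mirna`, `gene`, then one correlation column per cohort
#' with MISSING encoded as `NA`.
#'
#' @param table A `feature_table`.
#' @param path File path.
#' @return `path` invisibly for the writer; a `feature_table` for the
#'   reader (retention counters reflect the stored table only).
#' @export
write_feature_tsv <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  dt <- cbind(data.table::as.data.table(table$pairs),
              data.table::as.data.table(table$values))
  data.table::fwrite(dt, path, sep = "\t", na = "NA")
  invisible(path)
}

#' @rdname write_feature_tsv
#' @export
read_feature_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          na.strings = "NA", colClasses = list(character = 1:2))
  values <- as.matrix(dt[, -(1:2), drop = FALSE])
  structure(list(pairs = dt[, 1:2],
                 cohorts = colnames(values),
                 values = values,
                 n_missing = rowSums(is.na(values)),
                 n_total_pairs = nrow(dt),
                 n_retained = nrow(dt),
                 min_coexpressing = NA_integer_,
                 max_missing = NA_integer_),
            class = "feature_table")
}

#' Write / read a label set
#' @param labels A `label_set`.
#' @param path File path.
#' @return `path` invisibly for the writer; a `label_set` for the reader.
#' @export
write_labels_tsv <- function(labels, path) {
  stopifnot(inherits(labels, "label_set"))
  data.table::fwrite(data.table::data.table(
    pair = labels$keys,
    label = ifelse(labels$positive, "positive", "negative")),
    path, sep = "\t")
  invisible(path)
}

#' @rdname write_labels_tsv
#' @export
read_labels_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  positive <- dt$label == "positive"
  structure(list(keys = dt$pair, positive = positive,
                 n_positive = sum(positive), n_negative = sum(!positive),
                 positive_pct = positive_fraction_pct(sum(positive), length(positive)),
                 n_unmatched_db_pairs = 0L),
            class = "label_set")
}

#' Read a pipeline configuration file
#'
#' YAML with optional sections `simulation` ([simulation_config()]
#' fields), `ensemble` ([ensemble_config()] fields), `validation`
#' (`alpha`), plus top-level `seed` and `out_dir`. Omitted fields take
#' the package defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  pipeline_config(simulation = raw$simulation %||% list(),
                  ensemble = raw$ensemble %||% list(),
                  validation = raw$validation %||% list(),
                  seed = raw$seed %||% 1L,
                  out_dir = raw$out_dir)
}

#' Assemble a pipeline configuration
#'
#' @param simulation Named list of [simulation_config()] overrides.
#' @param ensemble Named list of [ensemble_config()] overrides.
#' @param validation Named list; supports `alpha` (DEG level) and
#'   `freq_threshold` / `rate` used for the reported significant set.
#' @param seed Global seed; stage seeds are derived from it at fixed
#'   offsets (simulation +0, ensemble +1000).
#' @param out_dir Output directory for [run_pipeline()] artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = list(), ensemble = list(),
                            validation = list(), seed = 1L, out_dir = NULL) {
  seed <- check_count(seed, "seed", min = 0)
  simulation$seed <- simulation$seed %||% seed
  ensemble$base_seed <- ensemble$base_seed %||% (seed + 1000L)
  sim_cfg <- do.call(simulation_config, simulation)
  ens_cfg <- do.call(ensemble_config, ensemble)
  structure(list(simulation = sim_cfg,
                 ensemble = ens_cfg,
                 validation = list(alpha = validation$alpha %||% 0.05,
                                   rate = validation$rate,
                                   freq_threshold = validation$freq_threshold),
                 seed = seed,
                 out_dir = out_dir),
            class = "pipeline_config")
}
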