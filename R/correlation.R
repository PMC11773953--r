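#' Pearson product-moment correlation
#'
#' Thin, validating wrapper used everywhere a single pair is correlated.
#' Inputs of length < 2 or with zero variance have no defined correlation
#' and raise a condition of class `mirpancor_undefined_correlation`;
#' [cohort_correlation()] converts that condition into a MISSING cell.
#'
#' @param x,y Equal-length numeric vectors.
#' @return Correlation in `[-1, 1]`.
#' @examples
#' pearson_r(c(1, 2, 3), c(2, 4, 6)) # 1
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 2L || sd(x) == 0 || sd(y) == 0)
    stop(structure(class = c("mirpancor_undefined_correlation", "error", "condition"),
                   list(message = "correlation undefined: length < 2 or constant input",
                        call = sys.call(-1))))
  unname(cor(x, y))
}

#' Samples co-expressing a miRNA and a gene
#'
#' A sample counts as expressing a feature when its (log-scale) value is
#' strictly positive; zero encodes non-expression.
#'
#' @param mi,g Equal-length numeric expression vectors.
#' @return Integer indices (1-based) of samples where both are positive.
#' @export
coexpressing_samples <- function(mi, g) {
  if (length(mi) != length(g))
    stop("vectors must have equal length", call. = FALSE)
  which(mi > 0 & g > 0)
}

#' Per-cohort correlation of one miRNA-gene pair
#'
#' Computes the Pearson correlation over co-expressing samples only, and
#' only when their number strictly exceeds `min_coexpressing` (so exactly
#' `min_coexpressing` co-expressing samples yields MISSING). Constant
#' sub-vectors also yield MISSING.
#'
#' @param panel An [expression_panel()].
#' @param mirna,gene Feature ids present in the panel.
#' @param min_coexpressing Minimum co-expressing sample count that must be
#'   exceeded (default 10, i.e. at least 11 samples).
#' @param use_all_samples If `TRUE`, the co-expression count acts only as a
#'   gate and the correlation is computed over all samples.
#' @return A correlation in `[-1, 1]`, or `NA_real_` (MISSING).
#' @export
cohort_correlation <- function(panel, mirna, gene, min_coexpressing = 10,
                               use_all_samples = FALSE) {
  stopifnot(inherits(panel, "expression_panel"))
  if (!mirna %in% colnames(panel$mirna_matrix))
    stop(sprintf("unknown miRNA id '%s' in cohort '%s'", mirna, panel$cohort_id),
         call. = FALSE)
  if (!gene %in% colnames(panel$gene_matrix))
    stop(sprintf("unknown gene id '%s' in cohort '%s'", gene, panel$cohort_id),
         call. = FALSE)
  mi <- panel$mirna_matrix[, mirna]
  g <- panel$gene_matrix[, gene]
  idx <- coexpressing_samples(mi, g)
  if (length(idx) <= min_coexpressing) return(NA_real_)
  if (!use_all_samples) {
    mi <- mi[idx]
    g <- g[idx]
  }
  tryCatch(pearson_r(mi, g),
           mirpancor_undefined_correlation = function(e) NA_real_)
}

## All miRNA x gene correlations of one cohort at once, via closed-form
## moment sums over the co-expression masks: values outside a feature's
## support are exactly zero, so crossprods against the other feature's
## support indicator give the needed subset sums without looping over the
## per-pair sample subsets.
cohort_cor_matrix <- function(panel, min_coexpressing = 10,
                              use_all_samples = FALSE) {
  A <- panel$mirna_matrix
  B <- panel$gene_matrix
  Za <- (A > 0) * 1
  Zb <- (B > 0) * 1
  n <- crossprod(Za, Zb)
  if (use_all_samples) {
    R <- suppressWarnings(cor(A, B))
  } else {
    Sx <- crossprod(A, Zb)
    Sy <- crossprod(Za, B)
    Sxx <- crossprod(A^2, Zb)
    Syy <- crossprod(Za, B^2)
    Sxy <- crossprod(A, B)
    vx <- n * Sxx - Sx^2
    vy <- n * Syy - Sy^2
    scale_x <- pmax(n * Sxx, 1)
    scale_y <- pmax(n * Syy, 1)
    R <- (n * Sxy - Sx * Sy) / sqrt(pmax(vx, 0) * pmax(vy, 0))
    # constant sub-vectors (variance ~ 0 up to float error) are undefined
    R[vx <= 1e-9 * scale_x | vy <= 1e-9 * scale_y] <- NA_real_
    R <- pmin(pmax(R, -1), 1)
  }
  R[!is.finite(R)] <- NA_real_
  R[n <= min_coexpressing] <- NA_real_
  R
}

#' Assemble the pair x cohort correlation feature table
#'
#' Evaluates every miRNA x gene pair in every cohort with
#' [cohort_correlation()] semantics, then applies the missing-cohort
#' exclusion rule: pairs whose correlation is MISSING in more than
#' `max_missing` cohorts are dropped.
#'
#' @param panels Non-empty list of [expression_panel()] sharing one feature
#'   universe.
#' @param min_coexpressing Passed to the per-cohort filter (strictly
#'   exceeded; default 10).
#' @param max_missing Maximum number of MISSING cohorts a retained pair may
#'   have (default 3).
#' @param use_all_samples Compute correlations over all samples instead of
#'   the co-expressing subset (the filter still gates computability).
#' @return A `feature_table`: `pairs` (data frame mirna/gene), `cohorts`,
#'   `values` (pairs x cohorts matrix, `NA` = MISSING), `n_missing` per
#'   pair, and retention counts.
#' @export
build_feature_table <- function(panels, min_coexpressing = 10, max_missing = 3,
                                use_all_samples = FALSE) {
  if (length(panels) == 0L) stop("at least one panel is required", call. = FALSE)
  stopifnot(all(vapply(panels, inherits, logical(1), "expression_panel")))
  mirnas <- colnames(panels[[1]]$mirna_matrix)
  genes <- colnames(panels[[1]]$gene_matrix)
  for (p in panels)
    if (!identical(colnames(p$mirna_matrix), mirnas) ||
        !identical(colnames(p$gene_matrix), genes))
      stop("panels must share identical miRNA and gene universes", call. = FALSE)

  cohorts <- vapply(panels, `[[`, character(1), "cohort_id")
  values <- matrix(NA_real_, nrow = length(mirnas) * length(genes),
                   ncol = length(cohorts),
                   dimnames = list(NULL, cohorts))
  for (ci in seq_along(panels))
    values[, ci] <- as.vector(cohort_cor_matrix(panels[[ci]], min_coexpressing,
                                                use_all_samples))
  pairs <- data.frame(mirna = rep(mirnas, times = length(genes)),
                      gene = rep(genes, each = length(mirnas)),
                      stringsAsFactors = FALSE)
  n_missing <- rowSums(is.na(values))
  keep <- n_missing <= max_missing
  structure(list(pairs = pairs[keep, , drop = FALSE],
                 cohorts = cohorts,
                 values = values[keep, , drop = FALSE],
                 n_missing = n_missing[keep],
                 n_total_pairs = nrow(pairs),
                 n_retained = sum(keep),
                 min_coexpressing = min_coexpressing,
                 max_missing = max_missing),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d of %d pairs retained (max %d MISSING of %d cohorts)\n",
              x$n_retained, x$n_total_pairs, x$max_missing, length(x$cohorts)))
  cat(sprintf("  %d unique miRNAs, %d unique genes\n",
              length(unique(x$pairs$mirna)), length(unique(x$pairs$gene))))
  invisible(x)
}

#' Keys of a feature table's pairs
#' @param table A `feature_table`.
#' @return Character vector of [pair_key()] strings, one per retained pair.
#' @export
feature_table_keys <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  pair_key(table$pairs$mirna, table$pairs$gene)
}
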