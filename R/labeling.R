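#' Canonicalize a miRNA identifier
#'
#' Lowercases, trims whitespace, removes a leading `hsa-` species prefix
#' (which also maps `miR` to `mir`), and optionally strips a trailing
#' `-5p`/`-3p` arm suffix so database entries and expression-matrix names
#' can be matched regardless of arm annotation.
#'
#' @param raw Character vector of miRNA names.
#' @param strip_arm Remove a `-5p`/`-3p` suffix (default `FALSE`).
#' @return Canonical names, e.g. `"hsa-miR-335-5p"` -> `"mir-335-5p"`
#'   (`"mir-335"` with `strip_arm = TRUE`).
#' @export
normalize_mirna_id <- function(raw, strip_arm = FALSE) {
  if (length(raw) == 0L || any(is.na(raw)) || any(!nzchar(trimws(raw))))
    stop("miRNA ids must be non-empty strings", call. = FALSE)
  x <- tolower(trimws(raw))
  x <- sub("^hsa-", "", x)
  if (strip_arm) x <- sub("-[35]p$", "", x)
  x
}

#' Canonicalize a gene symbol
#'
#' Uppercases and strips surrounding whitespace; no alias resolution.
#'
#' @param raw Character vector of gene symbols.
#' @return Canonical symbols.
#' @export
normalize_gene_id <- function(raw) {
  if (length(raw) == 0L || any(is.na(raw)) || any(!nzchar(trimws(raw))))
    stop("gene symbols must be non-empty strings", call. = FALSE)
  toupper(trimws(raw))
}

#' Construct an interaction database from a pair table
#'
#' @param pairs Data frame (or coercible) whose first two columns are miRNA
#'   and gene identifiers; canonicalized and de-duplicated here.
#' @param name Database name.
#' @param role `"training"` or `"validation"`; training databases define the
#'   positive label class, validation databases are quarantined for the
#'   held-out validation rate.
#' @param strip_arm Passed to [normalize_mirna_id()].
#' @return An `interaction_db` with canonical `pairs`, `keys`, and the
#'   number of duplicates removed in `n_duplicates`.
#' @export
interaction_db <- function(pairs, name, role = c("training", "validation"),
                           strip_arm = FALSE) {
  role <- match.arg(role)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (nrow(pairs) > 0L) {
    p <- data.frame(mirna = normalize_mirna_id(pairs[[1]], strip_arm = strip_arm),
                    gene = normalize_gene_id(pairs[[2]]),
                    stringsAsFactors = FALSE)
  } else {
    p <- data.frame(mirna = character(0), gene = character(0),
                    stringsAsFactors = FALSE)
  }
  keys <- pair_key(p$mirna, p$gene)
  dup <- duplicated(keys)
  structure(list(name = name, role = role,
                 pairs = p[!dup, , drop = FALSE],
                 keys = keys[!dup],
                 n_duplicates = sum(dup)),
            class = "interaction_db")
}

#' @export
print.interaction_db <- function(x, ...) {
  cat(sprintf("interaction_db '%s' (%s role): %d pairs (%d duplicates removed)\n",
              x$name, x$role, nrow(x$pairs), x$n_duplicates))
  invisible(x)
}

#' Load an interaction database from a two-column TSV
#'
#' @param path Tab-separated file whose first two columns are miRNA and
#'   gene ids. Rows with a missing field are rejected with their line
#'   number.
#' @param name Database name (defaults to the file name).
#' @param role `"training"` or `"validation"`.
#' @param header Whether the file carries a header row (default `TRUE`).
#' @param strip_arm Passed to [normalize_mirna_id()].
#' @return An [interaction_db()].
#' @export
load_interaction_db <- function(path, name = basename(path),
                                role = c("training", "validation"),
                                header = TRUE, strip_arm = FALSE) {
  role <- match.arg(role)
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path), call. = FALSE)
  lines <- readLines(path)
  if (header && length(lines) > 0L) lines <- lines[-1L]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(interaction_db(data.frame(mirna = character(0), gene = character(0)),
                          name = name, role = role))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, function(f)
    length(f) < 2L || !nzchar(trimws(f[1])) || !nzchar(trimws(f[2])), logical(1)))
  if (length(bad) > 0L)
    stop(sprintf("malformed row in '%s' at line %d: expected two tab-separated fields",
                 path, bad[1] + if (header) 1L else 0L), call. = FALSE)
  interaction_db(data.frame(mirna = vapply(fields, `[`, character(1), 1L),
                            gene = vapply(fields, `[`, character(1), 2L),
                            stringsAsFactors = FALSE),
                 name = name, role = role, strip_arm = strip_arm)
}

#' Positive-class fraction as a printed percentage
#'
#' The positive fraction of a labeled pair universe, as a percentage
#' rounded to two decimals (the precision used when reporting label
#' imbalance).
#'
#' @param n_positive,n_total Counts.
#' @return `round(100 * n_positive / n_total, 2)`.
#' @export
positive_fraction_pct <- function(n_positive, n_total) {
  stopifnot(n_total > 0, n_positive >= 0, n_positive <= n_total)
  round(100 * n_positive / n_total, 2)
}

#' Label feature-table pairs from training interaction databases
#'
#' A retained pair is positive iff it appears in the union of the training
#' databases; every other retained pair is negative (which therefore mixes
#' truly unrelated pairs with interactions not yet curated). Databases with
#' a validation role are refused outright — the held-out sets must never
#' influence labels.
#'
#' @param table A `feature_table`.
#' @param training_dbs List of [interaction_db()], all with role
#'   `"training"`.
#' @return A `label_set`: logical `positive` aligned to the table's pairs,
#'   `n_positive`, `n_negative`, `positive_pct` (two decimals), and
#'   `n_unmatched_db_pairs` (database pairs absent from the table, e.g.
#'   dropped by the eligibility filter).
#' @export
assign_labels <- function(table, training_dbs) {
  stopifnot(inherits(table, "feature_table"))
  if (inherits(training_dbs, "interaction_db")) training_dbs <- list(training_dbs)
  roles <- vapply(training_dbs, `[[`, character(1), "role")
  if (any(roles != "training"))
    stop("refusing validation-role database(s) in label assignment: ",
         paste(vapply(training_dbs, `[[`, character(1), "name")[roles != "training"],
               collapse = ", "), call. = FALSE)
  keys <- feature_table_keys(table)
  db_keys <- unique(unlist(lapply(training_dbs, `[[`, "keys")))
  positive <- keys %in% db_keys
  n_unmatched <- sum(!db_keys %in% keys)
  if (n_unmatched > 0L)
    message(sprintf("%d training-database pair(s) not in the feature table were ignored",
                    n_unmatched))
  structure(list(keys = keys, positive = positive,
                 n_positive = sum(positive), n_negative = sum(!positive),
                 positive_pct = positive_fraction_pct(sum(positive), length(positive)),
                 n_unmatched_db_pairs = n_unmatched),
            class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  cat(sprintf("label_set: %d positives / %d negatives (%.2f%% positive)\n",
              x$n_positive, x$n_negative, x$positive_pct))
  invisible(x)
}
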