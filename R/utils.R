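#' @importFrom stats cor pt rnorm runif sd t.test
#' @importFrom utils modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical key for a miRNA-gene pair
#'
#' Pairs are compared throughout the package by a single string key so that
#' feature tables, label sets, databases and consensus calls all agree on
#' identity.
#'
#' @param mirna Character vector of canonical miRNA ids.
#' @param gene Character vector of canonical gene symbols.
#' @return Character vector `"<mirna>|<gene>"`.
#' @export
pair_key <- function(mirna, gene) paste(mirna, gene, sep = "|")

## Rank-based AUC (probability a random positive outscores a random negative).
auc_score <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  as.numeric(x)
}
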