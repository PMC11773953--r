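fake_keys <- function(n, prefix = "mir-x|G") paste0(prefix, seq_len(n))

db_from_keys <- function(keys, name, role) {
  parts <- strsplit(keys, "|", fixed = TRUE)
  interaction_db(data.frame(mirna = vapply(parts, `[`, "", 1),
                            gene = vapply(parts, `[`, "", 2),
                            stringsAsFactors = FALSE), name, role)
}

test_that("validation rate counts only held-out-exclusive pairs", {
  sig <- fake_keys(871)
  heldout <- db_from_keys(c(sig[1:28], fake_keys(100, "mir-h|G")), "held", "validation")
  training <- db_from_keys(fake_keys(50, "mir-t|G"), "train", "training")
  v <- validation_rate(sig, list(heldout), list(training))
  expect_equal(v$n_validated, 28L)
  expect_equal(v$percentage, 3.21)

  # held-out knowledge already in training contributes nothing
  both <- db_from_keys(sig[1:28], "both", "training")
  v0 <- validation_rate(sig, list(heldout), list(both))
  expect_equal(v0$n_validated, 0L)

  v100 <- validation_rate(sig[1:10],
                          db_from_keys(sig[1:10], "held", "validation"))
  expect_equal(v100$percentage, 100)
  expect_error(validation_rate(character(0), list(heldout)), "empty")
})

test_that("DEG t-tests are calibrated under the null and powered under shifts", {
  tr <- simulate_panels(tiny_config(n_genes = 2000, n_mirnas = 2, n_cohorts = 1,
                                    samples_per_cohort = 5,
                                    n_planted_training = 1, n_planted_heldout = 0,
                                    n_planted_undiscovered = 0))$truth
  null_pd <- simulate_perturbation(tr, "mir-002", tr$cohorts[1], n_per_group = 20,
                                   shift = 0, noise_sd = 0.5, seed = 5)
  deg <- deg_ttest(null_pd)
  frac <- length(deg$degs) / nrow(deg$tests)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
  # alpha nesting
  expect_true(all(deg_ttest(null_pd, alpha = 0.01)$degs %in% deg$degs))

  shifted <- simulate_perturbation(tr, tr$pairs$mirna[1], tr$active[[1]][1],
                                   n_per_group = 20, shift = 5, noise_sd = 0.5,
                                   seed = 6)
  dsh <- deg_ttest(shifted)
  g <- tr$pairs$gene[1]
  expect_true(g %in% dsh$degs)
  expect_equal(dsh$tests$direction[dsh$tests$gene == g],
               if (tr$pairs$sign[1] > 0) "up" else "down")
})

test_that("direction is the sign of treated minus control and constants are excluded", {
  ctrl <- cbind(G1 = c(5, 5.1, 4.9, 5), G2 = c(9, 9.2, 8.8, 9), G3 = rep(1, 4))
  trt <- cbind(G1 = c(7, 7.1, 6.9, 7), G2 = c(4, 4.2, 3.8, 4), G3 = rep(1, 4))
  rownames(ctrl) <- paste0("c", 1:4); rownames(trt) <- paste0("t", 1:4)
  pd <- structure(list(mirna_id = "mir-x", cohort_context = "COH01",
                       control_matrix = ctrl, treated_matrix = trt,
                       perturbation = "overexpression"),
                  class = "perturbation_dataset")
  expect_message(deg <- deg_ttest(pd), "1 constant gene")
  expect_equal(deg$n_excluded, 1L)
  expect_equal(deg$tests$direction[deg$tests$gene == "G1"], "up")
  expect_equal(deg$tests$direction[deg$tests$gene == "G2"], "down")
  expect_false("G3" %in% deg$tests$gene)
})

test_that("overlap rows print integer-rounded percentages", {
  degs <- paste0("D", 1:2000)
  predicted <- c(degs[1:31], paste0("P", 1:538))        # 31 of 569
  known <- c(degs[100 + 1:130], paste0("K", 1:3281))    # 130 of 3411
  ov <- overlap_stats(predicted, known, degs, "GSE-toy")
  expect_equal(ov$n_predicted, 569L)
  expect_equal(ov$label_predicted, "31 (5%)")
  expect_equal(ov$label_known, "130 (4%)")
  disjoint <- overlap_stats(paste0("A", 1:10), paste0("B", 1:10), degs)
  expect_equal(disjoint$label_predicted, "0 (0%)")
  expect_error(overlap_stats(character(0), known, degs), "non-empty")
})

test_that("concordance applies the overexpression rule and its knockdown mirror", {
  e <- data.frame(direction = c("up", "down", "up", "down"),
                  corr_sign = c("positive", "negative", "negative", "positive"),
                  stringsAsFactors = FALSE)
  r <- direction_concordance(e)
  expect_equal(r$n_concordant, 2L)
  expect_equal(r$percentage, 50)
  single <- direction_concordance(data.frame(direction = "up",
                                             corr_sign = "negative"))
  expect_equal(single$n_concordant, 0L)

  e$perturbation <- "knockdown"
  # under knockdown the previously discordant rows (up/negative, down/positive)
  # become the concordant ones
  rk <- direction_concordance(e)
  expect_equal(rk$n_concordant, 2L)

  # reversing every sign maps concordance c to total - c
  set.seed(9)
  big <- data.frame(direction = sample(c("up", "down"), 50, TRUE),
                    corr_sign = sample(c("positive", "negative"), 50, TRUE),
                    stringsAsFactors = FALSE)
  c1 <- direction_concordance(big)$n_concordant
  big$corr_sign <- ifelse(big$corr_sign == "positive", "negative", "positive")
  expect_equal(direction_concordance(big)$n_concordant, 50 - c1)

  big$corr_sign[1:5] <- NA
  expect_message(r2 <- direction_concordance(big), "skipped")
  expect_equal(r2$n_total, 45L)
  expect_equal(r2$n_skipped, 5L)
})

test_that("paired overlap t-tests match the closed form", {
  r0 <- paired_overlap_ttest(c(3, 5, 7), c(3, 5, 7))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)

  a <- c(5, 7, 9, 11); b <- a - c(1, 2, 3, 4)
  r <- paired_overlap_ttest(a, b)
  s_d <- sqrt(5 / 3)
  expect_equal(r$t, 2.5 / (s_d / 2), tolerance = 1e-12)
  expect_equal(r$p, 2 * pt(-2.5 / (s_d / 2), df = 3), tolerance = 1e-12)
  expect_error(paired_overlap_ttest(1:3, 1:4), "equal length")

  m <- cbind(A = c(5, 7, 9, 11), B = c(4, 5, 6, 7), C = c(5, 8, 7, 12))
  cm <- overlap_comparison_matrix(m)
  expect_equal(cm$p["A", "B"], cm$p["B", "A"])
  expect_equal(cm$t["A", "B"], -cm$t["B", "A"])
  expect_true(all(is.na(diag(cm$p))))
})

test_that("matched top-k selection is a deterministic sort with lexicographic ties", {
  sc <- data.frame(gene = c("G1", "G2", "G3"), score = c(0.9, 0.5, 0.9))
  expect_setequal(select_matched_predictions(sc, 3), c("G1", "G2", "G3"))
  expect_equal(select_matched_predictions(sc, 2), c("G1", "G3"))
  expect_error(select_matched_predictions(sc, 4), "exceeds")
  set.seed(10)
  for (i in 1:10) {
    sc <- data.frame(gene = sprintf("G%02d", sample(99, 15)),
                     score = sample(round(runif(15), 1)))
    k <- sample(15, 1)
    brute <- sc[order(-sc$score, sc$gene), "gene"][seq_len(k)]
    expect_identical(select_matched_predictions(sc, k), brute)
  }
})
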