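test_that("identical seeds reproduce panels and ground truth exactly", {
  a <- simulate_panels(tiny_config())
  b <- simulate_panels(tiny_config())
  expect_identical(a, b)
  c <- simulate_panels(tiny_config(seed = 12L))
  expect_false(identical(a$panels, c$panels))
})

test_that("config invariants are enforced", {
  expect_error(simulation_config(n_cohorts = 0), "n_cohorts")
  expect_error(simulation_config(dropout_prob = 1.5), "probability")
  expect_error(simulation_config(n_mirnas = 2, n_genes = 2,
                                 n_planted_training = 5,
                                 n_planted_heldout = 0,
                                 n_planted_undiscovered = 0),
               "exceed")
  expect_error(simulation_config(effect_size_range = c(2, 1)), "range")
  tr <- simulate_panels(tiny_config())$truth
  expect_equal(anyDuplicated(pair_key(tr$pairs$mirna, tr$pairs$gene)), 0L)
  expect_true(all(unlist(tr$active) %in% tr$cohorts))
})

test_that("planted pairs approach |r| = 1 in the noise-free, dropout-free limit", {
  cfg <- tiny_config(noise_sd = 1e-6, dropout_prob = 0, effect_size_range = c(1, 1),
                     frac_active_cohorts = 1)
  sim <- simulate_panels(cfg)
  ft <- build_feature_table(sim$panels)
  keys <- feature_table_keys(ft)
  solo <- which(!sim$truth$pairs$gene %in%
                  sim$truth$pairs$gene[duplicated(sim$truth$pairs$gene)])
  rows <- match(pair_key(sim$truth$pairs$mirna[solo], sim$truth$pairs$gene[solo]),
                keys)
  expect_true(all(abs(ft$values[rows, ]) > 0.99))
})

test_that("non-planted pairs stay within the null band at n = 500", {
  cfg <- tiny_config(n_cohorts = 1, samples_per_cohort = 500, dropout_prob = 0,
                     n_planted_training = 1, n_planted_heldout = 0,
                     n_planted_undiscovered = 0)
  sim <- simulate_panels(cfg)
  ft <- build_feature_table(sim$panels, max_missing = 1)
  planted <- pair_key(sim$truth$pairs$mirna, sim$truth$pairs$gene)
  null_r <- ft$values[!feature_table_keys(ft) %in% planted, 1]
  # null sd ~ 1/sqrt(n-1) = 0.0448; 0.2 is ~4.5 sigma
  expect_true(all(abs(null_r) < 0.2))
})

test_that("null pairs match the analytic 5% two-sided rejection rate", {
  cfg <- simulation_config(n_cohorts = 1, n_mirnas = 20, n_genes = 60,
                           samples_per_cohort = 100, dropout_prob = 0,
                           n_planted_training = 0, n_planted_heldout = 0,
                           n_planted_undiscovered = 0, seed = 3L)
  ft <- build_feature_table(simulate_panels(cfg)$panels, max_missing = 1)
  n <- 100
  t_crit <- qt(0.975, n - 2)
  r_crit <- t_crit / sqrt(n - 2 + t_crit^2)
  frac <- mean(abs(ft$values[, 1]) > r_crit)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("strong planted effects recover the planted sign in active cohorts", {
  cfg <- tiny_config(effect_size_range = c(1.5, 1.5), noise_sd = 0.5,
                     dropout_prob = 0, samples_per_cohort = 100)
  sim <- simulate_panels(cfg)
  ft <- build_feature_table(sim$panels)
  keys <- feature_table_keys(ft)
  for (i in seq_len(nrow(sim$truth$pairs))) {
    row <- match(pair_key(sim$truth$pairs$mirna[i], sim$truth$pairs$gene[i]), keys)
    cols <- match(sim$truth$active[[i]], ft$cohorts)
    expect_true(all(sign(ft$values[row, cols]) == sim$truth$pairs$sign[i]))
  }
})

test_that("perturbation shifts planted targets by sign under overexpression", {
  sim <- simulate_panels(tiny_config(frac_active_cohorts = 1))
  tr <- sim$truth
  m <- tr$pairs$mirna[1]
  pd <- simulate_perturbation(tr, m, tr$cohorts[1], n_per_group = 20,
                              shift = 5, noise_sd = 0.5, seed = 8)
  deg <- deg_ttest(pd)
  for (i in which(tr$pairs$mirna == m)) {
    g <- tr$pairs$gene[i]
    expect_true(g %in% deg$degs)
    expect_equal(deg$tests$direction[deg$tests$gene == g],
                 if (tr$pairs$sign[i] > 0) "up" else "down")
  }
  # knockdown mirrors the direction
  pk <- simulate_perturbation(tr, m, tr$cohorts[1], n_per_group = 20,
                              shift = 5, noise_sd = 0.5, seed = 8,
                              perturbation = "knockdown")
  dk <- deg_ttest(pk)
  i <- which(tr$pairs$mirna == m)[1]
  g <- tr$pairs$gene[i]
  expect_equal(dk$tests$direction[dk$tests$gene == g],
               if (tr$pairs$sign[i] > 0) "down" else "up")
  expect_error(simulate_perturbation(tr, "mir-999", tr$cohorts[1]), "unknown miRNA")
  expect_identical(pd, simulate_perturbation(tr, m, tr$cohorts[1], n_per_group = 20,
                                             shift = 5, noise_sd = 0.5, seed = 8))
})

test_that("fixtures round-trip through the package readers", {
  sim <- simulate_panels(tiny_config())
  pd <- simulate_perturbation(sim$truth, sim$truth$pairs$mirna[1],
                              sim$truth$cohorts[1], seed = 2)
  out <- withr::local_tempdir()
  paths <- write_fixtures(sim$panels, sim$truth, list(pd), out)
  expect_true(all(file.exists(paths)))
  expect_length(grep("^db_", names(paths)), 3L)

  back <- read_panels(out)
  expect_equal(names(back), names(sim$panels))
  for (co in names(back)) {
    expect_equal(back[[co]]$mirna_matrix, sim$panels[[co]]$mirna_matrix)
    expect_equal(back[[co]]$gene_matrix, sim$panels[[co]]$gene_matrix)
  }
  db <- load_interaction_db(file.path(out, "db_training.tsv"), role = "training")
  expect_setequal(db$keys,
                  with(subset(sim$truth$pairs, tier == "training"),
                       pair_key(mirna, gene)))
  pd2 <- read_perturbation_tsv(paths[grep("perturbation", names(paths))],
                               pd$mirna_id, pd$cohort_context)
  expect_equal(pd2$control_matrix, pd$control_matrix)
  expect_equal(pd2$treated_matrix, pd$treated_matrix)
})

test_that("an empty planted tier writes a header-only database file", {
  cfg <- tiny_config(n_planted_undiscovered = 0, n_planted_heldout = 1,
                     n_planted_training = 1)
  sim <- simulate_panels(cfg)
  out <- withr::local_tempdir()
  write_fixtures(sim$panels, sim$truth, out_dir = out)
  f <- file.path(out, "db_undiscovered.tsv")
  expect_true(file.exists(f))
  db <- load_interaction_db(f, role = "validation")
  expect_equal(nrow(db$pairs), 0L)
})
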