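test_that("simulation is deterministic in the seed and respects coverage", {
  cfg <- simulation_config(n_tissues = 4, lines_per_tissue = 6, n_genes = 30,
                           n_drugs = 6, seed = 11)
  a <- simulate_screen(cfg)
  b <- simulate_screen(cfg)
  expect_identical(a$dataset$expression, b$dataset$expression)
  expect_identical(a$dataset$response, b$dataset$response)
  expect_identical(a$truth, b$truth)
  c <- simulate_screen(simulation_config(n_tissues = 4, lines_per_tissue = 6,
                                         n_genes = 30, n_drugs = 6,
                                         seed = 12))
  expect_false(identical(a$dataset$expression, c$dataset$expression))
  # Coverage: every drug screened in round(coverage * n) lines.
  tab <- table(a$dataset$response$drug_id)
  expect_true(all(tab == round(0.8 * 24)))
  expect_true(all(a$dataset$response$auc >= 0 & a$dataset$response$auc <= 1))
})

test_that("expression variance components match the configured values", {
  cfg <- simulation_config(n_tissues = 10, lines_per_tissue = 50,
                           n_genes = 200, n_drugs = 2, n_decoy_genes = 0,
                           tissue_effect_var = 0.3, residual_var = 0.7,
                           seed = 21)
  sim <- simulate_screen(cfg)
  x <- sim$dataset$expression
  tiss <- tissue_map(sim$dataset)[rownames(x)]
  f <- factor(tiss)
  # Within-tissue variance per gene, pooled.
  within <- mean(apply(x, 2, function(g) mean(tapply(g, f, var))))
  expect_equal(within, 0.7, tolerance = 0.05)
  # Between-tissue variance of tissue means ~ sigma_t^2 + sigma_e^2 / n_t.
  between <- mean(apply(x, 2, function(g) var(tapply(g, f, mean))))
  expect_equal(between, 0.3 + 0.7 / 50, tolerance = 0.07)
})

test_that("a null screen plants nothing and shows no within-tissue signal", {
  cfg <- simulation_config(n_tissues = 6, lines_per_tissue = 15,
                           n_genes = 80, n_drugs = 5, seed = 31,
                           drug_coverage = 1)
  sim <- simulate_null_screen(cfg)
  expect_equal(nrow(sim$truth$planted), 0)
  expect_false(any(sim$truth$drugs$carrier))
  # Mean within-tissue gene/AUC correlation across genes stays near 0.
  ds <- sim$dataset
  tiss <- tissue_map(ds)
  y <- ds$response$auc[ds$response$drug_id == "drug001"]
  names(y) <- ds$response$cell_line_id[ds$response$drug_id == "drug001"]
  z <- zscore_by_tissue(ds$expression, tiss)$values
  rs <- apply(z[names(y), ], 2, function(g) cor(g, y))
  expect_lt(abs(mean(rs)), 3 / sqrt(length(y)))
})

test_that("planted biomarkers drive negative within-tissue correlations for carriers", {
  cfg <- simulation_config(n_tissues = 5, lines_per_tissue = 14,
                           n_genes = 50, n_drugs = 6, drug_coverage = 1,
                           biomarkers = data.frame(pathway = "pathway1",
                                                   gene = "gene0001",
                                                   beta = 0.2,
                                                   carrier_fraction = 1),
                           response_noise_sd = 0.02, seed = 41)
  sim <- simulate_screen(cfg)
  ds <- sim$dataset
  tiss <- tissue_map(ds)
  carriers <- sim$truth$drugs$drug_id[sim$truth$drugs$carrier]
  expect_gt(length(carriers), 0)
  for (d in carriers[1:2]) {
    sub <- ds$response[ds$response$drug_id == d, ]
    for (t in unique(tiss[sub$cell_line_id])) {
      idx <- sub$cell_line_id[tiss[sub$cell_line_id] == t]
      expect_lt(cor(ds$expression[idx, "gene0001"], sub$auc[match(idx, sub$cell_line_id)]), 0)
    }
  }
})

test_that("tissue-variance extremes behave as expected and decoys dominate eta-squared", {
  tiss_of <- function(sim) tissue_map(sim$dataset)[rownames(sim$dataset$expression)]
  flat <- simulate_screen(simulation_config(
    n_tissues = 6, lines_per_tissue = 10, n_genes = 40, n_drugs = 3,
    tissue_effect_var = 0, solid_shift = 0, n_decoy_genes = 0,
    biomarkers = data.frame(pathway = "pathway1", gene = "gene0001",
                            beta = 0, carrier_fraction = 1), seed = 51))
  eta_flat <- vapply(1:40, function(j)
    eta_squared(flat$dataset$expression[, j], tiss_of(flat)), numeric(1))
  # Null eta2 centers on its no-signal expectation (k-1)/(n-1), not on a
  # tissue signal.
  expect_lt(mean(eta_flat), 2 * (6 - 1) / (60 - 1))

  sharp <- simulate_screen(simulation_config(
    n_tissues = 6, lines_per_tissue = 10, n_genes = 40, n_drugs = 3,
    tissue_effect_var = 1, residual_var = 1e-6, n_decoy_genes = 0,
    seed = 52))
  eta_sharp <- vapply(1:40, function(j)
    eta_squared(sharp$dataset$expression[, j], tiss_of(sharp)), numeric(1))
  expect_gt(min(eta_sharp), 0.999)

  sim <- simulate_screen(simulation_config(n_tissues = 8,
                                           lines_per_tissue = 12,
                                           n_genes = 60, n_drugs = 6,
                                           seed = 53))
  tiss <- tiss_of(sim)
  eta_decoy <- eta_squared(sim$dataset$expression[, sim$truth$decoy_genes],
                           tiss)
  eta_planted <- eta_squared(
    sim$dataset$expression[, sim$truth$planted$gene[1]], tiss)
  expect_gt(eta_decoy, eta_planted)
})

test_that("infeasible configurations are rejected", {
  expect_error(simulation_config(n_genes = 10, biomarkers = data.frame(
    pathway = "pathway1", gene = "gene9999", beta = 0.1,
    carrier_fraction = 1)), "not present among simulated genes")
  expect_error(simulation_config(drug_coverage = 0), "drug_coverage")
  expect_error(simulation_config(residual_var = 0), "variances")
  expect_error(simulation_config(n_genes = 50, n_decoy_genes = 1,
                                 biomarkers = data.frame(
                                   pathway = "pathway1", gene = "gene0050",
                                   beta = 0.1, carrier_fraction = 1)),
               "distinct from decoy")
})

test_that("written screens include ground truth", {
  dir <- withr::local_tempdir()
  sim <- simulate_screen(simulation_config(n_tissues = 3,
                                           lines_per_tissue = 4,
                                           n_genes = 10, n_drugs = 3,
                                           seed = 61))
  write_simulated_screen(sim, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "expression.tsv", "samples.tsv", "response.tsv", "drugs.tsv",
    "ground_truth.tsv")))))
  gt <- read.delim(file.path(dir, "ground_truth.tsv"))
  expect_equal(nrow(gt), 3)
})
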