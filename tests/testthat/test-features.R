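test_that("feature ranks order genes by absolute averaged weight", {
  ms <- fake_model_set(list(
    d1 = matrix(c(0.5, -0.9, 0.1), 1, 3,
                dimnames = list(NULL, c("g1", "g2", "g3")))))
  rk <- rank_features(ms)
  expect_equal(rk$rank[match(c("g2", "g1", "g3"), rk$gene)], c(1L, 2L, 3L))
  # Cancelling weights average to zero and rank behind nonzero genes.
  ms2 <- fake_model_set(list(
    d1 = matrix(c(1, 0.2, -1, 0.2), 2, 2, byrow = TRUE,
                dimnames = list(NULL, c("g1", "g2")))))
  rk2 <- rank_features(ms2)
  expect_equal(rk2$weight[rk2$gene == "g1"], 0)
  expect_equal(rk2$rank[rk2$gene == "g1"], 2L)
  # All-zero weights still yield a deterministic permutation.
  ms3 <- fake_model_set(list(
    d1 = matrix(0, 1, 3, dimnames = list(NULL, c("gB", "gA", "gC")))))
  rk3 <- rank_features(ms3)
  expect_setequal(rk3$rank, 1:3)
  expect_equal(rk3$gene[order(rk3$rank)], c("gA", "gB", "gC"))
})

test_that("unique-gene percentage matches its definition and bounds", {
  expect_equal(unique_gene_percentage(list(paste0("a", 1:10),
                                           paste0("b", 1:10))), 100)
  expect_equal(unique_gene_percentage(list(paste0("a", 1:10),
                                           paste0("a", 1:10))), 50)
  sets3 <- list(paste0("g", 1:10), paste0("g", 6:15), paste0("g", 13:22))
  expect_equal(length(unique(unlist(sets3))), 22)
  # 3 drugs, union of 18 genes -> 60%.
  sets18 <- list(paste0("g", 1:10), paste0("g", 5:14), paste0("g", 9:18))
  expect_equal(unique_gene_percentage(sets18), 60)
  expect_error(unique_gene_percentage(list(paste0("g", 1:9))), "exactly 10")
  # Bounds hold on random set systems.
  set.seed(17)
  for (i in 1:25) {
    d <- sample(2:6, 1)
    sets <- replicate(d, sample(paste0("g", 1:30), 10), simplify = FALSE)
    pct <- unique_gene_percentage(sets)
    expect_gte(pct, 100 / d)
    expect_lte(pct, 100)
  }
})

test_that("recurrent features follow the inclusive 25% rule", {
  rk <- data.frame(
    drug_id = rep(paste0("d", 1:4), each = 12),
    modality = "zscore",
    gene = rep(paste0("g", 1:12), 4),
    weight = 0,
    rank = c(1:12, 1:12, 1:12, c(2:11, 1, 12)),
    stringsAsFactors = FALSE)
  rec <- recurrent_pathway_features(rk, paste0("d", 1:4), 0.25, k = 10)
  # g11 is top-10 in exactly 1 of 4 drugs: fraction 0.25, included.
  expect_true("g11" %in% rec$gene)
  expect_equal(rec$fraction[rec$gene == "g11"], 0.25)
  # g12 is never in a top-10: excluded.
  expect_false("g12" %in% rec$gene)
  expect_equal(rec$fraction[rec$gene == "g1"], 1)
})

test_that("stability classes partition the union of top-10 sets", {
  mk <- function(drug, genes) data.frame(
    drug_id = drug, modality = "x", gene = c(genes, paste0("pad", 1:5)),
    weight = 0, rank = seq_len(length(genes) + 5), stringsAsFactors = FALSE)
  same <- classify_feature_stability(mk("d1", paste0("g", 1:10)),
                                     mk("d1", paste0("g", 1:10)))
  expect_equal(sum(same$class == "retained"), 10)
  expect_equal(sum(same$class != "retained"), 0)
  disj <- classify_feature_stability(mk("d1", paste0("r", 1:10)),
                                     mk("d1", paste0("z", 1:10)))
  expect_equal(as.vector(table(disj$class)[c("dropped", "emerged")]),
               c(10L, 10L))
  # Drugs missing one modality are excluded and reported.
  mixed <- classify_feature_stability(
    rbind(mk("d1", paste0("g", 1:10)), mk("d2", paste0("g", 1:10))),
    mk("d1", paste0("g", 1:10)))
  expect_equal(attr(mixed, "excluded_drugs"), "d2")
  expect_setequal(unique(mixed$drug_id), "d1")
})

test_that("eta squared reproduces hand-computed sums of squares", {
  x <- c(0, 2, 4, 6)
  tiss <- c("a", "a", "b", "b")
  expect_equal(eta_squared(x, tiss), 0.8)          # SSb 16 / SSt 20
  expect_equal(eta_squared(c(1, 1, 5, 5), tiss), 1)
  expect_equal(eta_squared(c(1, 3, 1, 3), tiss), 0)
  expect_true(is.na(eta_squared(c(2, 2, 2, 2), tiss)))
  expect_error(eta_squared(x, rep("a", 4)), "at least 2 tissues")
  # Decomposition identity against an independent within-group computation.
  set.seed(18)
  for (i in 1:20) {
    v <- rnorm(30)
    g <- sample(letters[1:4], 30, replace = TRUE)
    ss_within <- sum(unlist(lapply(split(v, g), function(z)
      sum((z - mean(z))^2))))
    ss_total <- sum((v - mean(v))^2)
    expect_equal(eta_squared(v, g), 1 - ss_within / ss_total,
                 tolerance = 1e-10)
  }
})

test_that("delta rank differences and medians match a sort-based oracle", {
  mk <- function(mod, ranks) data.frame(
    drug_id = rep(paste0("d", 1:5), each = 2), modality = mod,
    gene = rep(c("gX", "gY"), 5), weight = 0, rank = ranks,
    stringsAsFactors = FALSE)
  raw <- mk("raw", c(100, 7, 50, 3, 80, 9, 60, 5, 70, 1))
  zsc <- mk("zscore", c(1, 7, 2, 4, 3, 6, 4, 8, 5, 2))
  dr <- delta_rank(raw, zsc)
  gX <- dr$values[dr$values$gene == "gX", ]
  expect_equal(gX$delta_rank, gX$rank_exp - gX$rank_zscore)
  expect_equal(dr$values$delta_rank[dr$values$gene == "gX" &
                                      dr$values$drug_id == "d1"], 99)
  med_oracle <- vapply(split(dr$values$delta_rank, dr$values$gene),
                       function(v) sort(v)[(length(v) + 1) / 2], numeric(1))
  expect_equal(dr$per_gene$median_delta_rank,
               unname(med_oracle[dr$per_gene$gene]))
})

test_that("pathway summaries combine uniqueness and recurrence", {
  rk <- data.frame(
    drug_id = rep(c("d1", "d2", "d3"), each = 12),
    modality = "zscore", gene = rep(paste0("g", 1:12), 3), weight = 0,
    rank = c(1:12, 1:12, 1:12), stringsAsFactors = FALSE)
  drugs <- data.frame(drug_id = c("d1", "d2", "d3"),
                      pathway = c("pwA", "pwA", "pwB"),
                      stringsAsFactors = FALSE)
  ps <- pathway_feature_summary(rk, drugs)
  expect_equal(ps$summary$unique_pct[ps$summary$pathway == "pwA"], 50)
  expect_equal(ps$summary$n_models, c(2L, 1L))
  expect_true(all(ps$recurrent$fraction[ps$recurrent$pathway == "pwA"] == 1))
})
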