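# Shared fixtures, all built in code.

# Four cell lines, two tissues, three genes, two drugs.
tiny_dataset <- function() {
  expr <- matrix(c(1, 2, 3, 4,
                   5, 5, 5, 5,
                   2, 1, 4, 3), nrow = 4,
                 dimnames = list(c("L1", "L2", "L3", "L4"),
                                 c("gA", "gB", "gC")))
  samples <- data.frame(cell_line_id = c("L1", "L2", "L3", "L4"),
                        cancer_type = c("t1", "t1", "t2", "t2"),
                        tumor_class = c("solid", "solid", "non_solid",
                                        "non_solid"),
                        stringsAsFactors = FALSE)
  response <- data.frame(
    cell_line_id = rep(c("L1", "L2", "L3", "L4"), 2),
    drug_id = rep(c("d1", "d2"), each = 4),
    auc = c(0.9, 0.8, 0.3, 0.2, 0.5, 0.6, 0.55, 0.45),
    stringsAsFactors = FALSE)
  drugs <- data.frame(drug_id = c("d1", "d2"),
                      pathway = c("pw1", "pw1"), stringsAsFactors = FALSE)
  screen_dataset(expr, samples, response, drugs)
}

# A screen small enough for fast fitting but with a biomarker strong enough
# (half the within-tissue response variance) that carrier drugs are
# detectably informative.
detectable_config <- function(seed = 1) {
  simulation_config(n_tissues = 6, lines_per_tissue = 20, n_genes = 60,
                    n_drugs = 10, non_solid_tissues = 2,
                    biomarkers = data.frame(pathway = "pathway1",
                                            gene = "gene0001", beta = 0.16,
                                            carrier_fraction = 1,
                                            stringsAsFactors = FALSE),
                    solid_shift = -0.1, response_noise_sd = 0.08,
                    drug_coverage = 1, seed = seed)
}

fast_spec <- function(repeats = 2, seed = 1) {
  model_spec(folds = 5, repeats = repeats, nlambda = 30, seed = seed)
}

# Minimal hand-rolled drug_model_set carrying only what rank_features needs.
fake_model_set <- function(coef_list, modality = "zscore") {
  drugs <- lapply(names(coef_list), function(d)
    list(drug_id = d, coefficients = coef_list[[d]]))
  names(drugs) <- names(coef_list)
  structure(list(drugs = drugs, modality = modality,
                 features = colnames(coef_list[[1]]),
                 skipped = data.frame()),
            class = "drug_model_set")
}

# Independent high-precision evaluation of the tissue-weighted Pearson
# formula, written from the definition (not shared with the implementation).
wp_oracle <- function(r, n) {
  keep <- !is.na(r) & n >= 3
  r <- r[keep]; n <- n[keep]
  if (!length(r)) return(NA_real_)
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  z <- 0.5 * log((1 + r) / (1 - r))
  zbar <- sum((n - 1) * z) / sum(n - 1)
  (exp(2 * zbar) - 1) / (exp(2 * zbar) + 1)
}

# Independent brute-force running-sum ES (second implementation).
es_oracle <- function(weights, ids, set, exponent = 1) {
  ord <- order(-weights, ids)
  w <- weights[ord]; id <- ids[ord]
  s <- 0; mx <- 0; mn <- 0
  m <- sum(id %in% set)
  tot <- sum(abs(w[id %in% set])^exponent)
  for (i in seq_along(w)) {
    if (id[i] %in% set) {
      s <- s + if (tot > 0) unname(abs(w[i]))^exponent / tot else 1 / m
    } else {
      s <- s - 1 / (length(w) - m)
    }
    mx <- max(mx, s); mn <- min(mn, s)
  }
  # Same near-tie rule as the implementation: positive extremum wins ties.
  if (abs(mx) >= abs(mn) - 1e-12) mx else mn
}
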