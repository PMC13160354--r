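test_that("weighted Pearson matches its defining identities", {
  expect_equal(weighted_pearson(0.5, 10), 0.5)
  expect_equal(weighted_pearson(rep(0.3, 3), c(5, 9, 4)), 0.3)
  expect_equal(weighted_pearson(c(0, 0.8), c(3, 5)),
               tanh((2 * 0 + 4 * atanh(0.8)) / 6))
  expect_equal(round(weighted_pearson(c(0, 0.8), c(3, 5)), 4), 0.6245)
  # Tissues under the n_i >= 3 rule and undefined correlations are excluded.
  expect_equal(weighted_pearson(c(0.9, 0.2), c(2, 10)), 0.2)
  expect_equal(weighted_pearson(c(NA, 0.2), c(8, 10)), 0.2)
  expect_true(is.na(weighted_pearson(c(NA, 0.5), c(10, 2))))
  # Perfect correlations are clamped, not infinite.
  expect_lt(weighted_pearson(c(1, 0), c(5, 5)), 1)
})

test_that("weighted Pearson is monotone in each per-tissue correlation", {
  set.seed(10)
  for (i in 1:100) {
    k <- sample(2:8, 1)
    r <- runif(k, -0.9, 0.9)
    n <- sample(3:30, k, replace = TRUE)
    j <- sample(k, 1)
    r2 <- r
    r2[j] <- r[j] + 0.05
    expect_gte(weighted_pearson(r2, n), weighted_pearson(r, n))
  }
})

test_that("ridge at vanishing penalty matches the normal-equations solution", {
  set.seed(11)
  X <- matrix(rnorm(50 * 10), 50, 10,
              dimnames = list(paste0("s", 1:50), paste0("g", 1:10)))
  beta <- rnorm(10)
  y <- as.vector(X %*% beta) + rnorm(50, sd = 0.3)
  spec <- model_spec(folds = 5, repeats = 1, lambda = 1e-10, seed = 1)
  fit <- fit_drug_model_run(X, y, spec, run_seed = 3)
  # Oracle: OLS on standardized predictors, centered response.
  Xs <- scale(X)
  yc <- y - mean(y)
  b_ols <- solve(crossprod(Xs), crossprod(Xs, yc))
  expect_lt(max(abs(fit$coefficients - as.vector(b_ols))), 1e-6)
})

test_that("the SVD ridge path agrees with glmnet at matched penalties", {
  set.seed(12)
  X <- matrix(rnorm(60 * 25), 60, 25)
  y <- rnorm(60)
  Xs <- scale(X) * sqrt(60 / 59)  # glmnet's 1/n standardization
  yc <- y - mean(y)
  lam <- c(5, 1, 0.5)
  B <- panscreen:::fit_penalized_path(Xs, yc, lam, alpha = 0)
  # Exact oracle: ridge normal equations (X'X/n + lambda I) b = X'y/n.
  for (j in seq_along(lam)) {
    b_ne <- solve(crossprod(Xs) / 60 + diag(lam[j], 25),
                  crossprod(Xs, yc) / 60)
    expect_lt(max(abs(B[, j] - as.vector(b_ne))), 1e-8)
  }
  # glmnet agrees up to its coordinate-descent convergence tolerance.
  g <- glmnet::glmnet(Xs, yc, alpha = 0, lambda = lam, standardize = FALSE,
                      intercept = FALSE, thresh = 1e-14)
  expect_lt(max(abs(B - as.matrix(coef(g))[-1, ])), 5e-3)
})

test_that("degenerate and undersized inputs are handled per contract", {
  X <- matrix(rnorm(40), 20, 2, dimnames = list(paste0("s", 1:20), c("a", "b")))
  fit <- fit_drug_model_run(X, rep(0.5, 20), model_spec(folds = 5, repeats = 1))
  expect_true(fit$degenerate)
  expect_true(all(fit$coefficients == 0))
  expect_true(all(fit$predictions == 0.5))
  expect_error(fit_drug_model_run(X[1:4, ], rnorm(4),
                                  model_spec(folds = 5, repeats = 1)),
               "at least 5 observations")
})

test_that("a single strong predictor gets the largest coefficient", {
  set.seed(13)
  X <- matrix(rnorm(80 * 20), 80, 20,
              dimnames = list(paste0("s", 1:80), paste0("g", 1:20)))
  y <- -1.5 * X[, 7] + rnorm(80, sd = 0.3)
  fit <- fit_drug_model_run(X, y, model_spec(folds = 5, repeats = 1), 5)
  expect_equal(which.max(abs(fit$coefficients)), c(g7 = 7L))
  # Univariate correlation screen picks the same gene.
  expect_equal(which.max(abs(cor(X, y))), 7L)
})

test_that("model runs are deterministic in the run seed", {
  set.seed(14)
  X <- matrix(rnorm(50 * 8), 50, 8,
              dimnames = list(paste0("s", 1:50), paste0("g", 1:8)))
  y <- rnorm(50)
  spec <- model_spec(folds = 5, repeats = 1)
  f1 <- fit_drug_model_run(X, y, spec, run_seed = 77)
  f2 <- fit_drug_model_run(X, y, spec, run_seed = 77)
  expect_identical(f1, f2)
  f3 <- fit_drug_model_run(X, y, spec, run_seed = 78)
  expect_false(identical(f1$foldid, f3$foldid))
})

test_that("performance summaries behave at the extremes and match hand arithmetic", {
  y <- c(1, 2, 3, 4, 5, 6, 2, 4, 6, 8, 10)
  tis <- rep(c("a", "b"), c(6, 5))
  pt <- panscreen:::per_tissue_correlations(y, y + rnorm(11, sd = 1e-8), tis)
  expect_equal(weighted_pearson(pt$r, pt$n), 1, tolerance = 1e-6)
  pt2 <- panscreen:::per_tissue_correlations(y, -y, tis)
  expect_equal(weighted_pearson(pt2$r, pt2$n), -1, tolerance = 1e-9)
  # Hand-built toy: per-tissue r computed independently with cor().
  set.seed(15)
  yh <- y + rnorm(11, sd = 2)
  pt3 <- panscreen:::per_tissue_correlations(y, yh, tis)
  r_a <- cor(y[1:6], yh[1:6]); r_b <- cor(y[7:11], yh[7:11])
  manual <- tanh((5 * atanh(r_a) + 4 * atanh(r_b)) / 9)
  expect_equal(weighted_pearson(pt3$r, pt3$n), manual)
})

test_that("fitting a screen yields coherent models, methods and summaries", {
  sim <- simulate_screen(detectable_config(seed = 3))
  ds <- apply_qc_filters(sim$dataset)$dataset
  ms <- fit_drug_models(ds, "zscore", fast_spec(repeats = 2, seed = 2))
  expect_s3_class(ms, "drug_model_set")
  expect_equal(length(ms$drugs), 10)
  W <- coef(ms)
  expect_equal(dim(W), c(10, 60))
  perf <- summary(ms)
  expect_true(all(perf$p_w >= -1 & perf$p_w <= 1, na.rm = TRUE))
  # Out-of-fold predictions cover exactly the screened lines per drug.
  d1 <- ms$drugs[["drug001"]]
  expect_setequal(colnames(d1$predictions),
                  ds$response$cell_line_id[ds$response$drug_id == "drug001" &
                                             !is.na(ds$response$auc)])
  pr <- predict(ms, modality_matrix(ds, "zscore"), drugs = "drug001")
  expect_equal(dim(pr), c(nrow(ds$expression), 1))
})

test_that("corrected expression beats tissue labels where signal is within-tissue", {
  sim <- simulate_screen(detectable_config(seed = 4))
  ds <- apply_qc_filters(sim$dataset)$dataset
  spec <- fast_spec(repeats = 2, seed = 5)
  pz <- summarize_performance(fit_drug_models(ds, "zscore", spec))
  ptl <- summarize_performance(fit_drug_models(ds, "tissue_labels", spec))
  carriers <- sim$truth$drugs$drug_id[sim$truth$drugs$carrier]
  expect_gt(mean(pz$p_w[pz$drug_id %in% carriers]),
            mean(ptl$p_w[ptl$drug_id %in% carriers], na.rm = TRUE))
  # Tissue labels carry no within-tissue information, so their weighted
  # Pearson never rises above noise (it is mildly negative at small tissue
  # sizes: the cross-validated group-mean estimate excludes the held-out
  # line, anti-correlating with it).
  expect_lt(mean(ptl$p_w, na.rm = TRUE), 0.05)
})
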