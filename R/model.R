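#' Model specification for per-drug penalized regression
#'
#' @param alpha Elastic-net mixing parameter in `[0, 1]`: 0 = ridge
#'   (the default modality model), 1 = lasso; the comparison grid used for
#'   elastic net is `{0.2, 0.4, 0.5, 0.6, 0.8}`.
#' @param folds Cross-validation folds (default 10).
#' @param repeats Independent repetitions of the cross-validation (default
#'   10); each repeat redraws the fold assignment from a derived seed.
#' @param nlambda Size of the log-spaced penalty-strength grid.
#' @param lambda Optional explicit penalty grid (overrides `nlambda`).
#' @param lambda_min_ratio Smallest grid value as a fraction of the largest.
#' @param seed Base seed; per-(drug, run) seeds are derived from it.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(alpha = 0, folds = 10, repeats = 10, nlambda = 50,
                       lambda = NULL, lambda_min_ratio = 1e-4, seed = 1) {
  stopifnot(alpha >= 0, alpha <= 1, folds >= 2, repeats >= 1)
  if (!is.null(lambda) && length(lambda) == 0L) stop("lambda grid is empty")
  structure(list(alpha = alpha, folds = folds, repeats = repeats,
                 nlambda = nlambda, lambda = lambda,
                 lambda_min_ratio = lambda_min_ratio, seed = seed),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model_spec: alpha=%g (%s), %d-fold CV x %d repeats, %s penalty grid, seed %d\n",
              x$alpha, if (x$alpha == 0) "ridge" else if (x$alpha == 1) "lasso"
              else "elastic net", x$folds, x$repeats,
              if (is.null(x$lambda)) sprintf("%d-point", x$nlambda)
              else "user-supplied", x$seed))
  invisible(x)
}

# glmnet-convention grid: lambda_max = max |x_j' y| / (n * max(alpha, 1e-3)).
lambda_grid <- function(Xs, yc, spec) {
  if (!is.null(spec$lambda)) return(sort(spec$lambda, decreasing = TRUE))
  lmax <- max(abs(crossprod(Xs, yc))) / (length(yc) * max(spec$alpha, 1e-3))
  if (!is.finite(lmax) || lmax <= 0) lmax <- 1
  exp(seq(log(lmax), log(lmax * spec$lambda_min_ratio),
          length.out = spec$nlambda))
}

# Penalized coefficient path on pre-standardized predictors and centered
# response; returns a p x length(lambda) matrix. Ridge (alpha = 0) is solved
# exactly in closed form via SVD for the objective
# 1/(2n) ||yc - X b||^2 + lambda/2 ||b||^2; alpha > 0 delegates to glmnet.
fit_penalized_path <- function(Xs, yc, lambda, alpha) {
  n <- length(yc)
  if (alpha == 0) {
    s <- svd(Xs)
    keep <- s$d > max(s$d[1], 1) * 1e-12
    d <- s$d[keep]
    uty <- as.vector(crossprod(s$u[, keep, drop = FALSE], yc))
    num <- matrix(uty * d, length(d), length(lambda))
    B <- s$v[, keep, drop = FALSE] %*% (num / outer(d^2, lambda * n, "+"))
  } else {
    fit <- glmnet::glmnet(Xs, yc, alpha = alpha,
                          lambda = sort(lambda, decreasing = TRUE),
                          standardize = FALSE, intercept = FALSE,
                          thresh = 1e-10)
    B <- as.matrix(coef(fit))[-1L, , drop = FALSE]
    # glmnet may drop grid points; align back to the requested lambda.
    B <- B[, match(signif(sort(lambda, decreasing = TRUE), 10),
                   signif(fit$lambda, 10)), drop = FALSE]
    B[is.na(B)] <- 0
    B <- B[, match(lambda, sort(lambda, decreasing = TRUE)), drop = FALSE]
    return(B)
  }
  B
}

# Per-(tissue, gene) stats of a training block, with global column
# fallbacks for tissues unseen in training.
group_stats <- function(X, f) {
  f <- factor(f)
  n_i <- as.vector(table(f))
  mu <- rowsum(X, f) / n_i
  ss <- rowsum(X^2, f) - n_i * mu^2
  ss[ss < 0] <- 0
  sigma <- sqrt(sweep(ss, 1L, pmax(n_i - 1L, 1L), "/"))
  degen <- sigma == 0 | n_i < 2L
  gmu <- colMeans(X)
  gsd <- sqrt(colSums(sweep(X, 2L, gmu, "-")^2) / max(1, nrow(X) - 1L))
  gsd[gsd == 0] <- 1
  list(mu = mu, sigma = sigma, degenerate = degen,
       levels = levels(f), global_mu = gmu, global_sd = gsd)
}

# Apply a tissue correction estimated elsewhere to new rows.
apply_group_correction <- function(X, tissues, stats, method) {
  idx <- match(as.character(tissues), stats$levels)
  out <- X
  known <- !is.na(idx)
  if (any(known)) {
    mu <- stats$mu[idx[known], , drop = FALSE]
    if (method == "zscore") {
      sig <- stats$sigma[idx[known], , drop = FALSE]
      deg <- stats$degenerate[idx[known], , drop = FALSE]
      z <- (X[known, , drop = FALSE] - mu)
      z <- ifelse(deg | sig == 0, 0, z / sig)
      out[known, ] <- z
    } else {
      out[known, ] <- X[known, , drop = FALSE] - mu
    }
  }
  if (any(!known)) {
    Xc <- sweep(X[!known, , drop = FALSE], 2L, stats$global_mu, "-")
    if (method == "zscore") Xc <- sweep(Xc, 2L, stats$global_sd, "/")
    out[!known, ] <- Xc
  }
  out
}

#' Fit a single cross-validated penalized model run
#'
#' One repetition of the repeated-CV protocol for one drug: the fold
#' assignment is drawn from `run_seed`; each training fold is standardized
#' (sample-SD columns) and a penalized path fitted over a shared log-spaced
#' grid; the penalty is chosen by minimizing the pooled cross-validated
#' squared error; out-of-fold predictions are assembled at the chosen
#' penalty; and the reported coefficients come from a final fit on all
#' samples at that penalty, on standardized predictors (so absolute
#' coefficients are comparable across genes).
#'
#' When a tissue `correction` is requested, the per-(tissue, gene)
#' correction statistics are estimated on each training fold only and
#' applied to the held-out fold, so no information about a held-out sample
#' leaks into its prediction through the within-tissue standardization
#' constraint; the final full-sample refit uses full-sample statistics.
#' Held-out samples from tissues unseen in a training fold fall back to the
#' training block's global column statistics.
#'
#' @param X Numeric design matrix (no missing values), rows aligned to `y`.
#'   With a `correction`, this is the *uncorrected* expression block.
#' @param y Response (AUC) vector.
#' @param spec A [model_spec()].
#' @param run_seed Integer seed for the fold draw.
#' @param groups Tissue label per row (required for a correction).
#' @param correction `"none"` (default), `"zscore"` or `"residual"`.
#' @return List: `coefficients` (named, standardized scale), `intercept`,
#'   `lambda` (chosen penalty), `predictions` (out-of-fold, named by row),
#'   `center`, `scale` (full-data standardization), `foldid`, `degenerate`.
#'   A constant `y` yields the degenerate result (all-zero coefficients,
#'   mean predictions).
#' @export
fit_drug_model_run <- function(X, y, spec = model_spec(), run_seed = 1L,
                               groups = NULL,
                               correction = c("none", "zscore", "residual")) {
  correction <- match.arg(correction)
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (anyNA(X)) stop("design matrix contains missing values")
  if (anyNA(y)) stop("response contains missing values")
  if (correction != "none" && is.null(groups))
    stop("`groups` is required for a tissue correction")
  n <- length(y)
  if (n < spec$folds)
    stop(sprintf("need at least %d observations for %d-fold CV, got %d",
                 spec$folds, spec$folds, n))
  rn <- rownames(X) %||% as.character(seq_len(n))
  correct_block <- function(Xfit, tr_groups, Xnew, new_groups) {
    if (correction == "none") return(list(fit = Xfit, new = Xnew))
    gs <- group_stats(Xfit, tr_groups)
    list(fit = apply_group_correction(Xfit, tr_groups, gs, correction),
         new = if (is.null(Xnew)) NULL else
           apply_group_correction(Xnew, new_groups, gs, correction))
  }
  full <- correct_block(X, groups, NULL, NULL)$fit
  std <- standardize_columns(full)
  if (var(y) == 0) {
    return(list(coefficients = setNames(numeric(ncol(X)), colnames(X)),
                intercept = y[1], lambda = NA_real_,
                predictions = setNames(rep(y[1], n), rn),
                center = std$center, scale = std$scale,
                foldid = rep(NA_integer_, n), degenerate = TRUE))
  }
  yc <- y - mean(y)
  grid <- lambda_grid(std$x, yc, spec)
  foldid <- with_seed(run_seed, sample(rep(seq_len(spec$folds), length.out = n)))
  pred <- matrix(NA_real_, n, length(grid))
  for (k in seq_len(spec$folds)) {
    tr <- foldid != k
    cb <- correct_block(X[tr, , drop = FALSE], groups[tr],
                        X[!tr, , drop = FALSE], groups[!tr])
    st <- standardize_columns(cb$fit)
    B <- fit_penalized_path(st$x, y[tr] - mean(y[tr]), grid, spec$alpha)
    Xte <- standardize_columns(cb$new, center = st$center,
                               scale = st$scale)$x
    # Out-of-fold predictions carry the drug-level mean as intercept, not
    # the fold-training mean: standardized predictors are orthogonal to
    # the intercept, so the coefficient path is identical either way, and
    # a fold-varying constant only injects a spurious negative component
    # into correlation-based evaluation.
    pred[!tr, ] <- mean(y) + Xte %*% B
  }
  cv_err <- colMeans((pred - y)^2)
  best <- which.min(cv_err)
  Bfull <- fit_penalized_path(std$x, yc, grid[best], spec$alpha)
  list(coefficients = setNames(as.vector(Bfull), colnames(X)),
       intercept = mean(y), lambda = grid[best],
       predictions = setNames(pred[, best], rn),
       center = std$center, scale = std$scale,
       foldid = foldid, degenerate = FALSE)
}

#' Tissue-weighted Pearson correlation
#'
#' Aggregates per-tissue prediction-observation correlations into one
#' pan-cancer performance number via the Fisher-z weighted mean:
#' `p_w = tanh( sum_i (n_i - 1) atanh(p_i) / sum_i (n_i - 1) )`.
#' Only tissues with at least `min_n` treated cell lines contribute;
#' undefined correlations (`NA`, e.g. constant predictions within a tissue)
#' are excluded; `p_i = +/-1` is clamped to `+/-(1 - 1e-12)`. Weighting by
#' `n_i - 1` makes a single-tissue input return exactly that tissue's
#' correlation.
#'
#' @param r Per-tissue Pearson correlations.
#' @param n Per-tissue sample counts, aligned to `r`.
#' @param min_n Minimum lines per tissue (default 3).
#' @return The weighted correlation, or `NA` if no tissue survives.
#' @export
weighted_pearson <- function(r, n, min_n = 3) {
  if (is.data.frame(r)) { n <- r$n; r <- r$r }
  stopifnot(length(r) == length(n))
  keep <- !is.na(r) & n >= min_n
  r <- clamp_cor(r[keep]); n <- n[keep]
  if (length(r) == 0L) return(NA_real_)
  w <- n - 1
  tanh(sum(w * atanh(r)) / sum(w))
}

# Per-tissue prediction-observation Pearson correlations.
per_tissue_correlations <- function(y, yhat, tissues) {
  f <- factor(tissues)
  res <- lapply(levels(f), function(t) {
    idx <- f == t
    ni <- sum(idx)
    r <- if (ni >= 2 && sd(y[idx]) > 0 && sd(yhat[idx]) > 0)
      cor(y[idx], yhat[idx]) else NA_real_
    data.frame(tissue = t, n = ni, r = r, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Prepare the design matrix for a modality
#'
#' `raw` is the uncorrected expression matrix; `zscore` and `residual` are
#' the tissue corrections of [zscore_by_tissue()] and [residual_correct()];
#' `tissue_labels` is the naive baseline using one-hot cancer-type
#' indicators as the only predictors.
#'
#' @param ds A `screen_dataset`.
#' @param modality One of `"raw"`, `"zscore"`, `"residual"`,
#'   `"tissue_labels"`.
#' @return Numeric matrix with cell lines in rows.
#' @export
modality_matrix <- function(ds, modality = c("raw", "zscore", "residual",
                                             "tissue_labels")) {
  modality <- match.arg(modality)
  tiss <- tissue_map(ds)
  switch(modality,
    raw = ds$expression,
    zscore = zscore_by_tissue(ds$expression, tiss)$values,
    residual = residual_correct(ds$expression, tiss)$values,
    tissue_labels = {
      f <- factor(tiss[rownames(ds$expression)])
      m <- model.matrix(~ 0 + f)
      dimnames(m) <- list(rownames(ds$expression),
                          paste0("tissue_", levels(f)))
      m
    })
}

#' Fit per-drug penalized models under repeated cross-validation
#'
#' The central fitting function. For each drug, restricts to cell lines with
#' an observed AUC, runs `spec$repeats` independent cross-validation runs
#' (distinct derived fold seeds), and records per-run coefficients,
#' out-of-fold predictions, and both unweighted and tissue-weighted Pearson
#' performance. Drugs with fewer usable lines than CV folds are skipped with
#' a logged reason.
#'
#' For the `zscore` and `residual` modalities the tissue correction is
#' estimated inside each training fold and applied to the held-out fold
#' (see [fit_drug_model_run()]); the raw expression matrix is the input.
#' Supplying `x` disables the internal correction and fits the given
#' matrix as-is.
#'
#' @param ds A `screen_dataset` (post-QC).
#' @param modality Input modality, see [modality_matrix()].
#' @param spec A [model_spec()].
#' @param x Optional precomputed design matrix (rows named by cell line),
#'   fitted without internal correction.
#' @return Object of class `drug_model_set` with methods [print()],
#'   [summary()] (= [summarize_performance()]), [coef()] (run-averaged
#'   weights, drugs x features) and [predict()].
#' @export
fit_drug_models <- function(ds, modality = "zscore", spec = model_spec(),
                            x = NULL) {
  stopifnot(inherits(ds, "screen_dataset"), inherits(spec, "model_spec"))
  correction <- "none"
  if (is.null(x)) {
    if (modality %in% c("zscore", "residual")) {
      x <- ds$expression
      correction <- modality
    } else {
      x <- modality_matrix(ds, modality)
    }
  }
  tiss <- tissue_map(ds)
  usable <- ds$response[!is.na(ds$response$auc), , drop = FALSE]
  drug_ids <- unique(ds$response$drug_id)
  results <- list()
  skipped <- data.frame(drug_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  for (di in seq_along(drug_ids)) {
    d <- drug_ids[di]
    rows <- usable[usable$drug_id == d, , drop = FALSE]
    rows <- rows[rows$cell_line_id %in% rownames(x), , drop = FALSE]
    if (nrow(rows) < spec$folds) {
      skipped <- rbind(skipped, data.frame(
        drug_id = d,
        reason = sprintf("only %d usable lines (< %d folds)", nrow(rows),
                         spec$folds), stringsAsFactors = FALSE))
      next
    }
    Xd <- x[rows$cell_line_id, , drop = FALSE]
    y <- setNames(rows$auc, rows$cell_line_id)
    td <- tiss[rows$cell_line_id]
    coefs <- matrix(NA_real_, spec$repeats, ncol(x),
                    dimnames = list(NULL, colnames(x)))
    preds <- matrix(NA_real_, spec$repeats, nrow(rows),
                    dimnames = list(NULL, rows$cell_line_id))
    perf <- data.frame(run = seq_len(spec$repeats), pearson = NA_real_,
                       weighted_pearson = NA_real_, n_tissues = NA_integer_,
                       lambda = NA_real_)
    intercepts <- numeric(spec$repeats)
    center <- scale <- NULL
    for (r in seq_len(spec$repeats)) {
      fit <- fit_drug_model_run(Xd, y, spec,
                                run_seed = derive_seed(spec$seed, di, r),
                                groups = td, correction = correction)
      coefs[r, ] <- fit$coefficients
      preds[r, ] <- fit$predictions
      intercepts[r] <- fit$intercept
      center <- fit$center; scale <- fit$scale
      perf$lambda[r] <- fit$lambda
      if (!fit$degenerate && sd(fit$predictions) > 0) {
        perf$pearson[r] <- cor(y, fit$predictions)
        pt <- per_tissue_correlations(y, fit$predictions, td)
        perf$weighted_pearson[r] <- weighted_pearson(pt$r, pt$n)
        perf$n_tissues[r] <- sum(!is.na(pt$r) & pt$n >= 3)
      }
    }
    results[[d]] <- list(drug_id = d, coefficients = coefs,
                         predictions = preds, observed = y, tissues = td,
                         performance = perf, intercepts = intercepts,
                         center = center, scale = scale, n = nrow(rows))
  }
  structure(list(drugs = results, modality = modality, spec = spec,
                 features = colnames(x), skipped = skipped),
            class = "drug_model_set")
}

#' @export
print.drug_model_set <- function(x, ...) {
  perf <- summarize_performance(x)
  cat(sprintf("drug_model_set: %d drug models (%s modality), %d features, %d repeats\n",
              length(x$drugs), x$modality, length(x$features),
              x$spec$repeats))
  if (nrow(x$skipped))
    cat(sprintf("  %d drug(s) skipped\n", nrow(x$skipped)))
  if (nrow(perf))
    cat(sprintf("  mean Pearson %.3f, mean weighted Pearson %.3f\n",
                mean(perf$p, na.rm = TRUE), mean(perf$p_w, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.drug_model_set <- function(object, ...) {
  summarize_performance(object)
}

#' @export
coef.drug_model_set <- function(object, ...) {
  t(vapply(object$drugs, function(d) colMeans(d$coefficients),
           numeric(length(object$features))))
}

#' Predict drug response for new samples
#'
#' Applies the run-averaged standardized-scale coefficients of each fitted
#' drug model. `newdata` must live in the same modality space the models
#' were fitted in (e.g. z-score corrected expression for `zscore` models).
#'
#' @param object A `drug_model_set`.
#' @param newdata Numeric matrix, samples x features (same columns as used
#'   in fitting).
#' @param drugs Optional subset of drug ids.
#' @param ... Unused.
#' @return Matrix of predicted AUC, samples x drugs.
#' @export
predict.drug_model_set <- function(object, newdata, drugs = NULL, ...) {
  stopifnot(is.matrix(newdata))
  if (!all(object$features %in% colnames(newdata)))
    stop("newdata is missing model features")
  newdata <- newdata[, object$features, drop = FALSE]
  ids <- drugs %||% names(object$drugs)
  out <- vapply(ids, function(d) {
    m <- object$drugs[[d]]
    xs <- standardize_columns(newdata, center = m$center, scale = m$scale)$x
    as.vector(mean(m$intercepts) + xs %*% colMeans(m$coefficients))
  }, numeric(nrow(newdata)))
  matrix(out, nrow = nrow(newdata),
         dimnames = list(rownames(newdata), ids))
}

#' Summarize model performance per drug and modality
#'
#' Per run, the unweighted Pearson correlation over all out-of-fold pairs
#' and the tissue-weighted Pearson ([weighted_pearson()]) are computed at
#' fitting time; this aggregates them across repeats via the Fisher-z mean
#' and emits one row per (drug, modality).
#'
#' @param results A `drug_model_set` or a list of them (e.g. one per
#'   modality).
#' @return Data frame `(drug_id, modality, p, p_w, n, n_tissues)`.
#' @export
summarize_performance <- function(results) {
  if (inherits(results, "drug_model_set")) results <- list(results)
  rows <- lapply(results, function(ms) {
    if (length(ms$drugs) == 0L)
      return(data.frame(drug_id = character(), modality = character(),
                        p = numeric(), p_w = numeric(), n = integer(),
                        n_tissues = integer(), stringsAsFactors = FALSE))
    do.call(rbind, lapply(ms$drugs, function(d) {
      data.frame(drug_id = d$drug_id, modality = ms$modality,
                 p = fisher_mean(d$performance$pearson),
                 p_w = fisher_mean(d$performance$weighted_pearson),
                 n = d$n,
                 n_tissues = as.integer(round(median(d$performance$n_tissues,
                                                     na.rm = TRUE))),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
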