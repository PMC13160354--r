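#' Shuffle a drug-response vector
#'
#' Uniform random permutation of the AUC values across the same cell lines;
#' the multiset of values (and any names) is preserved, only the assignment
#' to lines is broken. Used to build shuffled-response null models.
#'
#' @param y Response vector (optionally named by cell line).
#' @param seed Integer seed.
#' @return Permuted vector with the original names.
#' @export
shuffle_response <- function(y, seed = 1L) {
  if (length(y) == 0L) stop("response vector is empty")
  perm <- with_seed(seed, sample.int(length(y)))
  out <- y[perm]
  names(out) <- names(y)
  out
}

#' Build the shuffled-response null distribution
#'
#' For each drug, the full cross-validation pipeline is refitted `n_nulls`
#' times on independently shuffled responses (one CV run each) and the
#' tissue-weighted Pearson recorded. The pooled distribution is formed from
#' the per-drug null means (Fisher-z mean of the per-null values), from
#' which the informative-model threshold is derived.
#'
#' @param ds A `screen_dataset`.
#' @param modality Input modality, see [modality_matrix()].
#' @param spec A [model_spec()]; `folds` and penalty settings match the real
#'   models, each null is fitted with a single run.
#' @param n_nulls Null matrices per drug (default 10).
#' @param x Optional precomputed modality matrix.
#' @return Object of class `null_distribution`: per-drug null values, the
#'   pooled vector of per-drug means, its mean `m0` and SD `s0`.
#' @export
build_null_distribution <- function(ds, modality = "zscore",
                                    spec = model_spec(), n_nulls = 10,
                                    x = NULL) {
  stopifnot(n_nulls >= 1)
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
  per_drug <- list()
  for (di in seq_along(drug_ids)) {
    d <- drug_ids[di]
    rows <- usable[usable$drug_id == d, , drop = FALSE]
    rows <- rows[rows$cell_line_id %in% rownames(x), , drop = FALSE]
    if (nrow(rows) < spec$folds) next
    Xd <- x[rows$cell_line_id, , drop = FALSE]
    y <- setNames(rows$auc, rows$cell_line_id)
    td <- tiss[rows$cell_line_id]
    vals <- vapply(seq_len(n_nulls), function(k) {
      yk <- shuffle_response(y, seed = derive_seed(spec$seed, 1000L + di, k))
      fit <- fit_drug_model_run(Xd, yk, spec,
                                run_seed = derive_seed(spec$seed, 2000L + di, k),
                                groups = td, correction = correction)
      if (fit$degenerate || sd(fit$predictions) == 0) return(NA_real_)
      pt <- per_tissue_correlations(yk, fit$predictions, td)
      weighted_pearson(pt$r, pt$n)
    }, numeric(1))
    per_drug[[d]] <- vals
  }
  pooled <- vapply(per_drug, fisher_mean, numeric(1))
  pooled <- pooled[!is.na(pooled)]
  structure(list(modality = modality, n_nulls = n_nulls,
                 per_drug = per_drug, pooled = pooled,
                 m0 = mean(pooled), s0 = sd(pooled)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("null_distribution (%s): %d drugs x %d nulls; pooled mean %.4f, sd %.4f\n",
              x$modality, length(x$per_drug), x$n_nulls, x$m0, x$s0))
  invisible(x)
}

#' Informative-model performance threshold
#'
#' `theta = m0 + 3 * s0`, where `m0` is the mean of the pooled per-drug null
#' means and `s0` is their standard deviation (`spread = "sd"`, the default)
#' or standard error (`spread = "sem"`). A conservative criterion under a
#' normal approximation of the null performance distribution.
#'
#' @param nd A `null_distribution`.
#' @param spread `"sd"` or `"sem"`.
#' @return The threshold `theta`.
#' @export
informative_threshold <- function(nd, spread = c("sd", "sem")) {
  spread <- match.arg(spread)
  pooled <- nd$pooled
  if (length(pooled) < 2L)
    stop("pooled null distribution has fewer than 2 values")
  s <- sd(pooled)
  if (spread == "sem") s <- s / sqrt(length(pooled))
  mean(pooled) + 3 * s
}

#' Select informative drug models
#'
#' A drug is informative in a modality iff its mean weighted Pearson
#' strictly exceeds that modality's null threshold; the overall flag is the
#' union (logical OR) over the supplied modalities. Drugs with missing
#' performance in a modality get `NA` there and are excluded from the union
#' only if missing everywhere.
#'
#' @param perf Performance table from [summarize_performance()].
#' @param nulls Named list of `null_distribution` objects, one per modality.
#' @param spread Threshold spread policy, see [informative_threshold()].
#' @param drugs Optional drug annotation data frame `(drug_id, pathway)` to
#'   carry through.
#' @return Object of class `informative_selection`: a data frame with one
#'   row per drug, per-modality flags, the overall `informative` flag and
#'   (if supplied) the pathway; thresholds attached as attribute
#'   `"thresholds"`.
#' @export
select_informative_models <- function(perf, nulls, spread = "sd",
                                      drugs = NULL) {
  stopifnot(is.list(nulls), length(nulls) > 0)
  mods <- names(nulls)
  theta <- vapply(nulls, informative_threshold, numeric(1), spread = spread)
  drug_ids <- unique(perf$drug_id)
  out <- data.frame(drug_id = drug_ids, stringsAsFactors = FALSE)
  for (m in mods) {
    pm <- perf[perf$modality == m, , drop = FALSE]
    pw <- pm$p_w[match(drug_ids, pm$drug_id)]
    out[[paste0("informative_", m)]] <- ifelse(is.na(pw), NA, pw > theta[[m]])
  }
  flags <- as.matrix(out[, paste0("informative_", mods), drop = FALSE])
  out$informative <- apply(flags, 1L, function(z) {
    if (all(is.na(z))) NA else any(z, na.rm = TRUE)
  })
  if (!is.null(drugs))
    out$pathway <- drugs$pathway[match(out$drug_id, drugs$drug_id)]
  attr(out, "thresholds") <- data.frame(
    modality = mods, m0 = vapply(nulls, `[[`, numeric(1), "m0"),
    s0 = vapply(nulls, `[[`, numeric(1), "s0"),
    policy = spread, theta = unname(theta), stringsAsFactors = FALSE)
  class(out) <- c("informative_selection", "data.frame")
  out
}

#' @export
print.informative_selection <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat(sprintf("informative_selection: %d of %d drugs informative overall\n",
              sum(x$informative, na.rm = TRUE), nrow(x)))
  for (i in seq_len(nrow(th)))
    cat(sprintf("  %s: theta = %.4f (m0 %.4f, s0 %.4f, %s), %d informative\n",
                th$modality[i], th$theta[i], th$m0[i], th$s0[i], th$policy[i],
                sum(x[[paste0("informative_", th$modality[i])]], na.rm = TRUE)))
  invisible(x)
}
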