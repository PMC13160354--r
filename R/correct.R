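#' Tissue-corrected expression matrices
#'
#' Two corrections are provided for removing tissue-of-origin structure from
#' a cell line x gene expression matrix before pan-cancer modelling:
#' within-tissue z-scoring ([zscore_by_tissue()]) and residualization on
#' tissue labels ([residual_correct()]). Both return a `corrected_matrix`
#' holding the corrected values plus the per-stratum statistics used to
#' produce them, with shape and dimnames identical to the input.
#'
#' @name correct
NULL

resolve_tissues <- function(x, tissues) {
  if (is.null(rownames(x))) stop("expression matrix must have rownames")
  if (!is.null(names(tissues))) {
    unknown <- setdiff(rownames(x), names(tissues))
    if (length(unknown))
      stop("no tissue mapping for sample(s): ",
           paste(head(unknown, 5), collapse = ", "))
    tissues <- tissues[rownames(x)]
  } else if (length(tissues) != nrow(x)) {
    stop("tissues must be named by sample or aligned to matrix rows")
  }
  tissues <- as.character(tissues)
  if (any(is.na(tissues) | tissues == "")) stop("empty tissue label")
  tissues
}

new_corrected_matrix <- function(values, mu, sigma, method, degenerate) {
  structure(list(values = values, mu = mu, sigma = sigma, method = method,
                 degenerate = degenerate), class = "corrected_matrix")
}

#' @export
print.corrected_matrix <- function(x, ...) {
  cat(sprintf("corrected_matrix (%s): %d samples x %d genes, %d tissues, %d degenerate strata\n",
              x$method, nrow(x$values), ncol(x$values), nrow(x$mu),
              nrow(x$degenerate)))
  invisible(x)
}

#' @export
as.matrix.corrected_matrix <- function(x, ...) x$values

#' Z-score expression within tissue
#'
#' Standardizes every (tissue, gene) stratum: `Z = (x - mu_i) / sigma_i`
#' with the tissue-specific mean and sample (n-1 denominator) standard
#' deviation. Degenerate strata — single-sample tissues or zero
#' within-stratum variance — are set to 0 rather than dropped, keeping the
#' matrix shape stable across modalities, and are recorded.
#'
#' @param x Numeric matrix, samples x genes, with rownames.
#' @param tissues Tissue label per sample; named vector (names = sample ids)
#'   or vector aligned to rows. See [tissue_map()].
#' @return A `corrected_matrix` with `method = "zscore"`.
#' @export
zscore_by_tissue <- function(x, tissues) {
  tissues <- resolve_tissues(x, tissues)
  f <- factor(tissues)
  n_i <- as.vector(table(f))
  mu <- rowsum(x, f) / n_i
  # Per-stratum sample SD via the sum-of-squares identity.
  ss <- rowsum(x^2, f) - n_i * mu^2
  ss[ss < 0] <- 0
  sigma <- sqrt(sweep(ss, 1L, pmax(n_i - 1L, 1L), "/"))
  idx <- as.integer(f)
  z <- (x - mu[idx, , drop = FALSE])
  sig_full <- sigma[idx, , drop = FALSE]
  degen <- sigma == 0 | n_i < 2L
  z <- ifelse(degen[idx, , drop = FALSE] | sig_full == 0, 0, z / sig_full)
  dimnames(z) <- dimnames(x)
  deg_idx <- which(degen, arr.ind = TRUE)
  degenerate <- data.frame(tissue = rownames(sigma)[deg_idx[, 1]],
                           gene = colnames(x)[deg_idx[, 2]],
                           stringsAsFactors = FALSE)
  new_corrected_matrix(z, mu, sigma, "zscore", degenerate)
}

#' Residualize expression on tissue labels
#'
#' Per gene, fits least squares of expression on tissue indicator variables
#' and returns the residuals; equivalently, subtracts the tissue-specific
#' mean. The fit is deterministic, so the `repeats` averaging mandated by
#' the procedure is a no-op hook: `repeats` identical residual matrices are
#' averaged.
#'
#' @inheritParams zscore_by_tissue
#' @param repeats Number of repeated fits to average (default 10).
#' @return A `corrected_matrix` with `method = "residual"`; `sigma` holds the
#'   per-stratum sample SDs for reference, and single-sample tissues are
#'   recorded as degenerate strata (their residuals are exactly 0).
#' @export
residual_correct <- function(x, tissues, repeats = 10) {
  stopifnot(repeats >= 1)
  tissues <- resolve_tissues(x, tissues)
  f <- factor(tissues)
  design <- model.matrix(~ 0 + f)
  acc <- NULL
  for (r in seq_len(repeats)) {
    fit <- lm.fit(design, x)
    res <- as.matrix(fit$residuals)
    acc <- if (is.null(acc)) res else acc + res
  }
  res <- acc / repeats
  dimnames(res) <- dimnames(x)
  n_i <- as.vector(table(f))
  mu <- rowsum(x, f) / n_i
  ss <- rowsum(x^2, f) - n_i * mu^2
  ss[ss < 0] <- 0
  sigma <- sqrt(sweep(ss, 1L, pmax(n_i - 1L, 1L), "/"))
  degen <- which(sigma == 0 | n_i < 2L, arr.ind = TRUE)
  degenerate <- data.frame(tissue = rownames(sigma)[degen[, 1]],
                           gene = colnames(x)[degen[, 2]],
                           stringsAsFactors = FALSE)
  new_corrected_matrix(res, mu, sigma, "residual", degenerate)
}

#' Diagnostic: tissue separation in principal-component space
#'
#' Projects the matrix onto its top principal components and scores how well
#' tissue labels separate there, as the mean silhouette width of the tissue
#' labelling in PC space. Near 1 = strong tissue clustering; near 0 = no
#' tissue structure. Used to verify that a correction removed the lineage
#' signal.
#'
#' @inheritParams zscore_by_tissue
#' @param n_components Number of leading PCs to use (default 2).
#' @return A number in `[-1, 1]`.
#' @export
tissue_separation_score <- function(x, tissues, n_components = 2) {
  if (inherits(x, "corrected_matrix")) x <- x$values
  tissues <- resolve_tissues(x, tissues)
  f <- factor(tissues)
  if (nlevels(f) < 2L) stop("need at least 2 tissues")
  if (any(table(f) < 2L)) stop("every tissue needs at least 2 samples")
  pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  sc <- pc$x[, seq_len(min(n_components, ncol(pc$x))), drop = FALSE]
  sil <- cluster::silhouette(as.integer(f), stats::dist(sc))
  mean(sil[, "sil_width"])
}

#' Write a corrected matrix and its stratum statistics as TSV
#'
#' Writes the corrected values in the expression schema and a long-format
#' sidecar `(tissue, gene, mu, sigma, degenerate)`.
#'
#' @param cm A `corrected_matrix`.
#' @param values_path,stats_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_corrected_matrix <- function(cm, values_path, stats_path) {
  df <- data.frame(cell_line_id = rownames(cm$values), cm$values,
                   check.names = FALSE)
  write_tsv(df, values_path)
  long <- data.frame(
    tissue = rep(rownames(cm$mu), times = ncol(cm$mu)),
    gene = rep(colnames(cm$mu), each = nrow(cm$mu)),
    mu = as.vector(cm$mu), sigma = as.vector(cm$sigma),
    stringsAsFactors = FALSE)
  key <- paste(long$tissue, long$gene)
  long$degenerate <- key %in% paste(cm$degenerate$tissue, cm$degenerate$gene)
  write_tsv(long, stats_path)
  invisible(c(values_path, stats_path))
}
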