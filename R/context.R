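#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement, capped at 1 (thin validated
#' wrapper over [stats::p.adjust()]).
#'
#' @param p P-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  p.adjust(p, method = "BH")
}

#' Within-cancer-type biomarker-drug correlations
#'
#' Maps candidate biomarkers to cancer types: for each (gene, drug, cancer
#' type) with at least `min_n` cell lines carrying both an expression value
#' and an observed AUC, computes Pearson and Spearman correlations between
#' UNCORRECTED expression and AUC (negative r = higher expression, more
#' sensitive). Degenerate strata (zero variance on either side) are skipped
#' with a logged reason. P-values are BH-adjusted; by default over all rows
#' of one invocation (`family = "global"`), optionally within each gene.
#'
#' @param ds A `screen_dataset`.
#' @param genes Candidate gene ids.
#' @param drugs Drug ids to test.
#' @param min_n Minimum lines per (gene, drug, type) (default 3).
#' @param family BH family: `"global"` or `"per_gene"`.
#' @return Data frame `(gene, drug_id, cancer_type, n, pearson_r,
#'   pearson_p, spearman_rho, spearman_p, padj_bh, heatmap)` where
#'   `heatmap` flags rows with `n >= 10`; skipped strata are in attribute
#'   `"skipped"`.
#' @export
per_type_drug_gene_correlations <- function(ds, genes, drugs, min_n = 3,
                                            family = c("global", "per_gene")) {
  family <- match.arg(family)
  stopifnot(inherits(ds, "screen_dataset"))
  missing_g <- setdiff(genes, colnames(ds$expression))
  if (length(missing_g))
    stop("gene(s) not in dataset: ", paste(missing_g, collapse = ", "))
  tiss <- tissue_map(ds)
  usable <- ds$response[!is.na(ds$response$auc) &
                          ds$response$drug_id %in% drugs, , drop = FALSE]
  usable <- usable[usable$cell_line_id %in% rownames(ds$expression), ,
                   drop = FALSE]
  usable$cancer_type <- tiss[usable$cell_line_id]
  rows <- list(); skipped <- list()
  for (g in genes) {
    expr_g <- ds$expression[, g]
    for (d in unique(usable$drug_id)) {
      sub <- usable[usable$drug_id == d, , drop = FALSE]
      for (ct in unique(sub$cancer_type)) {
        s <- sub[sub$cancer_type == ct, , drop = FALSE]
        if (nrow(s) < min_n) next
        x <- expr_g[s$cell_line_id]; y <- s$auc
        if (sd(x) == 0 || sd(y) == 0) {
          skipped[[length(skipped) + 1L]] <- data.frame(
            gene = g, drug_id = d, cancer_type = ct, n = nrow(s),
            reason = "zero variance", stringsAsFactors = FALSE)
          next
        }
        pe <- cor.test(x, y, method = "pearson")
        sp <- suppressWarnings(cor.test(x, y, method = "spearman",
                                        exact = FALSE))
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, drug_id = d, cancer_type = ct, n = nrow(s),
          pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
          spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), drug_id = character(),
               cancer_type = character(), n = integer(),
               pearson_r = numeric(), pearson_p = numeric(),
               spearman_rho = numeric(), spearman_p = numeric(),
               stringsAsFactors = FALSE)
  if (nrow(out)) {
    if (family == "global") {
      out$padj_bh <- bh_adjust(out$pearson_p)
    } else {
      out$padj_bh <- NA_real_
      for (g in unique(out$gene)) {
        idx <- out$gene == g
        out$padj_bh[idx] <- bh_adjust(out$pearson_p[idx])
      }
    }
    out$heatmap <- out$n >= 10
  } else {
    out$padj_bh <- numeric(); out$heatmap <- logical()
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(gene = character(), drug_id = character(),
               cancer_type = character(), n = integer(), reason = character(),
               stringsAsFactors = FALSE)
  out
}

#' Heatmap matrix of within-type correlations
#'
#' Retains rows with `n >= min_n` (default 10, the reporting filter for
#' heatmaps) and reshapes Pearson r into a matrix with biomarker-drug pairs
#' in rows and cancer types in columns; absent combinations are `NA`.
#' Row and column order is sorted and therefore stable across runs.
#'
#' @param table Output of [per_type_drug_gene_correlations()].
#' @param min_n Minimum lines per entry (default 10).
#' @return Numeric matrix, possibly 0 x 0.
#' @export
heatmap_matrix <- function(table, min_n = 10) {
  sub <- table[table$n >= min_n, , drop = FALSE]
  if (nrow(sub) == 0L) return(matrix(numeric(), 0, 0))
  pair <- paste(sub$gene, sub$drug_id, sep = "|")
  rows <- sort(unique(pair)); cols <- sort(unique(sub$cancer_type))
  m <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(rows, cols))
  m[cbind(match(pair, rows), match(sub$cancer_type, cols))] <- sub$pearson_r
  m
}
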