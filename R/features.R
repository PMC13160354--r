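#' Aggregate model coefficients into per-drug gene ranks
#'
#' For each drug the per-run weights of every gene are averaged
#' (`w_bar_dg`), then genes are sorted by absolute averaged weight in
#' descending order; the rank `r_bar_dg` in `1..G` is the position in that
#' sort (1 = largest magnitude). Ties are broken by lexicographic gene id so
#' ranks are a deterministic permutation of `1..G`.
#'
#' @param results A `drug_model_set` or list of them.
#' @return Data frame `(drug_id, modality, gene, weight, rank)`.
#' @export
rank_features <- function(results) {
  if (inherits(results, "drug_model_set")) results <- list(results)
  out <- lapply(results, function(ms) {
    do.call(rbind, lapply(ms$drugs, function(d) {
      w <- colMeans(d$coefficients)
      genes <- names(w)
      ord <- order(-abs(w), genes, method = "radix")
      rk <- integer(length(w)); rk[ord] <- seq_along(w)
      data.frame(drug_id = d$drug_id, modality = ms$modality, gene = genes,
                 weight = unname(w), rank = rk, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

top_k_sets <- function(rank_table, k = 10) {
  sub <- rank_table[rank_table$rank <= k, , drop = FALSE]
  split(sub$gene, sub$drug_id)
}

#' Percentage of unique top-10 genes in a pathway
#'
#' With `d_p` drug models targeting pathway p and the top-`k` genes of each,
#' the uniqueness of the pathway's feature pool is
#' `100 * n_unique / (d_p * k)`. 100% = all drugs nominate disjoint genes;
#' the lower bound `100 / d_p` is attained when all drugs share one set.
#'
#' @param top_sets List of character vectors, one per drug, each of length
#'   `k`.
#' @param k Required set size (default 10).
#' @return Percentage in `[100/d_p, 100]`.
#' @export
unique_gene_percentage <- function(top_sets, k = 10) {
  if (length(top_sets) < 1L) stop("need at least one drug set")
  sizes <- lengths(top_sets)
  if (any(sizes != k))
    stop(sprintf("every top set must have exactly %d genes (got sizes %s)",
                 k, paste(unique(sizes), collapse = ", ")))
  100 * length(unique(unlist(top_sets))) / (k * length(top_sets))
}

#' Recurrent features of a drug pathway
#'
#' Genes appearing in the top-`k` of at least `min_fraction` of the drugs
#' targeting one pathway, with their appearance fraction and mean rank among
#' appearances.
#'
#' @param rank_table Output of [rank_features()] (one modality).
#' @param drugs_in_pathway Drug ids targeting the pathway (typically the
#'   informative ones).
#' @param min_fraction Minimum appearance fraction (default 0.25; the `>=`
#'   boundary is inclusive).
#' @param k Top-rank cutoff (default 10).
#' @return Data frame `(gene, n_appearances, fraction, mean_rank)` sorted by
#'   decreasing fraction then mean rank.
#' @export
recurrent_pathway_features <- function(rank_table, drugs_in_pathway,
                                       min_fraction = 0.25, k = 10) {
  if (length(drugs_in_pathway) < 1L) stop("pathway has no drugs")
  sub <- rank_table[rank_table$drug_id %in% drugs_in_pathway &
                      rank_table$rank <= k, , drop = FALSE]
  if (nrow(sub) == 0L)
    return(data.frame(gene = character(), n_appearances = integer(),
                      fraction = numeric(), mean_rank = numeric(),
                      stringsAsFactors = FALSE))
  agg <- aggregate(rank ~ gene, sub, mean)
  cnt <- aggregate(drug_id ~ gene, sub, function(z) length(unique(z)))
  out <- data.frame(gene = agg$gene,
                    n_appearances = cnt$drug_id[match(agg$gene, cnt$gene)],
                    stringsAsFactors = FALSE)
  out$fraction <- out$n_appearances / length(drugs_in_pathway)
  out$mean_rank <- agg$rank
  out <- out[out$fraction >= min_fraction, , drop = FALSE]
  out <- out[order(-out$fraction, out$mean_rank, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify feature stability across raw and corrected models
#'
#' Per drug, the union of the raw-input and corrected-input top-`k` gene
#' sets is partitioned into `retained` (present in both), `emerged`
#' (corrected only) and `dropped` (raw only; reported so that proportions
#' are well defined over the union).
#'
#' @param rank_raw,rank_corrected [rank_features()] tables for the raw and
#'   corrected modality (matching drugs).
#' @param k Top-rank cutoff (default 10).
#' @return Data frame `(drug_id, gene, class)`; drugs missing either
#'   modality are excluded and listed in attribute `"excluded_drugs"`.
#' @export
classify_feature_stability <- function(rank_raw, rank_corrected, k = 10) {
  raw_sets <- top_k_sets(rank_raw, k)
  cor_sets <- top_k_sets(rank_corrected, k)
  common <- intersect(names(raw_sets), names(cor_sets))
  excluded <- setdiff(union(names(raw_sets), names(cor_sets)), common)
  rows <- lapply(common, function(d) {
    r <- raw_sets[[d]]; z <- cor_sets[[d]]
    u <- union(r, z)
    cls <- ifelse(u %in% r & u %in% z, "retained",
                  ifelse(u %in% z, "emerged", "dropped"))
    data.frame(drug_id = d, gene = u, class = cls, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded_drugs") <- excluded
  out
}

#' Proportion of expression variance explained by tissue of origin
#'
#' One-way decomposition `eta^2 = SS_between / SS_total` with
#' `SS_between = sum_i n_i (xbar_i - xbar)^2` and
#' `SS_total = sum (x - xbar)^2`, computed on the uncorrected expression of
#' one gene across cell lines grouped by cancer type.
#'
#' @param x Expression vector for one gene.
#' @param tissues Tissue label per entry (named or aligned).
#' @return Number in `[0, 1]`; `NA` if total variance is zero.
#' @export
eta_squared <- function(x, tissues) {
  if (!is.null(names(tissues)) && !is.null(names(x)))
    tissues <- tissues[names(x)]
  if (length(tissues) != length(x)) stop("tissues must align to x")
  f <- factor(as.character(tissues))
  if (nlevels(f) < 2L) stop("need at least 2 tissues")
  xbar <- mean(x)
  ss_total <- sum((x - xbar)^2)
  if (ss_total == 0) return(NA_real_)
  gm <- tapply(x, f, mean)
  n_i <- tapply(x, f, length)
  sum(n_i * (gm - xbar)^2) / ss_total
}

#' Rank change after tissue correction
#'
#' `delta_rank = rank_exp - rank_zscore` per (drug, gene): positive values
#' mean the gene improved (moved toward rank 1) after correction.
#'
#' @param rank_raw,rank_corrected [rank_features()] tables (raw and
#'   z-score-corrected modality).
#' @param genes Optional gene subset.
#' @return List: `values` data frame `(drug_id, gene, rank_exp,
#'   rank_zscore, delta_rank)` and `per_gene` data frame `(gene,
#'   median_delta_rank)`.
#' @export
delta_rank <- function(rank_raw, rank_corrected, genes = NULL) {
  a <- rank_raw[, c("drug_id", "gene", "rank")]
  b <- rank_corrected[, c("drug_id", "gene", "rank")]
  if (!is.null(genes)) {
    a <- a[a$gene %in% genes, , drop = FALSE]
    b <- b[b$gene %in% genes, , drop = FALSE]
  }
  m <- merge(a, b, by = c("drug_id", "gene"),
             suffixes = c("_exp", "_zscore"))
  m$delta_rank <- m$rank_exp - m$rank_zscore
  med <- aggregate(delta_rank ~ gene, m, median)
  names(med)[2] <- "median_delta_rank"
  list(values = m[order(m$gene, m$drug_id), ], per_gene = med)
}

#' Full stability and tissue-attribution report
#'
#' Combines [classify_feature_stability()], [eta_squared()] (always on the
#' uncorrected matrix) and [delta_rank()] into the per-gene stability
#' report, plus per-pathway mean retained/emerged proportions. Proportions
#' are reported under two normalizations: over the union of both top-k sets
#' (`*_union`) and over the corrected top-k set only (`*_corrected`).
#'
#' @param ds A `screen_dataset` (source of uncorrected expression and
#'   tissues).
#' @param rank_raw,rank_corrected [rank_features()] tables.
#' @param k Top-rank cutoff (default 10).
#' @return List: `classes` (per drug-gene), `genes` (per-gene modal class,
#'   eta2, median delta rank), `pathways` (per-pathway mean proportions with
#'   contributing model counts).
#' @export
stability_report <- function(ds, rank_raw, rank_corrected, k = 10) {
  classes <- classify_feature_stability(rank_raw, rank_corrected, k)
  tiss <- tissue_map(ds)
  genes <- sort(unique(classes$gene))
  eta <- vapply(genes, function(g) {
    if (!g %in% colnames(ds$expression)) return(NA_real_)
    eta_squared(ds$expression[, g], tiss[rownames(ds$expression)])
  }, numeric(1))
  dr <- delta_rank(rank_raw, rank_corrected, genes = genes)
  modal_class <- vapply(genes, function(g) {
    cls <- classes$class[classes$gene == g]
    tab <- sort(table(factor(cls, levels = c("retained", "emerged",
                                             "dropped"))), decreasing = TRUE)
    names(tab)[1]
  }, character(1))
  gene_table <- data.frame(
    gene = genes, class = modal_class, eta2 = unname(eta),
    median_delta_rank = dr$per_gene$median_delta_rank[
      match(genes, dr$per_gene$gene)],
    n_models = as.vector(table(factor(classes$gene, levels = genes))),
    stringsAsFactors = FALSE)

  path <- ds$drugs$pathway[match(classes$drug_id, ds$drugs$drug_id)]
  per_drug <- lapply(split(classes, classes$drug_id), function(df) {
    u <- nrow(df)
    nc <- sum(df$class != "dropped")
    data.frame(drug_id = df$drug_id[1],
               retained_union = sum(df$class == "retained") / u,
               emerged_union = sum(df$class == "emerged") / u,
               retained_corrected = sum(df$class == "retained") / max(nc, 1),
               emerged_corrected = sum(df$class == "emerged") / max(nc, 1),
               stringsAsFactors = FALSE)
  })
  per_drug <- do.call(rbind, per_drug)
  per_drug$pathway <- ds$drugs$pathway[match(per_drug$drug_id,
                                             ds$drugs$drug_id)]
  paths <- split(per_drug, per_drug$pathway)
  pathways <- do.call(rbind, lapply(paths, function(df) {
    data.frame(pathway = df$pathway[1], n_models = nrow(df),
               mean_retained_union = mean(df$retained_union),
               mean_emerged_union = mean(df$emerged_union),
               mean_retained_corrected = mean(df$retained_corrected),
               mean_emerged_corrected = mean(df$emerged_corrected),
               stringsAsFactors = FALSE)
  }))
  rownames(pathways) <- NULL
  list(classes = classes, genes = gene_table, pathways = pathways)
}

#' Pathway-level feature summary over informative models
#'
#' Per pathway: number of informative drug models, the unique-gene
#' percentage of their pooled top-`k` sets, and the recurrent features at
#' the `min_fraction` rule.
#'
#' @param rank_table [rank_features()] table for one modality.
#' @param drugs Drug annotation `(drug_id, pathway)` restricted to
#'   informative drugs.
#' @param min_fraction,k See [recurrent_pathway_features()].
#' @return List: `summary` data frame `(pathway, n_models, unique_pct)` and
#'   `recurrent` data frame with a pathway column.
#' @export
pathway_feature_summary <- function(rank_table, drugs, min_fraction = 0.25,
                                    k = 10) {
  paths <- split(drugs$drug_id, drugs$pathway)
  summ <- list(); rec <- list()
  for (p in names(paths)) {
    ids <- intersect(paths[[p]], unique(rank_table$drug_id))
    if (length(ids) == 0L) next
    sets <- top_k_sets(rank_table[rank_table$drug_id %in% ids, ], k)
    summ[[p]] <- data.frame(pathway = p, n_models = length(ids),
                            unique_pct = unique_gene_percentage(sets, k),
                            stringsAsFactors = FALSE)
    r <- recurrent_pathway_features(rank_table, ids, min_fraction, k)
    if (nrow(r)) { r$pathway <- p; rec[[p]] <- r }
  }
  list(summary = do.call(rbind, c(summ, list(make.row.names = FALSE))),
       recurrent = if (length(rec)) do.call(rbind, c(rec, list(make.row.names = FALSE)))
                   else data.frame(gene = character(), n_appearances = integer(),
                                   fraction = numeric(), mean_rank = numeric(),
                                   pathway = character(), stringsAsFactors = FALSE))
}
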