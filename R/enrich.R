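#' Rank drugs by a feature's model weight
#'
#' For a candidate biomarker gene, collects its run-averaged weight in every
#' drug model of a modality and orders drugs from lowest to highest weight
#' (most-negative = sensitivity end first). Ties are broken by drug id so
#' the order is a strict, deterministic total order.
#'
#' @param rank_table [rank_features()] table.
#' @param gene Feature gene id.
#' @param modality Modality to use (default `"zscore"`).
#' @param drugs Optional drug-id universe (defaults to all drugs in the
#'   table for that modality); the gene must be present in every model.
#' @return Object of class `ranked_drug_list`: `gene`, `table` (data frame
#'   `drug_id`, `weight`, ascending), `M` (universe size).
#' @export
rank_drugs_for_feature <- function(rank_table, gene, modality = "zscore",
                                   drugs = NULL) {
  sub <- rank_table[rank_table$modality == modality, , drop = FALSE]
  universe <- drugs %||% unique(sub$drug_id)
  sub <- sub[sub$gene == gene & sub$drug_id %in% universe, , drop = FALSE]
  missing <- setdiff(universe, sub$drug_id)
  if (length(missing))
    stop(sprintf("gene '%s' absent from model(s): %s", gene,
                 paste(missing, collapse = ", ")))
  ord <- order(sub$weight, sub$drug_id, method = "radix")
  tab <- data.frame(drug_id = sub$drug_id[ord], weight = sub$weight[ord],
                    stringsAsFactors = FALSE)
  structure(list(gene = gene, table = tab, M = nrow(tab)),
            class = "ranked_drug_list")
}

#' @export
print.ranked_drug_list <- function(x, ...) {
  cat(sprintf("ranked_drug_list: gene %s over %d drugs (weights %.4g .. %.4g)\n",
              x$gene, x$M, x$table$weight[1], x$table$weight[x$M]))
  invisible(x)
}

# Core running-sum statistic on a descending-by-weight drug list.
running_sum_es <- function(weights, is_hit, weight_exponent = 1) {
  hw <- abs(weights)^weight_exponent
  tot <- sum(hw[is_hit])
  inc <- if (tot > 0) hw / tot else rep(1 / sum(is_hit), length(weights))
  dec <- 1 / (length(weights) - sum(is_hit))
  steps <- ifelse(is_hit, inc, -dec)
  s <- cumsum(steps)
  mx <- max(s); mn <- min(s)
  # Near-ties between the positive and negative extremum resolve to the
  # positive one (deterministic across accumulation orders).
  if (abs(mx) >= abs(mn) - 1e-12) mx else mn
}

#' Preranked drug-set enrichment score
#'
#' Classic weighted running-sum statistic testing whether the drugs of a
#' target pathway concentrate at one extreme of a weight-ranked drug list.
#' The list is (re)sorted descending by weight; walking down it, hits
#' increment the running sum by `|w|^weight_exponent` normalized by the
#' set's total, misses decrement by `1/(M - |set|)`. The ES is the running
#' sum at its maximum absolute deviation (first occurrence on ties).
#' Negative ES = the set concentrates at the most-negative-weight
#' (sensitivity) end.
#'
#' @param rl A [rank_drugs_for_feature()] result.
#' @param drug_set Drug ids forming the set; must be a non-empty proper
#'   subset of the universe.
#' @param weight_exponent 1 (default, magnitude-weighted hits) or 0 (equal
#'   steps).
#' @return ES in `[-1, 1]`.
#' @export
enrichment_score <- function(rl, drug_set, weight_exponent = 1) {
  stopifnot(inherits(rl, "ranked_drug_list"))
  drug_set <- unique(drug_set)
  if (!all(drug_set %in% rl$table$drug_id))
    stop("drug_set contains drugs outside the ranked universe")
  if (length(drug_set) < 1L || length(drug_set) >= rl$M)
    stop("drug_set must be a non-empty proper subset of the universe")
  ord <- order(-rl$table$weight, rl$table$drug_id, method = "radix")
  w <- rl$table$weight[ord]
  hit <- rl$table$drug_id[ord] %in% drug_set
  running_sum_es(w, hit, weight_exponent)
}

#' Permutation p-value for an enrichment score
#'
#' Compares the observed ES against scores of random drug sets of the same
#' size. The default convention matches the directional preranked-GSEA
#' reading: a permutation counts as at least as extreme when
#' `|ES_perm| >= |ES_obs|` and its sign matches the observed sign (an
#' observed ES of 0 counts every permutation, giving p = 1);
#' `alternative = "two.sided"` drops the sign match. Monte-Carlo p-values
#' use the permutation estimator `(b + 1) / (n_perm + 1)`; with
#' `exact = TRUE` all same-size sets are enumerated and `p = b / total`.
#'
#' @param rl A [rank_drugs_for_feature()] result.
#' @param drug_set Drug set, as in [enrichment_score()].
#' @param n_perm Monte-Carlo permutations (default 10000).
#' @param seed Integer seed.
#' @param weight_exponent See [enrichment_score()].
#' @param alternative `"directional"` (default) or `"two.sided"`.
#' @param exact Enumerate all subsets instead of sampling (feasible for
#'   small universes only).
#' @return List: `es`, `p_value`, `n_perm` (or number enumerated).
#' @export
es_permutation_pvalue <- function(rl, drug_set, n_perm = 10000, seed = 1L,
                                  weight_exponent = 1,
                                  alternative = c("directional", "two.sided"),
                                  exact = FALSE) {
  alternative <- match.arg(alternative)
  es_obs <- enrichment_score(rl, drug_set, weight_exponent)
  ord <- order(-rl$table$weight, rl$table$drug_id, method = "radix")
  w <- rl$table$weight[ord]
  ids <- rl$table$drug_id[ord]
  m <- length(unique(drug_set))
  count_extreme <- function(es) {
    ok <- abs(es) >= abs(es_obs) - 1e-12
    if (alternative == "directional" && es_obs != 0)
      ok <- ok & (sign(es) == sign(es_obs))
    sum(ok)
  }
  if (exact) {
    sets <- combn(rl$M, m)
    es_all <- apply(sets, 2L, function(ix) {
      hit <- logical(rl$M); hit[ix] <- TRUE
      running_sum_es(w, hit, weight_exponent)
    })
    return(list(es = es_obs, p_value = count_extreme(es_all) / ncol(sets),
                n_perm = ncol(sets)))
  }
  es_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    hit <- logical(rl$M)
    hit[sample.int(rl$M, m)] <- TRUE
    running_sum_es(w, hit, weight_exponent)
  }, numeric(1)))
  list(es = es_obs, p_value = (count_extreme(es_perm) + 1) / (n_perm + 1),
       n_perm = n_perm)
}

#' Feature x pathway enrichment over drug rankings
#'
#' For every candidate feature and every pathway targeted by at least
#' `min_pathway_size` drugs, computes the preranked enrichment score of the
#' pathway's drugs in the feature's weight-ranked drug list, a permutation
#' p-value, and a Bonferroni-adjusted p (factor = number of tested
#' feature x pathway combinations).
#'
#' @param features Candidate gene ids.
#' @param rank_table [rank_features()] table (typically restricted to
#'   informative drugs).
#' @param drugs Drug annotation `(drug_id, pathway)` defining the universe
#'   and the sets.
#' @param modality Modality of the rankings (default `"zscore"`).
#' @param n_perm,seed,weight_exponent,alternative Passed to
#'   [es_permutation_pvalue()].
#' @param min_pathway_size Minimum drugs per tested pathway (default 2).
#' @return Data frame `(feature, pathway, set_size, es, p_value,
#'   padj_bonferroni, n_perm)` sorted by adjusted then raw p, of class
#'   `enrichment_result`.
#' @export
run_feature_pathway_enrichment <- function(features, rank_table, drugs,
                                           modality = "zscore",
                                           n_perm = 10000, seed = 1L,
                                           weight_exponent = 1,
                                           alternative = "directional",
                                           min_pathway_size = 2) {
  stopifnot(length(features) > 0)
  universe <- intersect(unique(drugs$drug_id),
                        unique(rank_table$drug_id[
                          rank_table$modality == modality]))
  sets <- split(drugs$drug_id[drugs$drug_id %in% universe],
                drugs$pathway[drugs$drug_id %in% universe])
  sets <- sets[lengths(sets) >= min_pathway_size &
                 lengths(sets) < length(universe)]
  if (length(sets) == 0L) stop("no pathway with enough drugs to test")
  grid <- expand.grid(feature = features, pathway = names(sets),
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    rl <- rank_drugs_for_feature(rank_table, grid$feature[i], modality,
                                 drugs = universe)
    pp <- es_permutation_pvalue(rl, sets[[grid$pathway[i]]], n_perm = n_perm,
                                seed = derive_seed(seed, i),
                                weight_exponent = weight_exponent,
                                alternative = alternative)
    rows[[i]] <- data.frame(feature = grid$feature[i],
                            pathway = grid$pathway[i],
                            set_size = length(sets[[grid$pathway[i]]]),
                            es = pp$es, p_value = pp$p_value,
                            n_perm = pp$n_perm, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$padj_bonferroni <- pmin(1, out$p_value * nrow(out))
  out <- out[order(out$padj_bonferroni, out$p_value, out$feature), ,
             drop = FALSE]
  out <- out[, c("feature", "pathway", "set_size", "es", "p_value",
                 "padj_bonferroni", "n_perm")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}
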