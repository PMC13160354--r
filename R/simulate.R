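#' Configuration for the synthetic screen generator
#'
#' Defines the statistical structure of a simulated pharmacogenomic screen:
#' tissue-structured expression, tissue-biased drug responses (the
#' Simpson's-paradox risk the pipeline is designed to defuse), planted
#' pathway-shared biomarkers, and lineage-proxy decoy genes.
#'
#' Expression for cell line c and gene g is
#' `x_cg = b_g + t_{tissue(c),g} + e_cg` with gene baselines
#' `b_g ~ N(baseline_mean, baseline_sd^2)` (log2/RMA-like units), tissue
#' effects `t ~ N(0, tissue_effect_var)` and residuals
#' `e ~ N(0, residual_var)`, so the true tissue-variance fraction of an
#' ordinary gene is `tissue_effect_var / (tissue_effect_var + residual_var)`.
#' Response is `auc_cd = alpha_d + solid_shift * [tissue(c) non-solid]
#' - beta_d * z*_c + eps`, where `z*` is the within-tissue standardized
#' expression of the drug's planted biomarker gene (so higher expression =>
#' lower AUC => more sensitive) and `eps ~ N(0, response_noise_sd^2)`; AUC is
#' clipped to `[0, 1]` afterwards. Decoy genes are affine in the tissue-level
#' mean sensitivity plus small noise: pure lineage proxies carrying no
#' within-tissue information.
#'
#' Defaults describe the package's reference screen: 10 cancer types of 20
#' lines (3 non-solid types), 2000 genes, 30 drugs in 3 target pathways, one
#' pathway of 10 drugs sharing a planted biomarker whose effect size makes it
#' explain ~25% of within-tissue response variance
#' (`beta = response_noise_sd / sqrt(3)`), one decoy gene, and 80% per-drug
#' screening coverage.
#'
#' @param n_tissues Number of cancer types.
#' @param lines_per_tissue Lines per cancer type; scalar or length
#'   `n_tissues` vector (unequal sizes allowed).
#' @param n_genes Number of genes (decoys included, occupying the last
#'   columns).
#' @param n_drugs Number of drugs.
#' @param pathways Optional named character vector drug id -> pathway label;
#'   default splits drugs round-robin-free into `pathway1..pathway3` blocks.
#' @param non_solid_tissues How many tissues (the last ones) are non-solid.
#' @param baseline_mean,baseline_sd Gene baseline distribution.
#' @param tissue_effect_var Between-tissue expression variance.
#' @param residual_var Within-tissue expression variance (> 0).
#' @param biomarkers Data frame `(pathway, gene, beta, carrier_fraction)`
#'   of planted effects; default plants `gene0001` for `pathway1` with
#'   `carrier_fraction = 1`. Use `NULL` rows via `data.frame()` for none.
#' @param solid_shift AUC offset added to non-solid lines (negative = more
#'   sensitive, the usual direction for haematological lines).
#' @param response_noise_sd Response noise standard deviation (> 0).
#' @param auc_mean,auc_sd Distribution of per-drug baseline AUC `alpha_d`.
#' @param n_decoy_genes Number of lineage-proxy decoy genes.
#' @param decoy_noise_sd Noise added to decoy genes; small values make them
#'   near-pure tissue proxies with eta-squared close to 1.
#' @param drug_coverage Fraction of lines screened per drug, in (0, 1].
#' @param seed Integer seed; all draws come from this generator.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_tissues = 10,
                              lines_per_tissue = 20,
                              n_genes = 2000,
                              n_drugs = 30,
                              pathways = NULL,
                              non_solid_tissues = 3,
                              baseline_mean = 7, baseline_sd = 1,
                              tissue_effect_var = 0.3,
                              residual_var = 0.7,
                              biomarkers = NULL,
                              solid_shift = -0.2,
                              response_noise_sd = 0.08,
                              auc_mean = 0.7, auc_sd = 0.05,
                              n_decoy_genes = 1,
                              decoy_noise_sd = 0.1,
                              drug_coverage = 0.8,
                              seed = 1) {
  if (length(lines_per_tissue) == 1L)
    lines_per_tissue <- rep(lines_per_tissue, n_tissues)
  if (length(lines_per_tissue) != n_tissues)
    stop("lines_per_tissue must be scalar or length n_tissues")
  if (tissue_effect_var < 0 || residual_var <= 0)
    stop("variances must satisfy tissue_effect_var >= 0, residual_var > 0")
  if (response_noise_sd <= 0) stop("response_noise_sd must be > 0")
  if (drug_coverage <= 0 || drug_coverage > 1)
    stop("drug_coverage must lie in (0, 1]")
  if (non_solid_tissues < 0 || non_solid_tissues > n_tissues)
    stop("non_solid_tissues out of range")
  drug_ids <- sprintf("drug%03d", seq_len(n_drugs))
  if (is.null(pathways)) {
    blocks <- sprintf("pathway%d", 1:3)
    pathways <- setNames(blocks[pmin(3, ceiling(3 * seq_len(n_drugs) / n_drugs))],
                         drug_ids)
  }
  if (is.null(names(pathways)) || !setequal(names(pathways), drug_ids))
    stop("pathways must be a named vector covering every drug id")
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  if (is.null(biomarkers)) {
    # Default planted effect sits in the first drug's pathway and explains
    # ~25% of within-tissue response variance for its carriers.
    biomarkers <- data.frame(pathway = unname(pathways[drug_ids[1]]),
                             gene = gene_ids[1],
                             beta = response_noise_sd / sqrt(3),
                             carrier_fraction = 1,
                             stringsAsFactors = FALSE)
  }
  decoy_genes <- if (n_decoy_genes > 0)
    gene_ids[seq(n_genes - n_decoy_genes + 1L, n_genes)] else character()
  if (nrow(biomarkers)) {
    if (!all(biomarkers$gene %in% gene_ids))
      stop("biomarker gene not present among simulated genes")
    if (any(biomarkers$gene %in% decoy_genes))
      stop("biomarker genes must be distinct from decoy genes")
    if (!all(biomarkers$pathway %in% pathways))
      stop("biomarker pathway not present among drug pathways")
  }
  structure(list(
    n_tissues = n_tissues, lines_per_tissue = lines_per_tissue,
    n_genes = n_genes, n_drugs = n_drugs, drug_ids = drug_ids,
    gene_ids = gene_ids, pathways = pathways,
    non_solid_tissues = non_solid_tissues,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    tissue_effect_var = tissue_effect_var, residual_var = residual_var,
    biomarkers = biomarkers, solid_shift = solid_shift,
    response_noise_sd = response_noise_sd,
    auc_mean = auc_mean, auc_sd = auc_sd,
    n_decoy_genes = n_decoy_genes, decoy_genes = decoy_genes,
    decoy_noise_sd = decoy_noise_sd,
    drug_coverage = drug_coverage, seed = seed), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config\n")
  cat(sprintf("  %d tissues (%d non-solid), %d lines, %d genes (%d decoys), %d drugs\n",
              x$n_tissues, x$non_solid_tissues, sum(x$lines_per_tissue),
              x$n_genes, x$n_decoy_genes, x$n_drugs))
  cat(sprintf("  tissue/residual variance %.2f/%.2f, solid shift %.2f, coverage %.0f%%, seed %d\n",
              x$tissue_effect_var, x$residual_var, x$solid_shift,
              100 * x$drug_coverage, x$seed))
  if (nrow(x$biomarkers))
    cat(sprintf("  planted: %s\n", paste(
      sprintf("%s->%s (beta=%.3f, carriers=%.0f%%)", x$biomarkers$pathway,
              x$biomarkers$gene, x$biomarkers$beta,
              100 * x$biomarkers$carrier_fraction), collapse = "; ")))
  invisible(x)
}

#' Simulate a pharmacogenomic screen with planted ground truth
#'
#' Generates a [screen_dataset] under the model documented in
#' [simulation_config()], together with the ground truth needed for
#' recovery tests: planted (pathway, gene, beta) triples, per-drug carrier
#' flags, decoy gene list, and the per-gene true tissue-variance fraction.
#'
#' @param cfg A `simulation_config`.
#' @return List with elements `dataset` (a `screen_dataset`) and `truth`
#'   (list: `planted` data frame, `drugs` data frame with carrier flags,
#'   `decoy_genes`, `tissue_variance_fraction`).
#' @export
simulate_screen <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, {
    tissues <- sprintf("tissue%02d", seq_len(cfg$n_tissues))
    tclass <- rep("solid", cfg$n_tissues)
    if (cfg$non_solid_tissues > 0)
      tclass[seq(cfg$n_tissues - cfg$non_solid_tissues + 1L, cfg$n_tissues)] <-
        "non_solid"
    line_tissue <- rep(tissues, cfg$lines_per_tissue)
    n_lines <- length(line_tissue)
    lines <- sprintf("line%04d", seq_len(n_lines))
    samples <- data.frame(cell_line_id = lines, cancer_type = line_tissue,
                          tumor_class = tclass[match(line_tissue, tissues)],
                          stringsAsFactors = FALSE)

    b <- rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
    tis_eff <- matrix(rnorm(cfg$n_tissues * cfg$n_genes,
                            sd = sqrt(cfg$tissue_effect_var)),
                      cfg$n_tissues, cfg$n_genes)
    expr <- matrix(rnorm(n_lines * cfg$n_genes, sd = sqrt(cfg$residual_var)),
                   n_lines, cfg$n_genes,
                   dimnames = list(lines, cfg$gene_ids))
    expr <- expr + rep(b, each = n_lines) +
      tis_eff[match(line_tissue, tissues), , drop = FALSE]

    nonsolid_line <- samples$tumor_class == "non_solid"
    alpha <- rnorm(cfg$n_drugs, cfg$auc_mean, cfg$auc_sd)

    # Per-drug planted effects: within each annotated pathway, the first
    # round(fraction * block size) drugs carry the effect.
    beta_d <- setNames(numeric(cfg$n_drugs), cfg$drug_ids)
    gene_d <- setNames(rep(NA_character_, cfg$n_drugs), cfg$drug_ids)
    if (nrow(cfg$biomarkers)) {
      for (i in seq_len(nrow(cfg$biomarkers))) {
        bm <- cfg$biomarkers[i, ]
        in_path <- cfg$drug_ids[cfg$pathways[cfg$drug_ids] == bm$pathway]
        carriers <- in_path[seq_len(round(bm$carrier_fraction * length(in_path)))]
        beta_d[carriers] <- bm$beta
        gene_d[carriers] <- bm$gene
      }
    }

    # Within-tissue standardized expression of each planted gene.
    zstar <- function(gene) {
      x <- expr[, gene]
      z <- numeric(n_lines)
      for (t in tissues) {
        idx <- line_tissue == t
        s <- sd(x[idx])
        z[idx] <- if (is.na(s) || s == 0) 0 else (x[idx] - mean(x[idx])) / s
      }
      z
    }
    zcache <- lapply(setNames(nm = unique(gene_d[!is.na(gene_d)])), zstar)

    resp <- vector("list", cfg$n_drugs)
    for (j in seq_len(cfg$n_drugs)) {
      d <- cfg$drug_ids[j]
      auc <- alpha[j] + cfg$solid_shift * nonsolid_line +
        rnorm(n_lines, sd = cfg$response_noise_sd)
      if (beta_d[d] != 0) auc <- auc - beta_d[d] * zcache[[gene_d[d]]]
      auc <- pmin(1, pmax(0, auc))
      screened <- sort(sample.int(n_lines, max(2L, round(cfg$drug_coverage * n_lines))))
      resp[[j]] <- data.frame(cell_line_id = lines[screened], drug_id = d,
                              auc = auc[screened], stringsAsFactors = FALSE)
    }
    response <- do.call(rbind, resp)

    # Decoy genes: affine in tissue-level mean sensitivity + small noise.
    if (cfg$n_decoy_genes > 0) {
      sens <- mean(alpha) + cfg$solid_shift * (tclass == "non_solid")
      s_sd <- sd(sens)
      s_std <- if (is.na(s_sd) || s_sd == 0) rep(0, cfg$n_tissues)
               else (sens - mean(sens)) / s_sd
      for (g in cfg$decoy_genes) {
        expr[, g] <- cfg$baseline_mean - s_std[match(line_tissue, tissues)] +
          rnorm(n_lines, sd = cfg$decoy_noise_sd)
      }
    }

    drugs <- data.frame(drug_id = cfg$drug_ids,
                        pathway = unname(cfg$pathways[cfg$drug_ids]),
                        stringsAsFactors = FALSE)
    frac <- cfg$tissue_effect_var / (cfg$tissue_effect_var + cfg$residual_var)
    truth <- list(
      planted = cfg$biomarkers,
      drugs = data.frame(drug_id = cfg$drug_ids,
                         carrier = unname(beta_d != 0),
                         biomarker_gene = unname(gene_d),
                         beta = unname(beta_d), stringsAsFactors = FALSE),
      decoy_genes = cfg$decoy_genes,
      tissue_variance_fraction = frac)
    list(dataset = screen_dataset(expr, samples, response, drugs),
         truth = truth)
  })
}

#' Simulate a no-signal (null) screen
#'
#' Identical to [simulate_screen()] but with every planted effect forced to
#' zero; tissue structure in expression and the solid/non-solid response
#' shift are retained. Used for calibration of the informative-model
#' selection.
#'
#' @param cfg A `simulation_config`.
#' @return As [simulate_screen()]; `truth$planted` has zero rows and all
#'   carrier flags are `FALSE`.
#' @export
simulate_null_screen <- function(cfg = simulation_config()) {
  cfg$biomarkers <- cfg$biomarkers[0, , drop = FALSE]
  simulate_screen(cfg)
}

#' Write a simulated screen (dataset + ground truth) to a directory
#'
#' @param sim Result of [simulate_screen()].
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_simulated_screen <- function(sim, dir) {
  write_screen_dataset(sim$dataset, dir)
  tr <- sim$truth$drugs
  tr$decoy_genes <- paste(sim$truth$decoy_genes, collapse = ",")
  tr$tissue_variance_fraction <- sim$truth$tissue_variance_fraction
  write_tsv(tr, file.path(dir, "ground_truth.tsv"))
  invisible(dir)
}
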