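#' @name pipeline
#' @title Config-driven end-to-end pipeline
#'
#' @description
#' [run_pipeline()] executes the whole biomarker-discovery workflow from a
#' YAML (or list) configuration: simulate or load a screen, QC, tissue
#' correction, per-drug model fitting per modality, null-model-based
#' informative selection, feature rank aggregation and stability, drug-set
#' enrichment, and cancer-type context mapping. Every stage writes its
#' tables under `output_dir` and the run ends with a machine-readable
#' `manifest.json` (config hash, seed, per-stage row counts, file list).
#' Re-running with an identical config and seed reproduces all outputs
#' bit-identically.
NULL

default_pipeline_config <- function() {
  list(
    seed = 1L,
    modalities = c("raw", "zscore"),
    qc = list(min_drug_coverage = 0.10),
    model = list(alpha = 0, folds = 10, repeats = 10, nlambda = 50),
    select = list(n_nulls = 10, spread = "sd"),
    features = list(k = 10, min_fraction = 0.25,
                    raw_modality = "raw", corrected_modality = "zscore"),
    enrich = list(n_perm = 2000, max_features = 10, modality = "zscore",
                  min_pathway_size = 2, weight_exponent = 1,
                  alternative = "directional"),
    context = list(min_n = 3, heatmap_min_n = 10, family = "global"),
    simulate = list()
  )
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]))
      base[[k]] <- merge_config(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

stage_log <- function(stage, rows_in, rows_out, t0) {
  message(sprintf("[%s] rows_in=%s rows_out=%s elapsed=%.1fs", stage,
                  rows_in, rows_out, as.numeric(Sys.time()) - t0))
}

ranks_from_coefficients <- function(coefs) {
  out <- list()
  for (m in unique(coefs$modality)) {
    cm <- coefs[coefs$modality == m, , drop = FALSE]
    for (d in unique(cm$drug_id)) {
      cd <- cm[cm$drug_id == d, , drop = FALSE]
      agg <- aggregate(weight ~ gene, cd, mean)
      ord <- order(-abs(agg$weight), agg$gene, method = "radix")
      rk <- integer(nrow(agg)); rk[ord] <- seq_len(nrow(agg))
      out[[length(out) + 1L]] <- data.frame(
        drug_id = d, modality = m, gene = agg$gene, weight = agg$weight,
        rank = rk, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Run the biomarker-discovery pipeline
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#'   Must define `output_dir` and either `inputs` (paths `expression`,
#'   `samples`, `response`, `drugs`) or `simulate` settings (arguments of
#'   [simulation_config()]); all other keys have defaults. `seed` drives
#'   every stochastic step.
#' @param stages Optional subset of
#'   `c("simulate","qc","correct","fit","select","features","enrich","context")`
#'   to run; later entry points reload what they need from `output_dir`.
#' @return Invisibly, the manifest list (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, stages = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a path or a list")
  if (is.null(config$output_dir))
    stop("config error: `output_dir` is required")
  cfg <- merge_config(default_pipeline_config(), config)
  all_stages <- c("simulate", "qc", "correct", "fit", "select", "features",
                  "enrich", "context")
  stages <- stages %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  out_dir <- cfg$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- new.env(parent = emptyenv())
  manifest_rows <- list()
  p <- function(...) file.path(out_dir, ...)

  ensure_dataset <- function() {
    if (!is.null(st$ds)) return(st$ds)
    dir <- if (file.exists(p("dataset_qc", "expression.tsv")))
      p("dataset_qc") else p("dataset")
    if (!file.exists(file.path(dir, "expression.tsv")))
      stop("no dataset available; run the simulate/qc stages first")
    st$ds <- load_screen_dataset(file.path(dir, "expression.tsv"),
                                 file.path(dir, "samples.tsv"),
                                 file.path(dir, "response.tsv"),
                                 file.path(dir, "drugs.tsv"))
    st$ds
  }
  ensure_table <- function(name, file) {
    if (!is.null(st[[name]])) return(st[[name]])
    if (!file.exists(p(file)))
      stop(sprintf("missing %s; run earlier stages first", file))
    st[[name]] <- read_tsv(p(file))
    st[[name]]
  }

  run_stage <- function(stage, fun) {
    t0 <- as.numeric(Sys.time())
    res <- tryCatch(fun(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
    stage_log(stage, res$rows_in, res$rows_out, t0)
    manifest_rows[[stage]] <<- list(rows_in = res$rows_in,
                                    rows_out = res$rows_out)
  }

  if ("simulate" %in% stages) run_stage("simulate", function() {
    if (!is.null(cfg$inputs)) {
      st$ds <- load_screen_dataset(cfg$inputs$expression, cfg$inputs$samples,
                                   cfg$inputs$response, cfg$inputs$drugs)
      write_screen_dataset(st$ds, p("dataset"))
      list(rows_in = NA, rows_out = nrow(st$ds$samples))
    } else {
      sim_args <- cfg$simulate
      if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
      if (!is.null(sim_args$biomarkers))
        sim_args$biomarkers <- as.data.frame(sim_args$biomarkers,
                                             stringsAsFactors = FALSE)
      scfg <- do.call(simulation_config, sim_args)
      sim <- if (isTRUE(cfg$simulate$null)) {
        scfg2 <- scfg; simulate_null_screen(scfg)
      } else simulate_screen(scfg)
      st$ds <- sim$dataset; st$truth <- sim$truth
      write_simulated_screen(sim, p("dataset"))
      yaml::write_yaml(cfg, p("config_resolved.yaml"))
      list(rows_in = NA, rows_out = nrow(st$ds$samples))
    }
  })

  if ("qc" %in% stages) run_stage("qc", function() {
    ds <- ensure_dataset()
    n_in <- nrow(ds$samples)
    qc <- apply_qc_filters(ds, cfg$qc$min_drug_coverage)
    st$ds <- qc$dataset
    write_screen_dataset(st$ds, p("dataset_qc"))
    dl <- qc$report$dropped_lines
    dd <- qc$report$dropped_drugs
    drops <- rbind(
      data.frame(id = dl$cell_line_id,
                 axis = rep("cell_line", nrow(dl)),
                 reason = dl$reason, stringsAsFactors = FALSE),
      data.frame(id = dd$drug_id, axis = rep("drug", nrow(dd)),
                 reason = dd$reason, stringsAsFactors = FALSE))
    write_tsv(drops, p("qc_report.tsv"))
    list(rows_in = n_in, rows_out = nrow(st$ds$samples))
  })

  if ("correct" %in% stages) run_stage("correct", function() {
    ds <- ensure_dataset()
    tiss <- tissue_map(ds)
    st$matrices <- list(raw = ds$expression)
    sep <- list(data.frame(modality = "raw",
                           score = tissue_separation_score(ds$expression, tiss),
                           stringsAsFactors = FALSE))
    for (m in intersect(cfg$modalities, c("zscore", "residual"))) {
      cm <- if (m == "zscore") zscore_by_tissue(ds$expression, tiss)
            else residual_correct(ds$expression, tiss)
      st$matrices[[m]] <- cm$values
      write_corrected_matrix(cm, p(sprintf("corrected_%s.tsv", m)),
                             p(sprintf("stratum_stats_%s.tsv", m)))
      sep[[length(sep) + 1L]] <- data.frame(
        modality = m, score = tissue_separation_score(cm$values, tiss),
        stringsAsFactors = FALSE)
    }
    sep <- do.call(rbind, sep)
    write_tsv(sep, p("separation.tsv"))
    list(rows_in = nrow(ds$expression), rows_out = nrow(sep))
  })

  if ("fit" %in% stages) run_stage("fit", function() {
    ds <- ensure_dataset()
    spec <- model_spec(alpha = cfg$model$alpha, folds = cfg$model$folds,
                       repeats = cfg$model$repeats,
                       nlambda = cfg$model$nlambda, seed = cfg$seed)
    st$msets <- list()
    coef_rows <- list(); pred_rows <- list()
    for (m in cfg$modalities) {
      # Corrected modalities re-estimate the correction inside CV folds;
      # only uncorrected matrices may be passed through pre-built.
      x <- if (m %in% c("raw", "tissue_labels")) st$matrices[[m]] else NULL
      ms <- fit_drug_models(ds, m, spec, x = x)
      st$msets[[m]] <- ms
      for (d in names(ms$drugs)) {
        md <- ms$drugs[[d]]
        for (r in seq_len(nrow(md$coefficients))) {
          coef_rows[[length(coef_rows) + 1L]] <- data.frame(
            drug_id = d, modality = m, run = r,
            gene = colnames(md$coefficients),
            weight = md$coefficients[r, ], stringsAsFactors = FALSE)
          pred_rows[[length(pred_rows) + 1L]] <- data.frame(
            drug_id = d, modality = m, run = r,
            cell_line_id = colnames(md$predictions),
            y = unname(md$observed), y_hat = md$predictions[r, ],
            stringsAsFactors = FALSE)
        }
      }
    }
    st$perf <- summarize_performance(st$msets)
    write_tsv(st$perf, p("performance.tsv"))
    st$coefficients <- do.call(rbind, coef_rows)
    write_tsv(st$coefficients, p("coefficients.tsv"))
    write_tsv(do.call(rbind, pred_rows), p("predictions.tsv"))
    st$ranks <- rank_features(st$msets)
    write_tsv(st$ranks, p("ranks.tsv"))
    list(rows_in = nrow(ds$response), rows_out = nrow(st$perf))
  })

  if ("select" %in% stages) run_stage("select", function() {
    ds <- ensure_dataset()
    perf <- ensure_table("perf", "performance.tsv")
    spec <- model_spec(alpha = cfg$model$alpha, folds = cfg$model$folds,
                       repeats = 1, nlambda = cfg$model$nlambda,
                       seed = cfg$seed)
    st$nulls <- list()
    null_rows <- list()
    for (m in cfg$modalities) {
      x <- if (m %in% c("raw", "tissue_labels")) st$matrices[[m]] else NULL
      nd <- build_null_distribution(ds, m, spec, cfg$select$n_nulls, x = x)
      st$nulls[[m]] <- nd
      for (d in names(nd$per_drug))
        null_rows[[length(null_rows) + 1L]] <- data.frame(
          drug_id = d, modality = m, null = seq_along(nd$per_drug[[d]]),
          p_w = nd$per_drug[[d]], stringsAsFactors = FALSE)
    }
    write_tsv(do.call(rbind, null_rows), p("null_performance.tsv"))
    sel <- select_informative_models(perf, st$nulls, cfg$select$spread,
                                     drugs = ds$drugs)
    st$informative <- sel
    write_tsv(attr(sel, "thresholds"), p("thresholds.tsv"))
    write_tsv(as.data.frame(sel), p("informative.tsv"))
    list(rows_in = nrow(perf), rows_out = sum(sel$informative, na.rm = TRUE))
  })

  if ("features" %in% stages) run_stage("features", function() {
    ds <- ensure_dataset()
    if (is.null(st$ranks)) {
      coefs <- ensure_table("coefficients", "coefficients.tsv")
      st$ranks <- ranks_from_coefficients(coefs)
    }
    sel <- ensure_table("informative_df", "informative.tsv")
    inf_drugs <- sel$drug_id[which(sel$informative)]
    corrected <- cfg$features$corrected_modality
    rawmod <- cfg$features$raw_modality
    rk_cor <- st$ranks[st$ranks$modality == corrected &
                         st$ranks$drug_id %in% inf_drugs, , drop = FALSE]
    ann <- ds$drugs[ds$drugs$drug_id %in% inf_drugs, , drop = FALSE]
    ps <- pathway_feature_summary(rk_cor, ann, cfg$features$min_fraction,
                                  cfg$features$k)
    write_tsv(ps$summary, p("pathway_summary.tsv"))
    write_tsv(ps$recurrent, p("recurrent.tsv"))
    st$recurrent <- ps$recurrent
    rk_raw <- st$ranks[st$ranks$modality == rawmod &
                         st$ranks$drug_id %in% inf_drugs, , drop = FALSE]
    if (nrow(rk_raw) && nrow(rk_cor)) {
      rep_ <- stability_report(ds, rk_raw, rk_cor, cfg$features$k)
      st$stability <- rep_
      write_tsv(rep_$genes, p("stability.tsv"))
      write_tsv(rep_$pathways, p("stability_pathways.tsv"))
    }
    list(rows_in = length(inf_drugs), rows_out = nrow(ps$recurrent))
  })

  if ("enrich" %in% stages) run_stage("enrich", function() {
    ds <- ensure_dataset()
    if (is.null(st$ranks)) {
      coefs <- ensure_table("coefficients", "coefficients.tsv")
      st$ranks <- ranks_from_coefficients(coefs)
    }
    sel <- ensure_table("informative_df", "informative.tsv")
    inf_drugs <- sel$drug_id[which(sel$informative)]
    feats <- cfg$enrich$features
    if (is.null(feats)) {
      rec <- if (!is.null(st$recurrent)) st$recurrent else
        ensure_table("recurrent", "recurrent.tsv")
      feats <- head(unique(rec$gene), cfg$enrich$max_features)
    }
    if (length(feats) == 0L) {
      write_tsv(data.frame(), p("enrichment.tsv"))
      return(list(rows_in = 0, rows_out = 0))
    }
    rk <- st$ranks[st$ranks$drug_id %in% inf_drugs, , drop = FALSE]
    er <- run_feature_pathway_enrichment(
      feats, rk, ds$drugs[ds$drugs$drug_id %in% inf_drugs, , drop = FALSE],
      modality = cfg$enrich$modality, n_perm = cfg$enrich$n_perm,
      seed = cfg$seed, weight_exponent = cfg$enrich$weight_exponent,
      alternative = cfg$enrich$alternative,
      min_pathway_size = cfg$enrich$min_pathway_size)
    er$seed <- cfg$seed
    write_tsv(as.data.frame(er), p("enrichment.tsv"))
    st$enrichment <- er
    list(rows_in = length(feats), rows_out = nrow(er))
  })

  if ("context" %in% stages) run_stage("context", function() {
    ds <- ensure_dataset()
    sel <- ensure_table("informative_df", "informative.tsv")
    inf_drugs <- sel$drug_id[which(sel$informative)]
    genes <- cfg$context$genes
    if (is.null(genes)) {
      rec <- if (!is.null(st$recurrent)) st$recurrent else
        ensure_table("recurrent", "recurrent.tsv")
      genes <- unique(rec$gene)
    }
    genes <- intersect(genes, colnames(ds$expression))
    if (length(genes) == 0L || length(inf_drugs) == 0L) {
      write_tsv(data.frame(), p("context_correlations.tsv"))
      return(list(rows_in = 0, rows_out = 0))
    }
    tab <- per_type_drug_gene_correlations(ds, genes, inf_drugs,
                                           min_n = cfg$context$min_n,
                                           family = cfg$context$family)
    write_tsv(tab, p("context_correlations.tsv"))
    hm <- heatmap_matrix(tab, cfg$context$heatmap_min_n)
    hm_df <- data.frame(pair = rownames(hm), hm, check.names = FALSE)
    write_tsv(hm_df, p("context_heatmap.tsv"))
    st$context <- tab
    list(rows_in = length(genes) * length(inf_drugs), rows_out = nrow(tab))
  })

  manifest <- list(
    package = "panscreen",
    version = as.character(packageVersion("panscreen")),
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    stages = manifest_rows,
    files = sort(list.files(out_dir, recursive = TRUE)))
  manifest$files <- setdiff(manifest$files, "manifest.json")
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
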