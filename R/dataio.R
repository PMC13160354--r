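#' Assemble a drug-screen dataset
#'
#' Bundles the four tables of a pharmacogenomic screen into a single object:
#' a log2-scale basal expression matrix (cell lines in rows, genes in
#' columns), per-line annotations (cancer type and solid/non-solid class), a
#' long-format drug-response table (AUC of the dose-response curve, lower =
#' more sensitive), and drug-to-target-pathway annotations.
#'
#' Identifiers are opaque, case-sensitive strings and are never normalized;
#' mismatches between tables are surfaced by [apply_qc_filters()], not
#' repaired here.
#'
#' @param expression Numeric matrix, rownames = cell line ids, colnames =
#'   gene ids. Missing values are not allowed.
#' @param samples Data frame with columns `cell_line_id`, `cancer_type`,
#'   `tumor_class` (values `"solid"` or `"non_solid"`).
#' @param response Data frame with columns `cell_line_id`, `drug_id`, `auc`.
#'   `auc` may be `NA` (screened but unusable record); such rows are excluded
#'   from model training by downstream code.
#' @param drugs Data frame with columns `drug_id`, `pathway`.
#' @return An object of class `screen_dataset`.
#' @seealso [load_screen_dataset()], [apply_qc_filters()], [simulate_screen()]
#' @export
screen_dataset <- function(expression, samples, response, drugs) {
  if (!is.matrix(expression) || !is.numeric(expression))
    stop("`expression` must be a numeric matrix")
  if (is.null(rownames(expression)) || is.null(colnames(expression)))
    stop("`expression` must have cell line rownames and gene colnames")
  if (any(!is.finite(expression)))
    stop("`expression` contains missing or non-finite values; the input matrix must be complete")
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(sprintf("%s table is missing column(s): %s", what,
                   paste(miss, collapse = ", ")))
  }
  need(samples, c("cell_line_id", "cancer_type", "tumor_class"), "samples")
  need(response, c("cell_line_id", "drug_id", "auc"), "response")
  need(drugs, c("drug_id", "pathway"), "drugs")
  if (anyDuplicated(samples$cell_line_id))
    stop("duplicated cell_line_id in samples table")
  key <- paste(response$cell_line_id, response$drug_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- response[duplicated(key), , drop = FALSE]
    stop(sprintf("duplicated (cell_line_id, drug_id) response rows, e.g. (%s, %s)",
                 dup$cell_line_id[1], dup$drug_id[1]))
  }
  if (!is.numeric(response$auc))
    stop("response `auc` column must be numeric")
  structure(
    list(expression = expression,
         samples = samples[, c("cell_line_id", "cancer_type", "tumor_class")],
         response = response[, c("cell_line_id", "drug_id", "auc")],
         drugs = drugs[, c("drug_id", "pathway")]),
    class = "screen_dataset")
}

#' @export
print.screen_dataset <- function(x, ...) {
  cat("screen_dataset\n")
  cat(sprintf("  expression: %d cell lines x %d genes\n",
              nrow(x$expression), ncol(x$expression)))
  cat(sprintf("  samples:    %d lines, %d cancer types (%d non-solid lines)\n",
              nrow(x$samples), length(unique(x$samples$cancer_type)),
              sum(x$samples$tumor_class == "non_solid")))
  cat(sprintf("  response:   %d records, %d drugs (%d missing AUC)\n",
              nrow(x$response), length(unique(x$response$drug_id)),
              sum(is.na(x$response$auc))))
  cat(sprintf("  drugs:      %d annotated, %d pathways\n",
              nrow(x$drugs), length(unique(x$drugs$pathway))))
  invisible(x)
}

#' Map cell line ids to cancer types
#'
#' @param ds A `screen_dataset`.
#' @return Named character vector, names = cell line ids.
#' @export
tissue_map <- function(ds) {
  setNames(as.character(ds$samples$cancer_type), ds$samples$cell_line_id)
}

parse_numeric_column <- function(x, what, allow_na = FALSE) {
  raw <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(raw))
  missing <- raw == "" | toupper(raw) == "NA"
  bad <- which(is.na(out) & !missing)
  if (length(bad))
    stop(sprintf("could not parse %s as a number at data row %d (value '%s')",
                 what, bad[1], raw[bad[1]]))
  if (!allow_na && any(missing))
    stop(sprintf("missing value not allowed in %s at data row %d",
                 what, which(missing)[1]))
  out
}

#' Load a screen dataset from tab-delimited files
#'
#' Reads the four TSV inputs (header row, UTF-8). Schemas: expression =
#' `cell_line_id` plus one numeric column per gene; samples =
#' `cell_line_id`, `cancer_type`, `tumor_class`; response = `cell_line_id`,
#' `drug_id`, `auc`; drugs = `drug_id`, `pathway`. An empty or `"NA"` AUC
#' field is loaded as a missing-response record; missing expression values
#' are an error. Row and column order is preserved.
#'
#' @param expression_path,samples_path,response_path,drugs_path File paths.
#' @return A `screen_dataset` (no QC applied).
#' @export
load_screen_dataset <- function(expression_path, samples_path,
                                response_path, drugs_path) {
  for (p in c(expression_path, samples_path, response_path, drugs_path))
    if (!file.exists(p)) stop("input file does not exist: ", p)

  expr_df <- read.delim(expression_path, sep = "\t", check.names = FALSE,
                        stringsAsFactors = FALSE, colClasses = "character")
  if (!"cell_line_id" %in% names(expr_df))
    stop("expression table is missing column(s): cell_line_id")
  if (ncol(expr_df) < 2L) stop("expression table has no gene columns")
  genes <- setdiff(names(expr_df), "cell_line_id")
  expression <- vapply(genes, function(g)
    parse_numeric_column(expr_df[[g]], sprintf("expression gene '%s'", g)),
    numeric(nrow(expr_df)))
  expression <- matrix(expression, nrow = nrow(expr_df),
                       dimnames = list(expr_df$cell_line_id, genes))

  samples <- read_tsv(samples_path)
  response <- read.delim(response_path, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("cell_line_id", "drug_id", "auc") %in% names(response))) {
    miss <- setdiff(c("cell_line_id", "drug_id", "auc"), names(response))
    stop("response table is missing column(s): ", paste(miss, collapse = ", "))
  }
  response$auc <- parse_numeric_column(response$auc, "response auc",
                                       allow_na = TRUE)
  drugs <- read_tsv(drugs_path)
  screen_dataset(expression, samples, response, drugs)
}

#' Write a screen dataset as four TSV files
#'
#' Inverse of [load_screen_dataset()]: writes `expression.tsv`,
#' `samples.tsv`, `response.tsv`, `drugs.tsv` under `dir`.
#'
#' @param ds A `screen_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the four file paths.
#' @export
write_screen_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  expr_df <- data.frame(cell_line_id = rownames(ds$expression),
                        ds$expression, check.names = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             samples = file.path(dir, "samples.tsv"),
             response = file.path(dir, "response.tsv"),
             drugs = file.path(dir, "drugs.tsv"))
  write_tsv(expr_df, paths["expression"])
  write_tsv(ds$samples, paths["samples"])
  write_tsv(ds$response, paths["response"])
  write_tsv(ds$drugs, paths["drugs"])
  invisible(paths)
}

#' Apply screen quality-control filters
#'
#' Filtering is two-staged with a fixed, documented order. First, cell lines
#' lacking full information are dropped: a line must have an expression
#' profile, a sample annotation, and at least one non-missing AUC record.
#' Second, drugs are dropped when screened (non-missing AUC) in fewer than
#' `min_drug_coverage` of the retained cell lines, or screened in exactly
#' one cancer type. Finally, lines left with no responses to the retained
#' drugs are swept so that every surviving line keeps at least one usable
#' record; this sweep makes the filter idempotent. Every drop is recorded
#' with its reason.
#'
#' The coverage denominator is the number of cell lines retained after the
#' line-level filter, not the raw input count.
#'
#' @param ds A `screen_dataset`.
#' @param min_drug_coverage Fraction in (0,1); default 0.10.
#' @return A list with elements `dataset` (filtered `screen_dataset`) and
#'   `report` (a `qc_report`).
#' @export
apply_qc_filters <- function(ds, min_drug_coverage = 0.10) {
  stopifnot(inherits(ds, "screen_dataset"))
  if (!is.numeric(min_drug_coverage) || min_drug_coverage <= 0 ||
      min_drug_coverage >= 1)
    stop("min_drug_coverage must lie in (0, 1)")

  all_lines <- unique(c(rownames(ds$expression), ds$samples$cell_line_id,
                        ds$response$cell_line_id))
  usable <- ds$response[!is.na(ds$response$auc), , drop = FALSE]
  has_expr <- all_lines %in% rownames(ds$expression)
  has_annot <- all_lines %in% ds$samples$cell_line_id
  has_resp <- all_lines %in% usable$cell_line_id

  dropped_lines <- data.frame(cell_line_id = character(), reason = character(),
                              stringsAsFactors = FALSE)
  add_line_drop <- function(ids, reason) {
    if (length(ids))
      dropped_lines <<- rbind(dropped_lines,
                              data.frame(cell_line_id = ids, reason = reason,
                                         stringsAsFactors = FALSE))
  }
  add_line_drop(all_lines[!has_expr], "missing expression")
  add_line_drop(all_lines[has_expr & !has_annot], "missing annotation")
  add_line_drop(all_lines[has_expr & has_annot & !has_resp],
                "no usable response records")
  keep_lines <- all_lines[has_expr & has_annot & has_resp]
  if (length(keep_lines) == 0L) stop("no data survives QC: all cell lines dropped")

  usable <- usable[usable$cell_line_id %in% keep_lines, , drop = FALSE]
  n_lines <- length(keep_lines)
  ttype <- tissue_map(ds)

  all_drugs <- unique(ds$response$drug_id)
  cov <- table(factor(usable$drug_id, levels = all_drugs))
  n_types <- vapply(all_drugs, function(d) {
    length(unique(ttype[usable$cell_line_id[usable$drug_id == d]]))
  }, integer(1))
  low_cov <- as.vector(cov) < min_drug_coverage * n_lines
  one_type <- n_types == 1L
  dropped_drugs <- data.frame(drug_id = character(), reason = character(),
                              stringsAsFactors = FALSE)
  if (any(low_cov))
    dropped_drugs <- rbind(dropped_drugs, data.frame(
      drug_id = all_drugs[low_cov],
      reason = sprintf("screened in fewer than %.0f%% of cell lines",
                       100 * min_drug_coverage), stringsAsFactors = FALSE))
  if (any(one_type & !low_cov))
    dropped_drugs <- rbind(dropped_drugs, data.frame(
      drug_id = all_drugs[one_type & !low_cov],
      reason = "screened in only one cancer type", stringsAsFactors = FALSE))
  keep_drugs <- setdiff(all_drugs, dropped_drugs$drug_id)
  if (length(keep_drugs) == 0L) stop("no data survives QC: all drugs dropped")

  # Sweep lines orphaned by the drug filter so every line keeps >=1 record.
  usable <- usable[usable$drug_id %in% keep_drugs, , drop = FALSE]
  orphan <- setdiff(keep_lines, unique(usable$cell_line_id))
  add_line_drop(orphan, "no responses to retained drugs")
  keep_lines <- setdiff(keep_lines, orphan)
  if (length(keep_lines) == 0L) stop("no data survives QC: all cell lines dropped")

  response <- ds$response[ds$response$cell_line_id %in% keep_lines &
                            ds$response$drug_id %in% keep_drugs, , drop = FALSE]
  out <- screen_dataset(
    expression = ds$expression[rownames(ds$expression) %in% keep_lines, ,
                               drop = FALSE],
    samples = ds$samples[ds$samples$cell_line_id %in% keep_lines, ,
                         drop = FALSE],
    response = response,
    drugs = ds$drugs[ds$drugs$drug_id %in% keep_drugs, , drop = FALSE])
  missing_annot <- setdiff(unique(response$drug_id), ds$drugs$drug_id)
  if (length(missing_annot))
    stop("response contains drug(s) absent from the drug annotation table: ",
         paste(missing_annot, collapse = ", "))

  report <- structure(
    list(n_lines_in = length(all_lines), n_lines_out = length(keep_lines),
         n_drugs_in = length(all_drugs), n_drugs_out = length(keep_drugs),
         dropped_lines = dropped_lines, dropped_drugs = dropped_drugs,
         min_drug_coverage = min_drug_coverage),
    class = "qc_report")
  list(dataset = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report\n")
  cat(sprintf("  cell lines: %d -> %d (%d dropped)\n", x$n_lines_in,
              x$n_lines_out, nrow(x$dropped_lines)))
  cat(sprintf("  drugs:      %d -> %d (%d dropped, coverage < %.0f%% or single cancer type)\n",
              x$n_drugs_in, x$n_drugs_out, nrow(x$dropped_drugs),
              100 * x$min_drug_coverage))
  invisible(x)
}
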