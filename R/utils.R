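# Internal helpers shared across the pipeline.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library code never clobbers user seeds.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

# Deterministic derived seeds, kept strictly below 2^31 - 1.
derive_seed <- function(base, ...) {
  idx <- c(...)
  s <- as.double(base) %% 2147483647
  for (k in idx) {
    s <- (s * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(s)
}

clamp_cor <- function(r, eps = 1e-12) {
  pmin(pmax(r, -1 + eps), 1 - eps)
}

# Fisher-z mean of correlations; NA values dropped, NA if none remain.
fisher_mean <- function(r) {
  r <- r[!is.na(r)]
  if (length(r) == 0L) return(NA_real_)
  tanh(mean(atanh(clamp_cor(r))))
}

# Column standardization with sample (n-1) standard deviation. Constant
# columns get scale 1 so they standardize to all-zero rather than NaN.
standardize_columns <- function(X, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(X)
  Xc <- sweep(X, 2L, center, "-")
  if (is.null(scale)) {
    scale <- sqrt(colSums(Xc^2) / max(1, nrow(X) - 1L))
    scale[scale == 0] <- 1
  }
  list(x = sweep(Xc, 2L, scale, "/"), center = center, scale = scale)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE, colClasses = NA, ...)
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
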