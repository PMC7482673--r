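# Fixtures built in code: tiny expression tables, CSV writers and a raw
# feature-table wrapper for the clustering/similarity/inference tests.

# small expression table: m = rows x proteins matrix, meta = data.frame
make_table <- function(m, meta = NULL, proteins = colnames(m)) {
  if (is.null(proteins)) proteins <- paste0("P", seq_len(ncol(m)))
  colnames(m) <- proteins
  df <- as.data.frame(m)
  meta_cols <- character()
  if (!is.null(meta)) {
    df <- cbind(meta, df)
    meta_cols <- stats::setNames(names(meta), names(meta))
  }
  expression_table(df, proteins, meta_cols)
}

# wrap a bare numeric matrix as a feature_table of sum features
make_feature_table <- function(m, meta = NULL, kinds = rep("sum", ncol(m))) {
  if (is.null(colnames(m))) colnames(m) <- paste0("F", seq_len(ncol(m)))
  specs <- lapply(seq_len(ncol(m)), function(j) {
    if (kinds[j] == "sum") {
      feature_spec(colnames(m)[j], "sum", colnames(m)[j])
    } else {
      feature_spec(colnames(m)[j], "index", "A", "B")
    }
  })
  df <- as.data.frame(m)
  meta_cols <- character()
  if (!is.null(meta)) {
    df <- cbind(meta, df)
    meta_cols <- names(meta)
  }
  structure(df,
            specs = specs,
            metadata_fields = meta_cols,
            feature_names = colnames(m),
            class = c("feature_table", "data.frame"))
}

write_csv_fixture <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# two well-separated 2-D Gaussian blobs
make_blobs <- function(n_per = 30, sep = 20, sd = 1, seed = 1) {
  set.seed(seed)
  coords <- rbind(
    cbind(rnorm(n_per, 0, sd), rnorm(n_per, 0, sd)),
    cbind(rnorm(n_per, sep, sd), rnorm(n_per, 0, sd)))
  list(coords = coords, label = rep(1:2, each = n_per))
}

# hand-rolled adjusted Rand index used as a cross-check against mclust
rand_adjusted <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n2
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}
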