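# Reading, validating and preprocessing protein expression tables.
#
# The central container is the `expression_table`: a data.frame whose first
# columns are sample metadata (kept as character) and whose remaining columns
# are nonnegative protein densitometry values (NA = missing), with attributes
# recording which columns play which role.

#' Construct an expression table from a data frame
#'
#' An `expression_table` is a data.frame carrying sample metadata columns
#' (case id, age label, rearing condition, cortical region, replicate run --
#' any subset) followed by one numeric column per protein. Protein values are
#' nonnegative or `NA`; metadata rows must be unique so that each
#' (case, region, run) combination appears once.
#'
#' @param df data.frame holding both metadata and protein columns.
#' @param protein_columns character vector of protein column names, in panel
#'   order.
#' @param metadata_columns character vector of metadata column names. Names of
#'   the vector, if given, declare roles, e.g.
#'   `c(case_id = "Case", region = "Region", run = "Run")`; unnamed entries
#'   keep the column name as the role.
#' @return An object of class `expression_table`.
#' @export
expression_table <- function(df, protein_columns, metadata_columns = character()) {
  stopifnot(is.data.frame(df))
  roles <- names(metadata_columns)
  if (is.null(roles)) roles <- rep("", length(metadata_columns))
  roles[roles == ""] <- metadata_columns[roles == ""]

  absent <- setdiff(c(metadata_columns, protein_columns), names(df))
  if (length(absent) > 0) {
    stop("declared column(s) absent from input: ", paste(absent, collapse = ", "))
  }
  if (anyDuplicated(protein_columns)) {
    stop("protein_names contains duplicates")
  }

  meta <- df[, metadata_columns, drop = FALSE]
  names(meta) <- roles
  meta[] <- lapply(meta, as.character)
  prot <- df[, protein_columns, drop = FALSE]
  prot[] <- lapply(prot, function(x) as.numeric(as.character(x)))
  bad <- vapply(prot, function(x) any(x < 0, na.rm = TRUE), logical(1))
  if (any(bad)) {
    stop("negative protein values in column(s): ",
         paste(protein_columns[bad], collapse = ", "))
  }
  if (ncol(meta) > 0 && anyDuplicated(meta)) {
    stop("duplicate metadata keys (case/region/run combinations must be unique)")
  }

  out <- cbind(meta, prot)
  rownames(out) <- NULL
  structure(out,
            protein_names = protein_columns,
            metadata_fields = roles,
            class = c("expression_table", "data.frame"))
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table: %d rows, %d proteins, %d metadata fields\n",
              nrow(x), length(protein_names(x)), length(metadata_fields(x))))
  cat("proteins: ", paste(protein_names(x), collapse = ", "), "\n", sep = "")
  if (length(metadata_fields(x)) > 0) {
    cat("metadata: ", paste(metadata_fields(x), collapse = ", "), "\n", sep = "")
  }
  m <- protein_matrix(x)
  cat(sprintf("observed cells: %d of %d (%d missing)\n",
              sum(!is.na(m)), length(m), sum(is.na(m))))
  invisible(x)
}

#' Accessors for expression tables
#'
#' `protein_names()` returns the ordered protein panel, `metadata_fields()`
#' the metadata roles, `protein_matrix()` the numeric n x p value matrix and
#' `metadata()` the metadata columns as a data.frame.
#'
#' @param x An `expression_table` (or `feature_table` where noted).
#' @return Character vector, numeric matrix or data.frame as described.
#' @export
protein_names <- function(x) attr(x, "protein_names")

#' @rdname protein_names
#' @export
metadata_fields <- function(x) attr(x, "metadata_fields")

#' @rdname protein_names
#' @export
protein_matrix <- function(x) {
  as.matrix(as.data.frame(x)[, protein_names(x), drop = FALSE])
}

#' @rdname protein_names
#' @export
metadata <- function(x) {
  as.data.frame(x)[, metadata_fields(x), drop = FALSE]
}

# tokens treated as missing when parsing protein cells (case-insensitive)
.missing_tokens <- c("", "na", "nan")

#' Read an expression table from CSV
#'
#' Parses an RFC 4180 CSV with a header row. Declared protein cells that are
#' empty, `"NA"`, `"NaN"` (case-insensitive) or otherwise non-numeric become
#' missing values; metadata is preserved verbatim as character.
#'
#' @param path path to the CSV file.
#' @inheritParams expression_table
#' @return An `expression_table` preserving the file's row order.
#' @export
read_expression_table <- function(path, protein_columns, metadata_columns = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  absent <- setdiff(c(metadata_columns, protein_columns), names(raw))
  if (length(absent) > 0) {
    stop("declared column(s) absent from ", path, ": ",
         paste(absent, collapse = ", "))
  }
  for (pc in protein_columns) {
    x <- trimws(raw[[pc]])
    x[tolower(x) %in% .missing_tokens] <- NA_character_
    num <- suppressWarnings(as.numeric(x))
    raw[[pc]] <- num # non-parsable -> NA (missing, never 0)
  }
  expression_table(raw, protein_columns, metadata_columns)
}

#' Average replicate western-blot runs
#'
#' Collapses replicate runs to one row per remaining metadata combination
#' (typically case x region). Each protein cell becomes the arithmetic mean
#' over the runs in which it was observed; a cell stays missing only when it
#' is missing in every run. The run field is dropped. A table without a run
#' field is returned unchanged.
#'
#' @param table An `expression_table`.
#' @param run_field Name of the run metadata role (default `"run"`).
#' @return An `expression_table` with one row per averaged group.
#' @export
average_runs <- function(table, run_field = "run") {
  stopifnot(inherits(table, "expression_table"))
  mf <- metadata_fields(table)
  if (!run_field %in% mf) return(table)
  keys <- setdiff(mf, run_field)
  prot <- protein_matrix(table)
  meta <- metadata(table)

  if (length(keys) == 0) {
    key <- rep("all", nrow(table))
  } else {
    key <- do.call(paste, c(meta[keys], sep = "\r"))
  }
  key <- factor(key, levels = unique(key)) # preserve first-appearance order
  idx <- split(seq_len(nrow(prot)), key)

  avg <- t(vapply(idx, function(i) {
    colMeans(prot[i, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(prot))))
  avg[is.nan(avg)] <- NA_real_ # missing in all runs

  meta_out <- meta[vapply(idx, `[`, integer(1), 1), keys, drop = FALSE]
  out <- cbind(meta_out, as.data.frame(avg))
  names(out) <- c(keys, protein_names(table))
  expression_table(out, protein_names(table),
                   stats::setNames(keys, keys))
}

#' Impute missing cells by nearest neighbours
#'
#' Each missing cell is replaced by the mean of that protein over the `k`
#' nearest rows in which it was observed. Distances are Euclidean over the
#' mutually observed proteins after standardising each column (mean 0, sd 1,
#' computed over observed cells); distances are rescaled by the number of
#' shared columns so rows with different missingness patterns are comparable.
#' Observed values are never altered; ties in distance are broken by row
#' order, so the result is deterministic.
#'
#' @param table An `expression_table`.
#' @param k number of neighbours (default 10, capped at the number of
#'   available donor rows).
#' @return An `expression_table` with no missing cells.
#' @export
impute_missing <- function(table, k = 10) {
  stopifnot(inherits(table, "expression_table"), k >= 1)
  prot <- protein_matrix(table)
  if (!anyNA(prot)) return(table)

  all_missing <- rowSums(!is.na(prot)) == 0
  if (any(all_missing)) {
    keys <- apply(metadata(table)[all_missing, , drop = FALSE], 1, paste,
                  collapse = "/")
    stop("row(s) with all proteins missing: ", paste(keys, collapse = "; "))
  }
  never_seen <- colSums(!is.na(prot)) == 0
  if (any(never_seen)) {
    stop("protein(s) never observed: ",
         paste(protein_names(table)[never_seen], collapse = ", "))
  }

  mu <- colMeans(prot, na.rm = TRUE)
  sd_ <- apply(prot, 2, stats::sd, na.rm = TRUE)
  sd_[is.na(sd_) | sd_ == 0] <- 1
  z <- sweep(sweep(prot, 2, mu), 2, sd_, "/")

  filled <- prot
  for (i in which(rowSums(is.na(prot)) > 0)) {
    for (j in which(is.na(prot[i, ]))) {
      donors <- which(!is.na(prot[, j]) & seq_len(nrow(prot)) != i)
      d <- vapply(donors, function(r) {
        shared <- which(!is.na(z[i, ]) & !is.na(z[r, ]))
        if (length(shared) == 0) return(Inf)
        sqrt(sum((z[i, shared] - z[r, shared])^2) *
               ncol(prot) / length(shared))
      }, numeric(1))
      use <- donors[order(d)][seq_len(min(k, length(donors)))]
      filled[i, j] <- mean(prot[use, j])
    }
  }
  out <- cbind(metadata(table), as.data.frame(filled))
  names(out) <- c(metadata_fields(table), protein_names(table))
  expression_table(out, protein_names(table),
                   stats::setNames(metadata_fields(table), metadata_fields(table)))
}

#' Centre the protein matrix (no scaling)
#'
#' Subtracts column means from the protein matrix, yielding the input for
#' PCA. Columns are deliberately *not* divided by their standard deviation:
#' abundant proteins retain proportionally more variance, as in unscaled
#' (covariance-matrix) PCA.
#'
#' @param table An `expression_table` with no missing cells.
#' @return A `centered_matrix`: list with `values` (n x p, columns sum to 0),
#'   `column_means` and `protein_names`.
#' @export
center <- function(table) {
  stopifnot(inherits(table, "expression_table"))
  prot <- protein_matrix(table)
  if (anyNA(prot)) {
    stop("missing cells present; run average_runs() and/or impute_missing() first")
  }
  mu <- colMeans(prot)
  structure(list(values = sweep(prot, 2, mu),
                 column_means = mu,
                 protein_names = protein_names(table)),
            class = "centered_matrix")
}

#' @export
print.centered_matrix <- function(x, ...) {
  cat(sprintf("centered_matrix: %d x %d (column means removed, unscaled)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Matrix accounting summary
#'
#' Reports the row, cell and missing-cell counts of a table, in the style of
#' a design-size bookkeeping table (cases x regions x runs x proteins). Both
#' row and cell counts are reported; no attempt is made to reconcile them
#' against an external design.
#'
#' @param table An `expression_table`.
#' @return A list with `rows`, `proteins`, `cells`, `observed`, `missing`.
#' @export
accounting <- function(table) {
  m <- protein_matrix(table)
  list(rows = nrow(m), proteins = ncol(m), cells = length(m),
       observed = sum(!is.na(m)), missing = sum(is.na(m)))
}
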