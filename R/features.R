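# Plasticity features: sums over protein sets and bounded contrast indices
# between two protein sets, proposed from PCA diagnostics and validated
# against component scores.

#' Contrast index between two nonnegative quantities
#'
#' The normalised difference `(a - b) / (a + b)`: 0 at balance, +1 when `a`
#' dominates exclusively, -1 when `b` does. Antisymmetric and invariant to a
#' common positive scaling of both arguments, which is what makes it
#' comparable across blots, ages and species.
#'
#' @param a,b nonnegative numerics (vectorised).
#' @return Numeric in `[-1, 1]`; `NA` with a warning where `a + b == 0`.
#' @export
contrast_index <- function(a, b) {
  stopifnot(all(a >= 0, na.rm = TRUE), all(b >= 0, na.rm = TRUE))
  s <- a + b
  out <- (a - b) / s
  if (any(!is.na(s) & s == 0)) {
    warning("contrast_index undefined where a + b == 0; returning NA")
    out[!is.na(s) & s == 0] <- NA_real_
  }
  out
}

#' Declare a plasticity feature
#'
#' A feature is either a `sum` over a protein set or an `index`, the contrast
#' index between the sums of two disjoint protein sets.
#'
#' @param name feature label.
#' @param kind `"sum"` or `"index"`.
#' @param numerator nonempty character vector of proteins (the summed set for
#'   sums; the A-side for indices).
#' @param denominator character vector of proteins (B-side; empty iff sum).
#' @param provenance one of `"high_amplitude"`, `"a_priori"`, `"novel_pair"`,
#'   `"user"`.
#' @return A `feature_spec`.
#' @export
feature_spec <- function(name, kind = c("sum", "index"), numerator,
                         denominator = character(),
                         provenance = "user") {
  kind <- match.arg(kind)
  stopifnot(length(numerator) > 0)
  if (kind == "sum" && length(denominator) > 0) {
    stop("sum features take no denominator")
  }
  if (kind == "index" && length(denominator) == 0) {
    stop("index features need a denominator protein set")
  }
  if (length(intersect(numerator, denominator)) > 0) {
    stop("numerator and denominator must be disjoint in feature '", name, "'")
  }
  structure(list(name = name, kind = kind,
                 numerator = unname(numerator),
                 denominator = unname(denominator),
                 provenance = provenance),
            class = "feature_spec")
}

#' @export
print.feature_spec <- function(x, ...) {
  if (x$kind == "sum") {
    cat(sprintf("[sum]   %s = sum(%s)  (%s)\n", x$name,
                paste(x$numerator, collapse = "+"), x$provenance))
  } else {
    cat(sprintf("[index] %s = (A-B)/(A+B), A=%s, B=%s  (%s)\n", x$name,
                paste(x$numerator, collapse = "+"),
                paste(x$denominator, collapse = "+"), x$provenance))
  }
  invisible(x)
}

.check_specs <- function(specs, panel) {
  for (sp in specs) {
    unknown <- setdiff(c(sp$numerator, sp$denominator), panel)
    if (length(unknown) > 0) {
      stop("feature '", sp$name, "' references protein(s) not in panel: ",
           paste(unknown, collapse = ", "))
    }
  }
  invisible(specs)
}

#' Evaluate features over an expression table
#'
#' Computes one column per feature spec: sums are totals over the numerator
#' proteins; indices are `contrast_index(sum A, sum B)`. A sample's feature
#' is missing if any referenced protein is missing in that sample.
#'
#' @param table An `expression_table`.
#' @param specs list of `feature_spec`s.
#' @return A `feature_table`: data.frame of metadata plus one numeric column
#'   per feature, with the specs stored as an attribute.
#' @export
evaluate_features <- function(table, specs) {
  stopifnot(inherits(table, "expression_table"))
  if (inherits(specs, "feature_spec")) specs <- list(specs)
  .check_specs(specs, protein_names(table))
  prot <- protein_matrix(table)

  cols <- lapply(specs, function(sp) {
    a <- rowSums(prot[, sp$numerator, drop = FALSE])
    if (sp$kind == "sum") return(a)
    b <- rowSums(prot[, sp$denominator, drop = FALSE])
    suppressWarnings(contrast_index(a, b))
  })
  vals <- do.call(cbind, cols)
  colnames(vals) <- vapply(specs, `[[`, character(1), "name")

  out <- cbind(metadata(table), as.data.frame(vals, check.names = FALSE))
  rownames(out) <- NULL
  structure(out,
            specs = specs,
            metadata_fields = metadata_fields(table),
            feature_names = colnames(vals),
            class = c("feature_table", "data.frame"))
}

#' Accessors for feature tables
#'
#' @param x A `feature_table`.
#' @return `feature_specs()` the list of specs, `feature_names()` the feature
#'   labels, `feature_matrix()` the numeric n x m value matrix.
#' @export
feature_specs <- function(x) attr(x, "specs")

#' @rdname feature_specs
#' @export
feature_names <- function(x) attr(x, "feature_names")

#' @rdname feature_specs
#' @export
feature_matrix <- function(x) {
  as.matrix(as.data.frame(x)[, feature_names(x), drop = FALSE])
}

#' Propose candidate plasticity features from a fitted PCA
#'
#' Implements three heuristics over the retained dimensions:
#' \enumerate{
#'   \item high-amplitude sums: the all-protein sum, plus a sum for every
#'     user-declared protein class with at least one member whose
#'     `|var_coord|` exceeds the per-dimension amplitude threshold (the
#'     `amplitude_quantile` of that dimension's amplitudes) on some retained
#'     dimension;
#'   \item a-priori pairs: an index for every supplied pair present in the
#'     panel;
#'   \item novel pairs: an index for every protein pair that, on some
#'     retained dimension, both exceed the amplitude threshold with opposite
#'     signs (one rises as the other falls), oriented so the positive-loading
#'     protein is the numerator on that dimension.
#' }
#' Proposals are deduplicated by unordered protein-set identity (a-priori
#' listing wins over novel-pair discovery). The proposal is assistive: review
#' it (and its provenance tags) before evaluating.
#'
#' @param model A `pca_model`.
#' @param ndims retained dimension count (from [significant_dimensions()]).
#' @param protein_classes named list of protein sets (e.g.
#'   `list(GlutR = c(...), GABAAR = c(...))`) eligible for class sums and for
#'   a class-vs-class index when both classes qualify.
#' @param apriori_pairs list of length-2 character vectors of protein pairs.
#' @param amplitude_quantile quantile (default 0.75) of per-dimension
#'   `|var_coord|` defining "large amplitude".
#' @return List of `feature_spec`s.
#' @export
propose_features <- function(model, ndims, protein_classes = list(),
                             apriori_pairs = list(),
                             amplitude_quantile = 0.75) {
  stopifnot(inherits(model, "pca_model"))
  panel <- model$protein_names
  vc <- model$var_coords[, seq_len(ndims), drop = FALSE]
  thr <- apply(abs(vc), 2, stats::quantile, probs = amplitude_quantile,
               names = FALSE)
  high <- sweep(abs(vc), 2, thr, ">=") # protein x dim: large amplitude?

  specs <- list(feature_spec("Protein Sum", "sum", panel,
                             provenance = "high_amplitude"))
  qualifying <- character()
  for (cl in names(protein_classes)) {
    members <- intersect(protein_classes[[cl]], panel)
    if (length(members) > 0 && any(high[members, , drop = FALSE])) {
      qualifying <- c(qualifying, cl)
      specs <- c(specs, list(feature_spec(paste(cl, "Sum"), "sum", members,
                                          provenance = "high_amplitude")))
    }
  }
  if (length(qualifying) >= 2) {
    # class-vs-class balance (e.g. E:I) for the first two qualifying classes
    a <- intersect(protein_classes[[qualifying[1]]], panel)
    b <- intersect(protein_classes[[qualifying[2]]], panel)
    if (length(intersect(a, b)) == 0) {
      specs <- c(specs, list(feature_spec(
        paste0(qualifying[1], ":", qualifying[2]), "index", a, b,
        provenance = "a_priori")))
    }
  }

  seen <- lapply(specs, function(sp) sort(c(sp$numerator, sp$denominator)))
  add_unique <- function(sp) {
    key <- sort(c(sp$numerator, sp$denominator))
    if (!any(vapply(seen, identical, logical(1), key))) {
      specs[[length(specs) + 1]] <<- sp
      seen[[length(seen) + 1]] <<- key
    }
  }

  for (pr in apriori_pairs) {
    if (all(pr %in% panel)) {
      add_unique(feature_spec(paste0(pr[1], ":", pr[2]), "index",
                              pr[1], pr[2], provenance = "a_priori"))
    }
  }

  pairs <- utils::combn(panel, 2, simplify = FALSE)
  for (pr in pairs) {
    for (d in seq_len(ndims)) {
      if (high[pr[1], d] && high[pr[2], d] &&
          sign(vc[pr[1], d]) * sign(vc[pr[2], d]) < 0) {
        pos <- if (vc[pr[1], d] > 0) pr else rev(pr)
        add_unique(feature_spec(paste0(pos[1], ":", pos[2]), "index",
                                pos[1], pos[2], provenance = "novel_pair"))
        break
      }
    }
  }
  specs
}

#' Validate features against PCA scores
#'
#' Pearson correlation (two-sided test) between every feature and every
#' retained component's scores, with a single multiplicity correction over
#' all `d x m` tests. A feature is considered validated when it is
#' significant on at least one retained dimension.
#'
#' @param features A `feature_table`.
#' @param scores n x >=ndims score matrix (same sample order as `features`).
#' @param ndims number of retained dimensions.
#' @param alpha significance level (default 0.05).
#' @param method `"bonferroni"` (default) or `"fdr"` (Benjamini-Hochberg).
#' @return A `validation_matrix`: list with `r`, `p_adjusted`, `significant`
#'   (all d x m), `validated` (per-feature logical), `alpha`, `method`.
#' @export
validate_features <- function(features, scores, ndims, alpha = 0.05,
                              method = c("bonferroni", "fdr")) {
  method <- match.arg(method)
  stopifnot(inherits(features, "feature_table"))
  fm <- feature_matrix(features)
  stopifnot(nrow(fm) == nrow(scores), ndims <= ncol(scores))
  sc <- scores[, seq_len(ndims), drop = FALSE]

  m <- ncol(fm); d <- ndims
  r <- matrix(NA_real_, d, m, dimnames = list(paste0("Dim", 1:d), colnames(fm)))
  p <- matrix(NA_real_, d, m, dimnames = dimnames(r))
  for (j in seq_len(m)) {
    fj <- fm[, j]
    if (stats::sd(fj, na.rm = TRUE) == 0 || all(is.na(fj))) {
      warning("feature '", colnames(fm)[j],
              "' is constant; correlation undefined, reported not significant")
      next
    }
    for (i in seq_len(d)) {
      ok <- stats::complete.cases(fj, sc[, i])
      ct <- stats::cor.test(fj[ok], sc[ok, i], method = "pearson")
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  p_adj <- matrix(stats::p.adjust(p, method = if (method == "fdr") "BH" else "bonferroni"),
                  d, m, dimnames = dimnames(p))
  sig <- !is.na(p_adj) & p_adj < alpha
  structure(list(r = r, p_adjusted = p_adj, significant = sig,
                 validated = apply(sig, 2, any),
                 alpha = alpha, method = method),
            class = "validation_matrix")
}

#' @export
print.validation_matrix <- function(x, ...) {
  cat(sprintf("validation_matrix (%s, alpha = %g): %d/%d features validated\n",
              x$method, x$alpha, sum(x$validated), length(x$validated)))
  print(round(x$r, 3))
  invisible(x)
}

#' Packaged feature presets
#'
#' `cat_feature_specs()` returns the nine features for the 7-protein
#' cat/human panel: three sums (all proteins, glutamatergic receptor
#' subunits, GABAA receptor subunits) and six indices (the E:I receptor
#' balance, three receptor-subunit pairs known to switch with visual
#' experience, and two cross-dimension pairings). `rat_feature_specs()`
#' returns a nine-feature set for the 10-protein rat panel (five sums, four
#' indices); its exact membership is a reconstruction from the figure labels
#' of the original study and is meant to be edited per experiment.
#'
#' @return List of `feature_spec`s.
#' @export
cat_feature_specs <- function() {
  glut <- c("GluN1", "GluN2A", "GluN2B", "GluA2")
  gaba <- c("GABAAa1", "GABAAa3")
  list(
    feature_spec("Protein Sum", "sum", c("Syn", glut, gaba), provenance = "high_amplitude"),
    feature_spec("GlutR Sum", "sum", glut, provenance = "high_amplitude"),
    feature_spec("GABAAR Sum", "sum", gaba, provenance = "high_amplitude"),
    feature_spec("GlutR:GABAAR", "index", glut, gaba, provenance = "a_priori"),
    feature_spec("GluN2A:GluN2B", "index", "GluN2A", "GluN2B", provenance = "a_priori"),
    feature_spec("GluN2B:GluA2", "index", "GluN2B", "GluA2", provenance = "a_priori"),
    feature_spec("GABAAa1:GABAAa3", "index", "GABAAa1", "GABAAa3", provenance = "a_priori"),
    feature_spec("GABAAa1:GluN2A", "index", "GABAAa1", "GluN2A", provenance = "novel_pair"),
    feature_spec("GluN2A:GluA2", "index", "GluN2A", "GluA2", provenance = "novel_pair")
  )
}

#' @rdname cat_feature_specs
#' @export
rat_feature_specs <- function() {
  recept <- c("GluA2", "GluN1", "GluN2A", "GluN2B", "GABAAa1", "GABAAa3")
  scaff <- c("PSD95", "Gephyrin")
  list(
    feature_spec("Protein Sum", "sum", c(recept, scaff, "VGLUT1", "VGAT"),
                 provenance = "high_amplitude"),
    feature_spec("VGLUT", "sum", "VGLUT1", provenance = "high_amplitude"),
    feature_spec("Receptors Sum", "sum", recept, provenance = "high_amplitude"),
    feature_spec("Scaffolding Sum", "sum", scaff, provenance = "high_amplitude"),
    feature_spec("VGAT Sum", "sum", "VGAT", provenance = "high_amplitude"),
    feature_spec("GluN2A:GluN2B", "index", "GluN2A", "GluN2B", provenance = "a_priori"),
    feature_spec("GlutR:GABAAR", "index", c("GluA2", "GluN1", "GluN2A", "GluN2B"),
                 c("GABAAa1", "GABAAa3"), provenance = "a_priori"),
    feature_spec("Receptors:Scaffolding", "index", recept, scaff,
                 provenance = "novel_pair"),
    feature_spec("VGLUT1:VGAT", "index", "VGLUT1", "VGAT", provenance = "a_priori")
  )
}
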