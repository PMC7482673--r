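# Centred, unscaled PCA with variable diagnostics.
#
# The model is the singular value decomposition of the centred data matrix:
# eigenvalue_d = sigma_d^2 / (n - 1) (sample covariance convention). Because
# percentages of variance are ratios, the denominator cancels everywhere
# downstream. SVD signs are arbitrary, so each loading column is flipped to
# make its largest-magnitude entry positive; the feature heuristics compare
# signs across proteins and need a reproducible convention.

#' Fit a centred, unscaled PCA
#'
#' Decomposes a centred protein matrix into orthonormal basis vectors
#' (loadings), per-component variances (eigenvalues) and sample scores.
#' Variable coordinates (`var_coords`, the loading scaled by the component
#' standard deviation) and `cos2` (quality of representation, the squared
#' correlation between each protein and each component's scores) match the
#' conventional variable diagnostics for covariance-matrix PCA.
#'
#' @param matrix A `centered_matrix` from [center()].
#' @return A `pca_model`: list with `eigenvalues`, `pct_variance`,
#'   `cum_pct_variance` (percent), `scores` (n x p), `loadings` (p x p,
#'   orthonormal columns), `var_coords`, `cos2`, `protein_names`.
#' @export
fit_pca <- function(matrix) {
  stopifnot(inherits(matrix, "centered_matrix"))
  x <- matrix$values
  n <- nrow(x); p <- ncol(x)
  if (n < 2) stop("need at least 2 samples for PCA")
  if (p < 2) stop("need at least 2 proteins for PCA")

  sv <- svd(x, nu = 0, nv = p)
  eig <- numeric(p)
  eig[seq_along(sv$d)] <- sv$d^2 / (n - 1)
  loadings <- sv$v

  # deterministic sign convention: largest-|entry| loading positive
  flip <- apply(loadings, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  loadings <- sweep(loadings, 2, flip, "*")

  scores <- x %*% loadings
  var_coords <- sweep(loadings, 2, sqrt(eig), "*")

  col_var <- rowSums(var_coords^2) # = per-protein variance
  cos2 <- var_coords^2
  zero_var <- col_var <= 0
  if (any(zero_var)) {
    warning("zero-variance protein(s): ",
            paste(matrix$protein_names[zero_var], collapse = ", "),
            "; cos2 reported as 0")
    cos2[zero_var, ] <- 0
    cos2[!zero_var, ] <- cos2[!zero_var, , drop = FALSE] / col_var[!zero_var]
  } else {
    cos2 <- cos2 / col_var
  }

  pct <- 100 * eig / sum(eig)
  dn <- list(matrix$protein_names, paste0("Dim", seq_len(p)))
  dimnames(loadings) <- dn
  dimnames(var_coords) <- dn
  dimnames(cos2) <- dn
  colnames(scores) <- dn[[2]]

  structure(list(eigenvalues = eig,
                 pct_variance = pct,
                 cum_pct_variance = cumsum(pct),
                 scores = scores,
                 loadings = loadings,
                 var_coords = var_coords,
                 cos2 = cos2,
                 protein_names = matrix$protein_names),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("pca_model (centred, unscaled)\n")
  tab <- rbind(`eigenvalue` = x$eigenvalues,
               `% variance` = x$pct_variance,
               `cum %` = x$cum_pct_variance)
  colnames(tab) <- paste0("Dim", seq_along(x$eigenvalues))
  print(round(tab, 3))
  invisible(x)
}

#' Number of significant dimensions
#'
#' The retained-component rule: the smallest number of leading components
#' whose cumulative percent variance reaches the threshold (inclusive,
#' default 80%).
#'
#' @param cum_pct_variance nondecreasing percent vector ending near 100.
#' @param thresh percent threshold in (0, 100].
#' @return Integer count of retained components.
#' @export
significant_dimensions <- function(cum_pct_variance, thresh = 80) {
  if (length(cum_pct_variance) == 0) stop("empty cumulative-variance vector")
  stopifnot(thresh > 0, thresh <= 100)
  if (is.unsorted(cum_pct_variance, strictly = FALSE)) {
    stop("cumulative variance must be nondecreasing")
  }
  which(cum_pct_variance >= thresh)[1]
}

#' Per-protein, per-dimension diagnostics
#'
#' Long-format table of cos2, signed variable coordinate and loading
#' amplitude for the retained dimensions -- the data behind scree/cos2/
#' amplitude plots.
#'
#' @param model A `pca_model`.
#' @param ndims number of leading dimensions to report.
#' @return data.frame with columns `protein`, `dim`, `cos2`, `var_coord`,
#'   `loading`.
#' @export
variable_diagnostics <- function(model, ndims) {
  stopifnot(inherits(model, "pca_model"))
  p <- length(model$protein_names)
  stopifnot(ndims >= 1, ndims <= p)
  data.frame(
    protein = rep(model$protein_names, times = ndims),
    dim = rep(seq_len(ndims), each = p),
    cos2 = as.vector(model$cos2[, seq_len(ndims)]),
    var_coord = as.vector(model$var_coords[, seq_len(ndims)]),
    loading = as.vector(model$loadings[, seq_len(ndims)]),
    stringsAsFactors = FALSE
  )
}

#' Scree plot of explained variance
#'
#' @param model A `pca_model`.
#' @return A ggplot bar chart of percent variance per component.
#' @export
plot_scree <- function(model) {
  stopifnot(inherits(model, "pca_model"))
  df <- data.frame(dim = factor(seq_along(model$pct_variance)),
                   pct = model$pct_variance)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dim, y = .data$pct)) +
    ggplot2::geom_col(fill = "gray", colour = "gray40") +
    ggplot2::labs(x = "Principal component", y = "% of variance explained") +
    ggplot2::theme_classic()
}
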