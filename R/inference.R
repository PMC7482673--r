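# column-wise medians without per-column apply(): sort within columns via a
# single order() call, then average the middle order statistics
.col_medians <- function(x) {
  n <- nrow(x)
  s <- matrix(x[order(col(x), x)], n, ncol(x))
  if (n %% 2 == 1) s[(n + 1) / 2, ] else (s[n / 2, ] + s[n / 2 + 1, ]) / 2
}

# Flagging features that deviate from a reference condition.
#
# Two routes, matched to design size: a percentile over-representation
# analysis (ORA) for small-N discovery designs, comparing a group's feature
# percentiles against bootstrap 5th/95th bounds of the reference cluster;
# and a bootstrap test of the median difference for larger-N designs. All
# quantiles are type 7 (linear interpolation), which matters at small n.

#' Bootstrap percentile bounds of a reference group
#'
#' Resamples the reference rows with replacement `n_sims` times, pools the
#' resampled values and reports the pooled 5th and 95th percentile per
#' feature. Deterministic given `seed`.
#'
#' @param ref_samples numeric matrix or data.frame of reference samples
#'   (rows) x features (columns), >= 3 rows.
#' @param n_sims number of bootstrap resamples (default 10000).
#' @param seed integer seed.
#' @return data.frame with columns `feature`, `q05`, `q95`.
#' @export
reference_bounds <- function(ref_samples, n_sims = 10000, seed = 1L) {
  m <- as.matrix(ref_samples)
  if (nrow(m) < 3) stop("need at least 3 reference samples")
  if (any(colSums(!is.na(m)) == 0)) stop("feature with no observed reference values")
  set.seed(seed)
  n <- nrow(m)
  idx <- sample.int(n, n * n_sims, replace = TRUE)
  out <- data.frame(feature = colnames(m), q05 = NA_real_, q95 = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(m))) {
    pool <- m[idx, j]
    q <- stats::quantile(pool, c(0.05, 0.95), na.rm = TRUE, type = 7,
                         names = FALSE)
    out$q05[j] <- q[1]; out$q95[j] <- q[2]
  }
  out
}

#' Percentile over-representation calls
#'
#' A feature is over-represented when the group's lower percentile exceeds
#' the reference 95th percentile, under-represented when the group's upper
#' percentile falls below the reference 5th percentile, and unremarkable
#' otherwise. Rule `"p25_75"` uses the group's 25th/75th percentiles (the box
#' of a boxplot); `"p10_90"` is the more conservative 10th/90th rule --
#' widening the group interval can only drop calls.
#'
#' @param group_samples numeric matrix/data.frame of group samples x features.
#' @param bounds reference bounds from [reference_bounds()].
#' @param rule `"p25_75"` (default) or `"p10_90"`.
#' @return data.frame with columns `feature`, `call`
#'   (`"over"`/`"under"`/`"none"`), `group_lo`, `group_hi`.
#' @export
ora_classify <- function(group_samples, bounds, rule = c("p25_75", "p10_90")) {
  rule <- match.arg(rule)
  m <- as.matrix(group_samples)
  if (nrow(m) == 0) stop("empty group")
  if (nrow(m) < 2) {
    warning("group has a single sample; its value stands in for all percentiles")
  }
  probs <- if (rule == "p25_75") c(0.25, 0.75) else c(0.10, 0.90)
  stopifnot(identical(colnames(m), bounds$feature))
  lo <- apply(m, 2, stats::quantile, probs = probs[1], na.rm = TRUE,
              type = 7, names = FALSE)
  hi <- apply(m, 2, stats::quantile, probs = probs[2], na.rm = TRUE,
              type = 7, names = FALSE)
  call <- ifelse(lo > bounds$q95, "over",
                 ifelse(hi < bounds$q05, "under", "none"))
  data.frame(feature = bounds$feature, call = call,
             group_lo = lo, group_hi = hi, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Bootstrap comparison of groups against a reference
#'
#' For every feature and every non-reference group, bootstraps the
#' difference of group medians (group minus reference; means selectable),
#' resampling the two groups independently `n_boot` times. The two-sided
#' p-value is `2 * min(P(diff* <= 0), P(diff* >= 0))` with a
#' `+1/(n_boot + 1)` continuity correction; a feature is called
#' `"greater"`/`"less"` when `p < alpha`, signed by the observed difference.
#' No multiplicity correction across features is applied by default (raw
#' per-feature calls); pass `p_adjust` to correct.
#'
#' @param features A `feature_table`.
#' @param group_field metadata field holding the group label.
#' @param reference_label reference group label.
#' @param n_boot bootstrap resamples (default 10000; < 1000 warns).
#' @param alpha significance level (default 0.05).
#' @param statistic `"median"` (default) or `"mean"`.
#' @param p_adjust `"none"` (default), `"bonferroni"` or `"fdr"`, applied per
#'   group across features.
#' @param seed integer seed.
#' @return A `comparison_result`: data.frame with columns `group`, `feature`,
#'   `observed_diff`, `p`, `call` (`"greater"`/`"less"`/`"none"`).
#' @export
bootstrap_compare <- function(features, group_field, reference_label,
                              n_boot = 10000, alpha = 0.05,
                              statistic = c("median", "mean"),
                              p_adjust = c("none", "bonferroni", "fdr"),
                              seed = 1L) {
  statistic <- match.arg(statistic)
  p_adjust <- match.arg(p_adjust)
  stopifnot(inherits(features, "feature_table"))
  if (n_boot < 1000) warning("n_boot < 1000 gives unstable p-values")
  stat_fun <- if (statistic == "median") stats::median else mean

  g <- as.data.frame(features)[[group_field]]
  if (is.null(g)) stop("no metadata field '", group_field, "'")
  if (!reference_label %in% g) stop("reference group '", reference_label, "' not found")
  fm <- feature_matrix(features)
  ref <- fm[g == reference_label, , drop = FALSE]
  if (nrow(ref) < 3) stop("reference group needs >= 3 samples")

  col_stat <- if (statistic == "mean") {
    function(x) .colMeans(x, nrow(x), ncol(x))
  } else {
    .col_medians
  }

  groups <- setdiff(unique(g), reference_label)
  set.seed(seed)
  res <- list()
  for (grp in groups) {
    gm <- fm[g == grp, , drop = FALSE]
    if (nrow(gm) < 3) stop("group '", grp, "' needs >= 3 samples")
    n_g <- nrow(gm); n_r <- nrow(ref)
    gi <- sample.int(n_g, n_g * n_boot, replace = TRUE)
    ri <- sample.int(n_r, n_r * n_boot, replace = TRUE)
    for (j in seq_len(ncol(fm))) {
      obs <- stat_fun(gm[, j]) - stat_fun(ref[, j])
      boots <- col_stat(matrix(gm[gi, j], n_g, n_boot)) -
        col_stat(matrix(ref[ri, j], n_r, n_boot))
      p <- 2 * min(sum(boots <= 0) + 1, sum(boots >= 0) + 1) / (n_boot + 1)
      p <- min(p, 1)
      res[[length(res) + 1]] <- data.frame(
        group = grp, feature = colnames(fm)[j],
        observed_diff = obs, p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  if (p_adjust != "none") {
    meth <- if (p_adjust == "fdr") "BH" else "bonferroni"
    out$p <- stats::ave(out$p, out$group,
                        FUN = function(p) stats::p.adjust(p, method = meth))
  }
  out$call <- ifelse(out$p < alpha,
                     ifelse(out$observed_diff > 0, "greater", "less"),
                     "none")
  structure(out,
            reference = reference_label, alpha = alpha,
            n_boot = n_boot, statistic = statistic, seed = seed,
            class = c("comparison_result", "data.frame"))
}
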