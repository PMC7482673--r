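# Clustering of samples in feature space: tSNE to 2-D, within-cluster
# sum-of-squares (WSS) over a range of k, exponential-decay elbow selection
# of k (the curve has plateaued at four time-constants), and seeded k-means
# partitioning with composition/subcluster accounting.

#' tSNE embedding of a feature table
#'
#' Embeds samples into 2-D using only the feature columns -- metadata
#' (region, condition, age) provably never reaches the embedding. The
#' embedding is deterministic given `seed`.
#'
#' @param features A `feature_table` (no missing feature values).
#' @param perplexity tSNE perplexity (default 25).
#' @param max_iter gradient-descent iterations (default 5000).
#' @param seed integer seed.
#' @return An `embedding`: list with `coords` (n x 2), `perplexity`,
#'   `max_iter`, `seed`, `backend`.
#' @export
embed_tsne <- function(features, perplexity = 25, max_iter = 5000, seed = 1L) {
  stopifnot(inherits(features, "feature_table"))
  x <- feature_matrix(features)
  if (anyNA(x)) stop("missing feature values; impute or drop before embedding")
  n <- nrow(x)
  if (n - 1 < 3 * perplexity) {
    stop(sprintf("perplexity %g too large for n = %d; need perplexity <= %g",
                 perplexity, n, (n - 1) / 3))
  }
  set.seed(seed)
  fit <- Rtsne::Rtsne(x, dims = 2, perplexity = perplexity,
                      max_iter = max_iter, check_duplicates = FALSE,
                      pca = FALSE, verbose = FALSE)
  coords <- fit$Y
  colnames(coords) <- c("tsne1", "tsne2")
  structure(list(coords = coords, perplexity = perplexity,
                 max_iter = max_iter, seed = seed,
                 backend = paste0("Rtsne ",
                                  as.character(utils::packageVersion("Rtsne")))),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("embedding: %d samples in 2-D (perplexity %g, %d iter, seed %d, %s)\n",
              nrow(x$coords), x$perplexity, x$max_iter, x$seed, x$backend))
  invisible(x)
}

#' Within-cluster sum of squares over a range of k
#'
#' For each `k` in `k_min:k_max`, runs seeded k-means (best of `nstart`
#' restarts) on the 2-D coordinates and records the total within-cluster sum
#' of squared Euclidean distances. The `k = 1` entry is the total centred sum
#' of squares, `(n-1) * sum(column variances)`.
#'
#' @param embedding an `embedding` (or bare n x 2 matrix).
#' @param k_min,k_max searched range (defaults 2 and 15).
#' @param nstart k-means restarts per k (default 25).
#' @param seed integer seed.
#' @return A `wss_curve`: data.frame with columns `k`, `wss`.
#' @export
wss_curve <- function(embedding, k_min = 2, k_max = 15, nstart = 25, seed = 1L) {
  coords <- if (inherits(embedding, "embedding")) embedding$coords else as.matrix(embedding)
  n <- nrow(coords)
  stopifnot(k_min >= 2, k_max >= k_min)
  if (k_max >= n) stop("k_max must be smaller than the number of samples")
  set.seed(seed)
  ks <- c(1L, seq.int(k_min, k_max))
  wss <- numeric(length(ks))
  wss[1] <- (n - 1) * sum(apply(coords, 2, stats::var))
  for (i in seq_along(ks)[-1]) {
    km <- stats::kmeans(coords, centers = ks[i], nstart = nstart,
                        iter.max = 100)
    wss[i] <- km$tot.withinss
  }
  structure(data.frame(k = ks, wss = wss), class = c("wss_curve", "data.frame"))
}

#' Elbow selection of k by exponential-decay fit
#'
#' Fits `WSS(k) = a * exp(-k / tau) + c` by nonlinear least squares and
#' returns `k_star = round(4 * tau)` (half away from zero), clamped to the
#' fitted k range: at four time-constants the decay has plateaued, which is
#' the elbow. By default the fit uses the searched clustering range
#' (`k >= fit_k_min`); the `k = 1` total-sum-of-squares entry, when present,
#' is reference only -- it measures unclustered spread, sits far above the
#' clustered-WSS scale for well-separated data and would bias `tau`
#' downwards. Set `fit_k_min = 1` to include it. Initialisation:
#' `c0 = min(wss)`, `a0` from the first fitted point, `tau0` = a quarter of
#' the fitted k span.
#'
#' @param curve a `wss_curve` (>= 4 points in the fitted range).
#' @param fit_k_min smallest k used in the fit (default 2).
#' @return An `elbow_fit`: list with `a`, `c`, `tau`, `k_star`, `rss`.
#' @export
elbow_k <- function(curve, fit_k_min = 2) {
  stopifnot(is.data.frame(curve), all(c("k", "wss") %in% names(curve)))
  curve <- curve[curve$k >= fit_k_min, , drop = FALSE]
  if (nrow(curve) < 4) stop("need at least 4 WSS points to fit the decay")
  k <- curve$k; w <- curve$wss
  c0 <- min(w)
  tau0 <- max((max(k) - min(k)) / 4, 0.5)
  a0 <- max(w[1] - c0, 1e-8) * exp(min(k) / tau0)
  fit <- tryCatch(
    minpack.lm::nlsLM(w ~ a * exp(-k / tau) + cc,
                      start = list(a = a0, tau = tau0, cc = c0),
                      lower = c(a = 0, tau = 1e-6, cc = -Inf),
                      upper = c(a = Inf, tau = max(k), cc = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    stop("exponential-decay fit failed (non-decaying WSS curve?); choose k manually")
  }
  cf <- stats::coef(fit)
  if (cf[["a"]] <= 0) {
    stop("WSS curve does not decay; choose k manually")
  }
  k_star <- as.integer(floor(4 * cf[["tau"]] + 0.5)) # round half away from zero
  k_star <- min(max(k_star, min(k)), max(k))
  structure(list(a = unname(cf["a"]), c = unname(cf["cc"]),
                 tau = unname(cf["tau"]), k_star = k_star,
                 rss = sum(stats::residuals(fit)^2)),
            class = "elbow_fit")
}

#' @export
print.elbow_fit <- function(x, ...) {
  cat(sprintf("elbow_fit: wss ~ %.3g * exp(-k/%.3g) + %.3g; k* = 4*tau -> %d\n",
              x$a, x$tau, x$c, x$k_star))
  invisible(x)
}

#' k-means partition of an embedding
#'
#' Seeded k-means (best of `nstart` restarts by WSS) on the 2-D coordinates.
#' On the rare empty-cluster failure the run is retried with a fresh seed
#' stream, up to `retries` times.
#'
#' @param embedding an `embedding` (or n x 2 matrix).
#' @param k number of clusters (1 < k < n).
#' @param metadata optional data.frame of per-sample metadata carried along.
#' @param nstart restarts (default 25).
#' @param seed integer seed.
#' @param retries empty-cluster retry cap (default 5).
#' @return A `cluster_assignment`: list with `cluster` (integer in 1..k),
#'   `k`, `seed`, `centers`, `metadata`.
#' @export
kmeans_partition <- function(embedding, k, metadata = NULL, nstart = 25,
                             seed = 1L, retries = 5) {
  coords <- if (inherits(embedding, "embedding")) embedding$coords else as.matrix(embedding)
  n <- nrow(coords)
  stopifnot(k > 1, k < n)
  km <- NULL
  for (attempt in seq_len(retries + 1)) {
    set.seed(seed + attempt - 1L)
    km <- tryCatch(stats::kmeans(coords, centers = k, nstart = nstart,
                                 iter.max = 100),
                   error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(km) && length(unique(km$cluster)) == k) break
    km <- NULL
  }
  if (is.null(km)) stop("k-means failed to produce ", k, " nonempty clusters")
  structure(list(cluster = unname(km$cluster), k = k, seed = seed,
                 centers = km$centers, wss = km$tot.withinss,
                 metadata = metadata),
            class = "cluster_assignment")
}

#' Cluster composition and subcluster labels
#'
#' Cross-tabulates clusters against a condition field (and optionally a
#' region field) and derives subcluster labels: the samples sharing both a
#' cluster and a condition, kept when the combination has at least
#' `min_size` members.
#'
#' @param assignment a `cluster_assignment` whose `metadata` holds the fields.
#' @param condition_field,region_field metadata field names (`region_field`
#'   may be `NULL`).
#' @param min_size minimum subcluster size (default 2).
#' @return A list with `by_condition` (+ `by_region` if requested) count
#'   tables and `subcluster`, a per-sample label `"<condition> <cluster>"`
#'   (`NA` for dropped combinations).
#' @export
compose_clusters <- function(assignment, condition_field, region_field = NULL,
                             min_size = 2) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  md <- assignment$metadata
  if (is.null(md)) stop("assignment carries no metadata")
  cl <- assignment$cluster
  cond <- md[[condition_field]]
  out <- list(by_condition = table(cluster = cl, condition = cond))
  if (!is.null(region_field)) {
    out$by_region <- table(cluster = cl, region = md[[region_field]])
  }
  lab <- paste(cond, cl)
  sizes <- table(lab)
  lab[lab %in% names(sizes)[sizes < min_size]] <- NA_character_
  out$subcluster <- lab
  out
}
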