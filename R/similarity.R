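# Pairwise similarity of phenotype vectors (subcluster medians or individual
# animals): Pearson correlation matrix, hierarchical ordering, group cutting
# and heatmap output.
#
# Distance convention: by default the Euclidean distance between ROWS of the
# correlation matrix (two entities are close when they correlate the same
# way with everyone), not 1 - r; `distance = "one_minus_r"` gives the more
# conventional alternative.

#' Pearson correlation matrix between entities
#'
#' Correlates every pair of entities (rows) across their feature values
#' (columns).
#'
#' @param vectors entity x feature numeric matrix (>= 3 feature columns,
#'   no missing values), rownames label the entities.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(vectors) {
  m <- as.matrix(vectors)
  if (ncol(m) < 3) stop("need at least 3 feature columns")
  if (anyNA(m)) stop("missing values in phenotype vectors")
  const <- apply(m, 1, stats::sd) == 0
  if (any(const)) {
    lab <- rownames(m)[const]
    if (is.null(lab)) lab <- which(const)
    stop("constant phenotype vector(s): ", paste(lab, collapse = ", "))
  }
  r <- stats::cor(t(m))
  diag(r) <- 1
  r
}

#' Order entities hierarchically and cut into groups
#'
#' Builds a dendrogram over the entities from their correlation matrix and
#' cuts it into `n_groups` by descending merge height. The group count is
#' user-supplied: branch heights are inspected by eye, not thresholded
#' automatically.
#'
#' @param r correlation matrix from [correlation_matrix()].
#' @param linkage `"complete"` (default) or `"ward.d2"`.
#' @param n_groups number of groups to cut (<= entities).
#' @param distance `"rows"` (Euclidean between correlation-matrix rows,
#'   default) or `"one_minus_r"`.
#' @return A `correlation_structure`: list with `r`, `linkage`, `hclust`,
#'   `order` (leaf order), `labels`, `groups` (cut labels in input order).
#' @export
order_and_cut <- function(r, linkage = c("complete", "ward.d2"),
                          n_groups = 2, distance = c("rows", "one_minus_r")) {
  linkage <- match.arg(linkage)
  distance <- match.arg(distance)
  r <- as.matrix(r)
  if (n_groups > nrow(r)) stop("n_groups exceeds the number of entities")
  d <- if (distance == "rows") {
    stats::dist(r, method = "euclidean")
  } else {
    stats::as.dist(1 - r)
  }
  hc <- stats::hclust(d, method = if (linkage == "complete") "complete" else "ward.D2")
  groups <- stats::cutree(hc, k = n_groups)
  structure(list(r = r, linkage = linkage, distance = distance,
                 hclust = hc, order = .leaf_order(hc, rownames(r)),
                 labels = rownames(r), groups = groups,
                 n_groups = n_groups),
            class = "correlation_structure")
}

# canonical leaf order by recursive merge traversal, tighter (lower-height)
# branch first; ties broken by the lexicographically smallest leaf label in
# the subtree, so relabeling entities permutes the order consistently
.leaf_order <- function(hc, labels) {
  sub_height <- function(node) if (node < 0) 0 else hc$height[node]
  min_label <- function(node) {
    if (node < 0) return(labels[-node])
    min(min_label(hc$merge[node, 1]), min_label(hc$merge[node, 2]))
  }
  visit <- function(node) {
    if (node < 0) return(-node)
    ch <- hc$merge[node, ]
    h <- c(sub_height(ch[1]), sub_height(ch[2]))
    first <- if (h[1] < h[2]) 1 else if (h[2] < h[1]) 2 else
      if (min_label(ch[1]) <= min_label(ch[2])) 1 else 2
    c(visit(ch[first]), visit(ch[3 - first]))
  }
  visit(nrow(hc$merge))
}

#' @export
print.correlation_structure <- function(x, ...) {
  cat(sprintf("correlation_structure: %d entities, %s linkage, %d groups\n",
              nrow(x$r), x$linkage, x$n_groups))
  cat("leaf order:", paste(x$labels[x$order], collapse = ", "), "\n")
  invisible(x)
}

#' Render the correlation heatmap with dendrogram and group separators
#'
#' Heatmap of the correlation matrix in dendrogram leaf order, dendrograms in
#' the margins and black separators at the group boundaries.
#'
#' @param structure a `correlation_structure`.
#' @param annotation optional data.frame (rownames = entities) of entity
#'   conditions used to colour the margins.
#' @param filename optional path; when given the heatmap is written there.
#' @return The pheatmap object, invisibly.
#' @export
render_corr_heatmap <- function(structure, annotation = NULL, filename = NA) {
  stopifnot(inherits(structure, "correlation_structure"))
  ph <- pheatmap::pheatmap(
    structure$r,
    cluster_rows = structure$hclust,
    cluster_cols = structure$hclust,
    cutree_rows = structure$n_groups,
    cutree_cols = structure$n_groups,
    annotation_row = annotation,
    border_color = NA,
    filename = filename,
    silent = TRUE
  )
  invisible(ph)
}
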