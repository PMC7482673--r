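# The phenotype: group medians of the plasticity features rendered as a
# stack of colour-coded horizontal bars. Sums use a white-to-near-black gray
# ramp; indices use a diverging red (negative) - yellow (zero) - green
# (positive) ramp. Under the "absolute" translation every profile passed in
# one call shares a single colour scale (the largest absolute index median
# across all groups of all profiles anchors full green/red), which is what
# makes phenotypes comparable across species or datasets; "local" scales
# each profile alone.

.ramp_index <- function(anchors = c("#FF0000", "#FFFF00", "#00FF00")) {
  grDevices::colorRamp(anchors, space = "rgb")
}
.ramp_sum <- function(anchors = c("#FFFFFF", "#1A1A1A")) {
  grDevices::colorRamp(anchors, space = "rgb")
}
.to_hex <- function(rgbm) {
  grDevices::rgb(rgbm[, 1], rgbm[, 2], rgbm[, 3], maxColorValue = 255)
}

#' Aggregate features to a group-level phenotype profile
#'
#' Computes the per-group median of every feature (missing values excluded),
#' with groups in a caller-supplied display order (e.g. youngest to oldest).
#'
#' @param features A `feature_table`.
#' @param group_field metadata field holding the group label.
#' @param group_order character vector of group labels in display order;
#'   defaults to first-appearance order.
#' @return A `phenotype_profile`: list with `medians` (g x m), `specs`,
#'   `groups`; uncoloured until [colorize()].
#' @export
aggregate_profile <- function(features, group_field,
                              group_order = NULL) {
  stopifnot(inherits(features, "feature_table"))
  g <- as.data.frame(features)[[group_field]]
  if (is.null(g)) stop("no metadata field '", group_field, "'")
  if (is.null(group_order)) group_order <- unique(g)
  unknown <- setdiff(g, group_order)
  if (length(unknown) > 0) {
    stop("sample group label(s) not in group_order: ",
         paste(unknown, collapse = ", "))
  }
  fm <- feature_matrix(features)
  med <- matrix(NA_real_, length(group_order), ncol(fm),
                dimnames = list(group_order, colnames(fm)))
  for (lev in group_order) {
    rows <- which(g == lev)
    if (length(rows) == 0) stop("empty group: ", lev)
    med[lev, ] <- apply(fm[rows, , drop = FALSE], 2, stats::median, na.rm = TRUE)
  }
  structure(list(medians = med, specs = feature_specs(features),
                 groups = group_order, colors = NULL, scale_mode = NULL),
            class = "phenotype_profile")
}

#' @export
print.phenotype_profile <- function(x, ...) {
  cat(sprintf("phenotype_profile: %d groups x %d features%s\n",
              nrow(x$medians), ncol(x$medians),
              if (is.null(x$colors)) " (uncoloured)"
              else paste0(" (", x$scale_mode, " colours)")))
  print(round(x$medians, 3))
  invisible(x)
}

.spec_kinds <- function(profile) {
  vapply(profile$specs, `[[`, character(1), "kind")
}

#' Colour-encode phenotype profiles
#'
#' Index medians map linearly in RGB onto red(-L) - yellow(0) - green(+L),
#' where `L` is the largest absolute index median over all groups of all
#' supplied profiles (`mode = "absolute"`) or of each profile alone
#' (`"local"`). Sum medians map onto a white(0) to near-black gray ramp whose
#' maximum is taken over the same span. Zero index medians are therefore
#' yellow exactly, and under absolute mode equal medians get identical
#' colours across profiles.
#'
#' @param profiles a `phenotype_profile` or list of them (sharing specs).
#' @param mode `"absolute"` (default) or `"local"`.
#' @param index_anchors,sum_anchors hex colour anchors for the two ramps.
#' @return The profile(s) with a `colors` matrix of hex codes filled in;
#'   a list in, a list out.
#' @export
colorize <- function(profiles, mode = c("absolute", "local"),
                     index_anchors = c("#FF0000", "#FFFF00", "#00FF00"),
                     sum_anchors = c("#FFFFFF", "#1A1A1A")) {
  mode <- match.arg(mode)
  single <- inherits(profiles, "phenotype_profile")
  if (single) profiles <- list(profiles)
  kinds <- .spec_kinds(profiles[[1]])
  for (p in profiles) {
    if (!identical(.spec_kinds(p), kinds)) {
      stop("all profiles must share the same feature specs")
    }
  }
  idx_ramp <- .ramp_index(index_anchors)
  sum_ramp <- .ramp_sum(sum_anchors)

  span_L <- function(ps) {
    v <- unlist(lapply(ps, function(p) abs(p$medians[, kinds == "index"])))
    if (length(v) == 0) 0 else max(v, na.rm = TRUE)
  }
  span_S <- function(ps) {
    v <- unlist(lapply(ps, function(p) p$medians[, kinds == "sum"]))
    if (length(v) == 0) 1 else max(v, na.rm = TRUE)
  }
  if (mode == "absolute") {
    L <- span_L(profiles); S <- span_S(profiles)
  }
  out <- lapply(profiles, function(p) {
    if (mode == "local") {
      L <- span_L(list(p)); S <- span_S(list(p))
    }
    if (L == 0 && any(kinds == "index")) {
      warning("all index medians are 0; index bars rendered at the midpoint")
    }
    cols <- p$medians
    cols[] <- NA_character_
    for (j in seq_along(kinds)) {
      v <- p$medians[, j]
      if (kinds[j] == "index") {
        t <- if (L == 0) rep(0.5, length(v)) else (v / L + 1) / 2
        cols[, j] <- .to_hex(idx_ramp(pmin(pmax(t, 0), 1)))
      } else {
        t <- if (S <= 0) rep(0, length(v)) else v / S
        cols[, j] <- .to_hex(sum_ramp(pmin(pmax(t, 0), 1)))
      }
    }
    p$colors <- cols
    p$scale_mode <- mode
    p
  })
  if (single) out[[1]] else out
}

#' Normalise sum features to a reference group
#'
#' Divides each sum feature by the reference group's median of that feature
#' (e.g. the youngest age), so sums read as fold change relative to the
#' reference; index features are untouched.
#'
#' @param features A `feature_table`.
#' @param group_field metadata field holding the group label.
#' @param reference_group reference group label.
#' @return The `feature_table` with rescaled sum columns.
#' @export
normalize_sums_to_reference <- function(features, group_field, reference_group) {
  stopifnot(inherits(features, "feature_table"))
  g <- as.data.frame(features)[[group_field]]
  ref_rows <- which(g == reference_group)
  if (length(ref_rows) == 0) stop("empty reference group: ", reference_group)
  specs <- feature_specs(features)
  out <- features
  for (sp in specs) {
    if (sp$kind != "sum") next
    ref_med <- stats::median(features[[sp$name]][ref_rows], na.rm = TRUE)
    if (is.na(ref_med) || ref_med <= 0) {
      stop("reference median of sum '", sp$name, "' is not positive")
    }
    out[[sp$name]] <- features[[sp$name]] / ref_med
  }
  out
}

.profile_long <- function(profile) {
  m <- profile$medians
  specs_order <- order(factor(.spec_kinds(profile),
                              levels = c("sum", "index")))
  data.frame(
    group = factor(rep(rownames(m), times = ncol(m)), levels = profile$groups),
    feature = factor(rep(colnames(m), each = nrow(m)),
                     levels = rev(colnames(m)[specs_order])),
    median = as.vector(m),
    fill = as.vector(profile$colors),
    stringsAsFactors = FALSE
  )
}

#' Render a phenotype bar stack
#'
#' One row per feature (sums above indices, in spec order), one column per
#' group, each cell filled with its phenotype colour.
#'
#' @param profile a colourised `phenotype_profile`.
#' @param title optional plot title.
#' @return A ggplot object.
#' @export
render_phenotype <- function(profile, title = NULL) {
  stopifnot(inherits(profile, "phenotype_profile"))
  if (is.null(profile$colors)) stop("profile is uncoloured; call colorize() first")
  df <- .profile_long(profile)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$feature)) +
    ggplot2::geom_tile(fill = df$fill, colour = "white", linewidth = 0.4) +
    ggplot2::labs(x = NULL, y = NULL, title = title) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Render colour-matched feature boxplots
#'
#' A grid of per-feature boxplots (median, quartiles, whiskers at 1.5 IQR,
#' seeded jittered points), each panel filled with the group's phenotype
#' colour for that feature so the grid reads alongside the bar stack.
#'
#' @param features A `feature_table`.
#' @param profile the matching colourised `phenotype_profile`.
#' @param group_field metadata field holding the group label.
#' @param seed seed for the point jitter.
#' @return A ggplot object (facetted by feature).
#' @export
render_boxplots <- function(features, profile, group_field, seed = 1L) {
  stopifnot(inherits(features, "feature_table"),
            inherits(profile, "phenotype_profile"))
  if (is.null(profile$colors)) stop("profile is uncoloured; call colorize() first")
  fm <- feature_matrix(features)
  g <- as.data.frame(features)[[group_field]]
  long <- data.frame(
    group = factor(rep(g, times = ncol(fm)), levels = profile$groups),
    feature = factor(rep(colnames(fm), each = nrow(fm)),
                     levels = colnames(profile$medians)),
    value = as.vector(fm)
  )
  long$fill <- profile$colors[cbind(as.character(long$group),
                                    as.character(long$feature))]
  set.seed(seed)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot(fill = long$fill, outlier.shape = NA, coef = 1.5) +
    ggplot2::geom_jitter(width = 0.15, size = 0.6, alpha = 0.6) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "feature value") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
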