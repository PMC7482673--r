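# End-to-end pipeline: io -> pca -> features (+validation) -> phenotype ->
# [cluster -> similarity] -> inference, driven by one config object, with a
# manifest recording seeds, parameters and per-file checksums so a run can
# be reproduced and compared byte for byte.

#' Read or write feature specs as JSON
#'
#' The on-disk form is a JSON list of
#' `{name, kind, numerator, denominator, provenance}` objects.
#'
#' @param path JSON file path.
#' @param specs list of `feature_spec`s (for writing).
#' @return `read_feature_specs()` returns a list of `feature_spec`s.
#' @export
read_feature_specs <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(x) {
    den <- unlist(x$denominator)
    feature_spec(x$name, x$kind, unlist(x$numerator),
                 if (is.null(den)) character() else den,
                 provenance = if (is.null(x$provenance)) "user" else x$provenance)
  })
}

#' @rdname read_feature_specs
#' @export
write_feature_specs <- function(specs, path) {
  jsonlite::write_json(lapply(specs, unclass), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Returns the full config list with the workflow's default parameters
#' (variance threshold 80%, Bonferroni validation at alpha 0.05, tSNE
#' perplexity 25 with 5000 iterations, k range 2-15, complete linkage,
#' 10000 simulations/resamples for inference). Override fields as needed and
#' pass to [run_pipeline()]. The config round-trips through JSON.
#'
#' @param ... named overrides of the defaults.
#' @return A named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    input = NULL,               # CSV path, or NULL to use `preset`
    preset = "cat_recovery",
    effect = "strong",
    protein_columns = NULL,     # inferred from preset when input is NULL
    metadata_columns = NULL,
    run_field = "run",
    impute = FALSE,
    impute_k = 10,
    variance_thresh = 80,
    specs = "cat",              # "cat", "rat", a JSON path, or a spec list
    alpha = 0.05,
    correction = "bonferroni",
    group_field = "condition",
    group_order = NULL,
    cluster = TRUE,
    perplexity = 25,
    max_iter = 5000,
    k = "auto",
    k_min = 2, k_max = 15,
    linkage = "complete",
    n_groups = NULL,            # similarity cut; default = cluster count
    inference = "ora",          # "ora", "bootstrap" or "none"
    reference_group = NULL,
    ora_rule = "p25_75",
    n_sims = 10000,
    n_boot = 10000,
    seed = 1L,
    out_dir = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) stop("unknown config field(s): ",
                                paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

.resolve_specs <- function(specs) {
  if (is.character(specs) && length(specs) == 1) {
    if (specs == "cat") return(cat_feature_specs())
    if (specs == "rat") return(rat_feature_specs())
    return(read_feature_specs(specs))
  }
  if (is.list(specs)) return(specs)
  stop("config$specs must be 'cat', 'rat', a JSON path or a list of specs")
}

.write_stage <- function(obj, path) {
  utils::write.csv(obj, path, row.names = FALSE)
  path
}

#' Run the full phenotyping pipeline
#'
#' Executes io -> pca -> feature evaluation and validation -> phenotype
#' profile -> (optionally) tSNE + elbow + k-means clustering and subcluster
#' similarity -> inference against a reference group, writing every stage's
#' output as CSV/JSON under `config$out_dir` plus a `manifest.json` with the
#' config, seeds and md5 checksum of every written file. Identical configs
#' produce identical checksums. Stage failures abort with the stage name.
#'
#' @param config list from [pipeline_config()].
#' @return The manifest, invisibly; its `files` entry maps stage outputs to
#'   checksums.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  out_dir <- config$out_dir
  if (is.null(out_dir)) out_dir <- tempfile("phenoplast_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- io ---------------------------------------------------------------
  truth <- NULL
  tab <- stage("io", {
    if (!is.null(config$input)) {
      read_expression_table(config$input, config$protein_columns,
                            config$metadata_columns)
    } else {
      gen <- generate_panel(panel_preset(config$preset, config$effect),
                            seed = config$seed)
      truth <- gen$truth
      gen$table
    }
  })
  tab <- stage("io", average_runs(tab, config$run_field))
  if (config$impute || anyNA(protein_matrix(tab))) {
    tab <- stage("io", impute_missing(tab, k = config$impute_k))
  }
  acct <- accounting(tab)
  df_out <- cbind(metadata(tab), as.data.frame(protein_matrix(tab)))
  files <- c(files, .write_stage(df_out, file.path(out_dir, "table.csv")))

  # --- pca --------------------------------------------------------------
  model <- stage("pca", fit_pca(center(tab)))
  ndims <- stage("pca", significant_dimensions(model$cum_pct_variance,
                                               config$variance_thresh))
  files <- c(files,
    .write_stage(data.frame(dim = seq_along(model$eigenvalues),
                            eigenvalue = model$eigenvalues,
                            pct = model$pct_variance,
                            cum_pct = model$cum_pct_variance),
                 file.path(out_dir, "eigenvalues.csv")),
    .write_stage(as.data.frame(model$scores), file.path(out_dir, "scores.csv")),
    .write_stage(as.data.frame(model$loadings), file.path(out_dir, "loadings.csv")),
    .write_stage(as.data.frame(model$cos2), file.path(out_dir, "cos2.csv")))

  # --- features ---------------------------------------------------------
  specs <- stage("features", .resolve_specs(config$specs))
  feats <- stage("features", evaluate_features(tab, specs))
  val <- stage("features", validate_features(feats, model$scores, ndims,
                                             alpha = config$alpha,
                                             method = config$correction))
  files <- c(files,
    .write_stage(as.data.frame(feats), file.path(out_dir, "features.csv")),
    .write_stage(data.frame(dim = rep(rownames(val$r), ncol(val$r)),
                            feature = rep(colnames(val$r), each = nrow(val$r)),
                            r = as.vector(val$r),
                            p_adjusted = as.vector(val$p_adjusted),
                            significant = as.vector(val$significant)),
                 file.path(out_dir, "validation.csv")))

  # --- phenotype --------------------------------------------------------
  profile <- stage("phenotype", {
    colorize(aggregate_profile(feats, config$group_field, config$group_order),
             mode = "absolute")
  })
  files <- c(files,
    .write_stage(data.frame(group = rownames(profile$medians),
                            as.data.frame(profile$medians, check.names = FALSE)),
                 file.path(out_dir, "medians.csv")),
    .write_stage(data.frame(group = rownames(profile$colors),
                            as.data.frame(profile$colors, check.names = FALSE)),
                 file.path(out_dir, "colors.csv")))

  # --- cluster + similarity --------------------------------------------
  assignment <- NULL
  if (isTRUE(config$cluster)) {
    emb <- stage("cluster", embed_tsne(feats, config$perplexity,
                                       config$max_iter, seed = config$seed))
    curve <- stage("cluster", wss_curve(emb, config$k_min, config$k_max,
                                        seed = config$seed))
    k <- config$k
    elbow <- NULL
    if (identical(k, "auto")) {
      elbow <- stage("cluster", elbow_k(curve))
      k <- elbow$k_star
    }
    assignment <- stage("cluster",
                        kmeans_partition(emb, k, metadata = metadata(feats),
                                         seed = config$seed))
    comp <- stage("cluster", compose_clusters(assignment, config$group_field))
    files <- c(files,
      .write_stage(cbind(metadata(feats), as.data.frame(emb$coords)),
                   file.path(out_dir, "embedding.csv")),
      .write_stage(as.data.frame(curve), file.path(out_dir, "wss.csv")),
      .write_stage(cbind(metadata(feats),
                         data.frame(cluster = assignment$cluster,
                                    subcluster = comp$subcluster)),
                   file.path(out_dir, "clusters.csv")),
      .write_stage(as.data.frame(comp$by_condition),
                   file.path(out_dir, "composition.csv")))
    if (!is.null(elbow)) {
      ej <- file.path(out_dir, "elbow.json")
      jsonlite::write_json(unclass(elbow), ej, auto_unbox = TRUE, digits = NA)
      files <- c(files, ej)
    }

    # subcluster similarity on subcluster median phenotypes
    sub <- comp$subcluster
    keep <- !is.na(sub)
    sub_meds <- stage("similarity", {
      fm <- feature_matrix(feats)[keep, , drop = FALSE]
      do.call(rbind, lapply(split(seq_len(nrow(fm)), sub[keep]), function(i) {
        apply(fm[i, , drop = FALSE], 2, stats::median)
      }))
    })
    if (nrow(sub_meds) >= 3) {
      r <- stage("similarity", correlation_matrix(sub_meds))
      ng <- config$n_groups
      if (is.null(ng)) ng <- min(k, nrow(r))
      struct <- stage("similarity", order_and_cut(r, config$linkage, ng))
      files <- c(files,
        .write_stage(data.frame(entity = rownames(r),
                                as.data.frame(r, check.names = FALSE)),
                     file.path(out_dir, "corr.csv")))
      dj <- file.path(out_dir, "dendrogram.json")
      jsonlite::write_json(list(merge = struct$hclust$merge,
                                height = struct$hclust$height,
                                order = struct$order,
                                labels = struct$labels,
                                groups = as.integer(struct$groups)),
                           dj, digits = NA)
      files <- c(files, dj)
    }
  }

  # --- inference --------------------------------------------------------
  if (!identical(config$inference, "none")) {
    ref <- config$reference_group
    if (is.null(ref)) ref <- profile$groups[1]
    g <- as.data.frame(feats)[[config$group_field]]
    fm <- feature_matrix(feats)
    calls <- stage("inference", {
      if (config$inference == "ora") {
        bounds <- reference_bounds(fm[g == ref, , drop = FALSE],
                                   n_sims = config$n_sims, seed = config$seed)
        do.call(rbind, lapply(setdiff(unique(g), ref), function(grp) {
          cbind(group = grp,
                ora_classify(fm[g == grp, , drop = FALSE], bounds,
                             rule = config$ora_rule))
        }))
      } else {
        as.data.frame(bootstrap_compare(feats, config$group_field, ref,
                                        n_boot = config$n_boot,
                                        alpha = config$alpha,
                                        seed = config$seed))
      }
    })
    files <- c(files, .write_stage(calls, file.path(out_dir, "calls.csv")))
  }

  # --- manifest ---------------------------------------------------------
  # out_dir is excluded from the hashed config: two runs of the same analysis
  # in different directories must agree on every checksum
  cfg_hashed <- config[setdiff(names(config), "out_dir")]
  cfg_json <- jsonlite::toJSON(cfg_hashed[!vapply(cfg_hashed, is.null, logical(1))],
                               auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest <- list(
    package_version = as.character(utils::packageVersion("phenoplast")),
    seed = config$seed,
    config = jsonlite::fromJSON(cfg_json),
    config_md5 = unname(tools::md5sum(tf)),
    accounting = acct,
    ndims = ndims,
    files = stats::setNames(as.list(unname(tools::md5sum(files))),
                            basename(files))
  )
  unlink(tf)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$out_dir <- out_dir
  if (!is.null(truth)) manifest$truth <- truth
  invisible(manifest)
}
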