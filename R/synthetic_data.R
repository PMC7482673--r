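# Synthetic expression panels with planted ground truth.
#
# The generator emulates the statistical structure the workflow assumes:
# positive, right-skewed densitometry values (multiplicative lognormal
# biological variation around a protein baseline), per-group and per-region
# multiplicative effects, additive Gaussian run noise per replicate blot,
# and missing cells at a fixed rate. Ground truth is recorded at the
# feature level (which contrast indices and sums a group effect shifts and
# in which direction), because that is what the downstream analyses are
# asked to recover.

#' Declare a synthetic panel design
#'
#' @param proteins data.frame with columns `name`, `baseline` (> 0) and
#'   optionally `bio_sd` (lognormal sigma of biological variation, default
#'   0.15).
#' @param groups data.frame with columns `label`, `n_cases`, plus one column
#'   per protein giving that group's multiplicative effect (1 = no effect).
#' @param regions character vector of region labels (default none).
#' @param region_effects optional regions x proteins matrix of multiplicative
#'   effects (default all 1).
#' @param runs number of replicate runs (default 2).
#' @param missing_rate fraction of cells masked missing (default 0).
#' @param run_noise_sd additive run noise, as a fraction of the cell's
#'   expected value (default 0.05).
#' @param truth optional data.frame of planted feature-level effects
#'   (`group`, `feature`, `direction`).
#' @return A `panel_design`.
#' @export
panel_design <- function(proteins, groups, regions = character(),
                         region_effects = NULL, runs = 2,
                         missing_rate = 0, run_noise_sd = 0.05,
                         truth = NULL) {
  stopifnot(all(proteins$baseline > 0),
            missing_rate >= 0, missing_rate < 1, runs >= 1)
  if (is.null(proteins$bio_sd)) proteins$bio_sd <- 0.15
  eff_cols <- proteins$name
  missing_eff <- setdiff(eff_cols, names(groups))
  if (length(missing_eff) > 0) {
    stop("groups lacks effect column(s): ", paste(missing_eff, collapse = ", "))
  }
  if (length(regions) > 0) {
    if (is.null(region_effects)) {
      region_effects <- matrix(1, length(regions), nrow(proteins),
                               dimnames = list(regions, eff_cols))
    }
    stopifnot(nrow(region_effects) == length(regions))
  }
  structure(list(proteins = proteins, groups = groups, regions = regions,
                 region_effects = region_effects, runs = runs,
                 missing_rate = missing_rate, run_noise_sd = run_noise_sd,
                 truth = truth),
            class = "panel_design")
}

#' Generate a synthetic expression panel
#'
#' Each measured cell is
#' `baseline * group_effect * region_effect * exp(N(0, bio_sd))` (one
#' biological draw per case x region x protein) plus independent additive
#' Gaussian run noise per replicate, truncated at zero. Cells are then
#' masked missing at the design's `missing_rate`. Byte-identical output for
#' a given design and seed.
#'
#' @param design a `panel_design`.
#' @param seed integer seed.
#' @return List with `table` (an `expression_table` with metadata
#'   `case_id`, `condition`, `region` (if any), `run`) and `truth` (the
#'   design's planted feature-level effects).
#' @export
generate_panel <- function(design, seed = 1L) {
  stopifnot(inherits(design, "panel_design"))
  set.seed(seed)
  pr <- design$proteins
  p <- nrow(pr)
  regions <- if (length(design$regions) > 0) design$regions else NA_character_

  rows <- list()
  case_counter <- 0L
  for (gi in seq_len(nrow(design$groups))) {
    grp <- design$groups[gi, ]
    g_eff <- as.numeric(grp[, pr$name])
    for (ci in seq_len(grp$n_cases)) {
      case_counter <- case_counter + 1L
      case_id <- sprintf("case%03d", case_counter)
      for (reg in regions) {
        r_eff <- if (is.na(reg)) rep(1, p) else design$region_effects[reg, pr$name]
        mu <- pr$baseline * g_eff * as.numeric(r_eff)
        bio <- mu * exp(stats::rnorm(p, 0, pr$bio_sd))
        for (run in seq_len(design$runs)) {
          val <- bio + stats::rnorm(p, 0, design$run_noise_sd * mu)
          val <- pmax(val, 0)
          meta_row <- list(case_id = case_id, condition = grp$label)
          if (!is.na(reg)) meta_row$region <- reg
          meta_row$run <- as.character(run)
          rows[[length(rows) + 1]] <- c(meta_row,
                                        stats::setNames(as.list(val), pr$name))
        }
      }
    }
  }
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
  if (design$missing_rate > 0) {
    mask <- matrix(stats::runif(nrow(df) * p) < design$missing_rate,
                   nrow(df), p)
    for (j in seq_len(p)) df[[pr$name[j]]][mask[, j]] <- NA_real_
  }
  meta <- intersect(c("case_id", "condition", "region", "run"), names(df))
  tab <- expression_table(df, pr$name, stats::setNames(meta, meta))
  list(table = tab, truth = design$truth)
}

# developmental trajectory helper: effect rises from `lo` at the first age
# to `hi` at the peak age index, then relaxes toward `end`
.traj <- function(n_ages, peak, lo, hi, end = hi) {
  up <- seq(lo, hi, length.out = peak)
  down <- seq(hi, end, length.out = n_ages - peak + 1)[-1]
  c(up, down)
}

#' Built-in panel designs
#'
#' Four presets mirroring the designs the workflow was developed on:
#' \describe{
#'   \item{cat_dev}{cat V1 development: 24 cases over 9 age groups
#'     (2-24 weeks) x 16 tissue regions x 2 runs = 768 rows; planted
#'     developmental trajectories (protein sums rising with age, the
#'     GluN2A:GluN2B index rising to a 4-6 week peak, GABAAa1 overtaking
#'     GABAAa3).}
#'   \item{cat_recovery}{recovery-treatment study: 6 rearing conditions
#'     (Normal, MD, RO, BD, ST-BV, LT-BV) x 6 cases x 3 regions x 2 runs;
#'     each condition plants a distinct receptor-balance signature.}
#'   \item{human_dev}{human V1 development: 30 cases in 5 age bins x 3 runs,
#'     7 proteins, no regions (210 cells after run averaging).}
#'   \item{rat_flx}{adult rat fluoxetine study: 4 conditions of 6/6/8/8
#'     animals x 3 runs, 10 proteins; MD perturbs five of the nine preset
#'     features, fluoxetine+MD only the GluN2A:GluN2B index, fluoxetine
#'     alone three features.}
#' }
#' Effect magnitudes at the default `"strong"` setting are approximately
#' 1.5-2.5-fold shifts, the scale of developmental and deprivation-driven
#' changes reported for these proteins; `"moderate"` halves the log effects.
#'
#' @param name preset name.
#' @param effect `"strong"` (default) or `"moderate"`.
#' @return A `panel_design` with planted feature-level `truth`.
#' @export
panel_preset <- function(name = c("cat_dev", "cat_recovery", "human_dev", "rat_flx"),
                         effect = c("strong", "moderate")) {
  name <- match.arg(name)
  effect <- match.arg(effect)
  shrink <- function(e) if (effect == "strong") e else exp(log(e) / 2)

  cat_panel <- data.frame(
    name = c("Syn", "GluN1", "GluN2A", "GluN2B", "GluA2", "GABAAa1", "GABAAa3"),
    baseline = c(1.0, 1.2, 0.9, 1.0, 1.1, 0.8, 0.9),
    bio_sd = 0.15)

  if (name == "cat_dev") {
    ages <- c("2wk", "3wk", "4wk", "5wk", "6wk", "8wk", "12wk", "16wk", "24wk")
    n_cases <- c(3, 3, 3, 3, 3, 3, 2, 2, 2) # 24 cases
    a <- length(ages); peak <- 5 # 6wk
    eff <- data.frame(
      label = ages, n_cases = n_cases,
      Syn     = shrink(.traj(a, peak, 0.6, 1.6, 1.4)),
      GluN1   = shrink(.traj(a, peak, 0.6, 1.7, 1.5)),
      GluN2A  = shrink(.traj(a, peak, 0.4, 1.9, 1.7)),
      GluN2B  = shrink(.traj(a, peak, 1.3, 1.0, 0.9)),
      GluA2   = shrink(.traj(a, peak, 0.5, 1.8, 1.7)),
      GABAAa1 = shrink(.traj(a, peak, 0.5, 1.6, 1.5)),
      GABAAa3 = shrink(.traj(a, peak, 1.2, 0.9, 0.8)))
    regions <- sprintf("R%02d", 1:16)
    truth <- data.frame(
      group = "6wk",
      feature = c("GluN2A:GluN2B", "GABAAa1:GABAAa3", "Protein Sum"),
      direction = c("up", "up", "up"))
    return(panel_design(cat_panel, eff, regions = regions, runs = 2,
                        missing_rate = 0, run_noise_sd = 0.05, truth = truth))
  }

  if (name == "cat_recovery") {
    conds <- c("Normal", "MD", "RO", "BD", "ST-BV", "LT-BV")
    base_eff <- matrix(1, length(conds), 7,
                       dimnames = list(conds, cat_panel$name))
    # distinct receptor-balance signatures per condition
    base_eff["MD", ]    <- c(0.6, 0.8, 0.4, 1.8, 0.6, 1.7, 1.1)
    base_eff["RO", ]    <- c(1.0, 1.2, 1.9, 0.7, 1.8, 0.6, 0.9)
    base_eff["BD", ]    <- c(0.9, 0.7, 0.6, 1.1, 0.8, 2.0, 1.7)
    base_eff["ST-BV", ] <- c(1.4, 1.1, 1.5, 1.4, 0.6, 1.0, 1.6)
    base_eff["LT-BV", ] <- c(1.4, 1.0, 1.4, 0.8, 1.5, 1.3, 0.6)
    base_eff[] <- shrink(base_eff)
    eff <- data.frame(label = conds, n_cases = 6,
                      as.data.frame(base_eff, check.names = FALSE))
    truth <- data.frame(
      group = c("MD", "MD", "RO", "RO", "BD"),
      feature = c("GluN2A:GluN2B", "GABAAa1:GABAAa3",
                  "GluN2A:GluN2B", "GlutR:GABAAR", "GlutR:GABAAR"),
      direction = c("down", "up", "up", "up", "down"))
    return(panel_design(cat_panel, eff, regions = c("C", "P", "M"), runs = 2,
                        missing_rate = 0, run_noise_sd = 0.05, truth = truth))
  }

  if (name == "human_dev") {
    bins <- c("<1yr", "1-5yr", "5-12yr", "12-20yr", ">20yr")
    n_cases <- c(9, 7, 5, 3, 6) # 30 cases
    a <- length(bins); peak <- 2
    eff <- data.frame(
      label = bins, n_cases = n_cases,
      Syn     = shrink(.traj(a, peak, 1.2, 1.5, 1.3)),
      GluN1   = shrink(.traj(a, peak, 1.1, 1.5, 1.2)),
      GluN2A  = shrink(.traj(a, peak, 0.9, 1.6, 1.5)),
      GluN2B  = shrink(.traj(a, peak, 1.4, 1.1, 0.9)),
      GluA2   = shrink(.traj(a, peak, 1.0, 1.6, 1.4)),
      GABAAa1 = shrink(.traj(a, peak, 1.0, 1.5, 1.4)),
      GABAAa3 = shrink(.traj(a, peak, 1.3, 1.0, 0.9)))
    truth <- data.frame(group = "1-5yr", feature = "GluN2A:GluN2B",
                        direction = "up")
    return(panel_design(cat_panel, eff, runs = 3, missing_rate = 0,
                        run_noise_sd = 0.05, truth = truth))
  }

  # rat_flx
  rat_panel <- data.frame(
    name = c("GluA2", "GluN1", "GluN2A", "GluN2B", "GABAAa1", "GABAAa3",
             "Gephyrin", "PSD95", "VGLUT1", "VGAT"),
    baseline = c(1.1, 1.2, 0.9, 1.0, 0.8, 0.9, 1.0, 1.2, 1.0, 0.9),
    bio_sd = 0.15)
  conds <- c("normal", "1wk MD", "flx+1wk MD", "flx")
  base_eff <- matrix(1, length(conds), 10,
                     dimnames = list(conds, rat_panel$name))
  # MD: VGLUT1 up, scaffolding (PSD95, Gephyrin) down, GluN2A up / GluN2B
  # down; receptor effects balance out so the receptor and whole-panel sums
  # stay near normal and exactly five features shift
  base_eff["1wk MD", ] <- c(0.8, 0.9, 1.6, 0.7, 1.0, 1.0, 0.6, 0.6, 1.8, 1.0)
  # flx + MD: only the GluN2A:GluN2B balance stays shifted
  base_eff["flx+1wk MD", ] <- c(1, 1, 1.5, 0.7, 1, 1, 1, 1, 1, 1)
  # flx alone: VGLUT1 down (dragging VGLUT1:VGAT down), more GluN2A
  base_eff["flx", ] <- c(1, 1, 1.5, 0.7, 1, 1, 1, 1, 0.6, 1.0)
  base_eff[] <- shrink(base_eff)
  eff <- data.frame(label = conds, n_cases = c(6, 6, 8, 8),
                    as.data.frame(base_eff, check.names = FALSE))
  truth <- data.frame(
    group = c(rep("1wk MD", 5), "flx+1wk MD", rep("flx", 3)),
    feature = c("VGLUT", "Scaffolding Sum", "GluN2A:GluN2B",
                "Receptors:Scaffolding", "VGLUT1:VGAT",
                "GluN2A:GluN2B",
                "VGLUT", "GluN2A:GluN2B", "VGLUT1:VGAT"),
    direction = c("up", "down", "up", "up", "up",
                  "up",
                  "down", "up", "down"))
  panel_design(rat_panel, eff, runs = 3, missing_rate = 0,
               run_noise_sd = 0.05, truth = truth)
}
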