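# phenoplast

Protein-panel phenotyping for studies of experience-dependent cortical
plasticity. Starting from replicate western-blot densitometry tables (one row
per case × tissue region × blot run, one column per synaptic protein),
`phenoplast` derives *plasticity features* — sums over protein sets and
bounded contrast indices between them — and assembles them into a
colour-coded *plasticity phenotype* per age or rearing condition. The same
features feed clustering, similarity and inference steps that classify which
conditions deviate from normal, and how.

The package is aimed at labs running small-to-medium N designs (developmental
series, deprivation/recovery paradigms, drug studies) across species: because
features are ratios and sums of protein expression, the same nine-feature
phenotype can be computed for cat, human or rat tissue and compared on one
colour scale.

## The method

1. **Preprocess** — average replicate blot runs per (case, region), optionally
   impute residual missing cells by k-nearest neighbours, and centre the
   matrix *without* scaling (abundant proteins keep proportionally more
   variance).
2. **PCA** — singular value decomposition of the centred matrix. Components
   are retained until cumulative explained variance reaches 80%. Variable
   diagnostics (cos², signed variable coordinates, basis-vector amplitudes)
   show which proteins drive each retained dimension.
3. **Feature engineering** — three heuristics propose candidate features:
   sums over high-amplitude protein classes; *a-priori* receptor pairs known
   to regulate plasticity (GluN2A:GluN2B, GABA\_Aα1:GABA\_Aα3, E:I balance);
   and novel pairs whose amplitudes point in opposite directions on a
   retained dimension. An index between protein sets A and B is the contrast
   `(A − B) / (A + B)` ∈ [−1, 1]: 0 is balance, ±1 exclusive dominance, and
   common scaling cancels. Candidates are validated by Bonferroni-corrected
   Pearson correlation against the retained component scores.
4. **Phenotype** — per-group feature medians rendered as a bar stack: gray
   ramp for sums, diverging red (−) / yellow (0) / green (+) for indices,
   with one shared colour scale across datasets in "absolute" mode.
5. **Clustering** — tSNE of the feature table (perplexity 25, 5000
   iterations), within-cluster sum of squares over k = 2–15, k chosen where
   an exponential-decay fit `a·exp(−k/τ) + c` plateaus (k\* = round 4τ), then
   seeded k-means. Subclusters (condition × cluster) are compared by Pearson
   correlation of their median phenotypes with hierarchical ordering.
6. **Inference** — percentile over-representation analysis against bootstrap
   5th/95th bounds of a reference cluster (for small-N discovery), or a
   bootstrap test of median differences (for larger N), flagging each
   feature as over/under-represented or greater/less than normal.

A synthetic-panel generator with planted, feature-level ground truth
(`panel_preset()`: `cat_dev`, `cat_recovery`, `human_dev`, `rat_flx`) makes
the whole chain testable without any external data.

## Worked example

A rat fluoxetine-style study: 4 rearing conditions (normal, 1 week monocular
deprivation, fluoxetine + MD, fluoxetine), 28 animals × 3 blot runs, a
10-protein panel.

```r
library(phenoplast)
gen   <- generate_panel(panel_preset("rat_flx"), seed = 1)
tab   <- average_runs(gen$table)
model <- fit_pca(center(tab))
nd    <- significant_dimensions(model$cum_pct_variance, thresh = 80)   # 4
feats <- evaluate_features(tab, rat_feature_specs())
val   <- validate_features(feats, model$scores, nd)                    # 6 of 9
res   <- bootstrap_compare(feats, "condition", "normal", n_boot = 10000, seed = 1)
subset(as.data.frame(res), call != "none")
```

```
      group               feature observed_diff          p    call
     1wk MD                 VGLUT     0.7702998 0.00019998 greater
     1wk MD       Scaffolding Sum    -1.0366057 0.00019998    less
     1wk MD         GluN2A:GluN2B     0.3901362 0.00019998 greater
     1wk MD Receptors:Scaffolding     0.2091788 0.00019998 greater
     1wk MD           VGLUT1:VGAT     0.2787277 0.00019998 greater
 flx+1wk MD         GluN2A:GluN2B     0.3435374 0.00019998 greater
        flx                 VGLUT    -0.3724563 0.00019998    less
        flx         GluN2A:GluN2B     0.3498212 0.00279972 greater
        flx           VGLUT1:VGAT    -0.1954627 0.00019998    less
```

Reading: MD alone shifts five of the nine features away from normal (more
vesicular glutamate transporter, less receptor scaffolding, a shift toward
GluN2A); adding fluoxetine normalises all of them except the GluN2A:GluN2B
balance; fluoxetine alone moves three features. The colour-coded phenotype
for the same run comes from
`render_phenotype(colorize(aggregate_profile(feats, "condition"), "absolute"))`,
and `run_pipeline(pipeline_config(preset = "rat_flx", specs = "rat", ...))`
executes the entire chain, writing CSV/JSON stage outputs plus a checksummed
manifest.

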