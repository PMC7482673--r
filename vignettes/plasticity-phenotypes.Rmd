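---
title: "Constructing and testing plasticity phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing and testing plasticity phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoplast)
```

## The problem

Studies of experience-dependent plasticity in visual cortex increasingly
measure panels of synaptic proteins (glutamatergic and GABAergic receptor
subunits, scaffolding proteins, vesicular transporters) across ages, rearing
conditions and species. Protein-by-protein curves multiply quickly and miss
higher-order structure: much of what matters biologically is *relative* —
the GluN2A:GluN2B ratio, the excitatory:inhibitory balance — rather than any
single band's intensity. `phenoplast` operationalises a workflow that turns
such panels into a small set of interpretable *plasticity features* and a
colour-coded *plasticity phenotype* per group, then clusters, compares and
tests those phenotypes.

## Model and assumptions

**Input.** A table with one row per (case × region × blot run) and one
nonnegative column per protein, already normalised to loading controls
upstream (densitometry itself is out of scope). Replicate runs are averaged
cell-wise before analysis; a cell is missing only when missing in every run.
Residual missing cells can be filled by k-nearest-neighbour imputation:
distances are Euclidean on column-standardised, mutually observed proteins
(rescaled by the number of shared columns), the imputed value is the mean of
the k = 10 (capped) nearest donors *on the original scale*, and distance ties
break by row order so the result is deterministic. Observed values are never
altered.

**PCA.** The matrix is centred but *not* scaled: the decomposition is of the
covariance, not correlation, structure, so abundant proteins retain
proportionally more variance. Eigenvalues use the sample-covariance
denominator n − 1; every percentage and all downstream results are invariant
to that choice. Because SVD signs are arbitrary and the feature heuristics
compare signs across proteins, each loading column is flipped so its
largest-magnitude entry is positive. Components are retained until cumulative
percent variance reaches the threshold, 80% by default, compared
inclusively. For each protein and component we report the signed variable
coordinate (loading × component standard deviation), its amplitude, and cos²
— which for all-components-retained PCA equals the squared Pearson
correlation between protein and component scores, and sums to one across
components. Zero-variance proteins get an all-zero cos² row with a warning
rather than NaN.

**Features.** A *sum* feature adds a protein set; an *index* feature is the
contrast `(A − B)/(A + B)` between the sums of two disjoint sets. This form
was chosen because it is bounded in [−1, 1], antisymmetric, and invariant to
common positive scaling — exactly the properties needed for a diverging
colour map anchored at zero and for cross-species comparison. Multi-protein
indices contrast the *sums* of each side (not means), consistent with the
sum features; this is worth remembering when sides have unequal sizes.
Proposal uses three heuristics over the retained dimensions: the all-protein
sum plus sums over user-declared classes with at least one high-amplitude
member; an index for every a-priori pair present in the panel; and an index
for every "novel" pair whose amplitudes both exceed the per-dimension
threshold with opposite signs (one protein rises as the other falls). The
amplitude threshold is the 0.75 quantile of |variable coordinate| per
retained dimension — "largest amplitudes" is qualitative in practice, so the
quantile is exposed as a parameter. Proposals carry provenance tags and are
meant to be reviewed: this is a supervised, knowledge-driven step, not an
automatic feature selector. Candidates are validated by two-sided Pearson
correlation against each retained component's scores with a single
Bonferroni correction over all dimension × feature tests (Benjamini-Hochberg
selectable); a feature is validated when significant on at least one
retained dimension.

**Phenotype.** Group-level feature medians are rendered as a bar stack, sums
above indices. Indices map linearly in RGB onto red(−L) → yellow(0) →
green(+L); sums onto white(0) → near-black(max). Under the default
"absolute" translation, L and the sum maximum pool over *all* profiles
passed in one call — this single shared scale is what makes, say, cat and
human phenotypes directly comparable; "local" scales each profile alone and
is appropriate within one dataset. Zero index medians are exactly yellow.
Sum features can be re-expressed as fold change over a reference group's
median (e.g. the youngest age) before plotting. Boxplots use the standard
1.5 · IQR whisker rule with seeded jitter, panel fills matching the
phenotype colours.

**Clustering.** Only feature columns reach the tSNE embedding (metadata
provably cannot affect it — the test shuffles metadata and asserts identical
coordinates). Defaults: perplexity 25, 5000 iterations, 2-D output, seeded;
the backend and version are recorded because tSNE is otherwise
seed-sensitive, and precomputed coordinates can be supplied where an
existing embedding must be reused. The number of clusters comes from the
within-cluster sum of squares over k = 2–15 (k-means, best of 25 restarts
per k — a single random start makes the curve irreproducible) with the k = 1
entry equal to the total centred sum of squares. An exponential decay
`a·exp(−k/τ) + c` is fitted by nonlinear least squares
(initialisation: c₀ = min WSS, τ₀ = span/4, a₀ from the first fitted point;
τ bounded in (0, k_max]) and k\* = round(4τ), half away from zero, clamped
to the searched range: at four time constants the decay has plateaued. The
fit uses the searched range k ≥ 2 by default; the k = 1 total-sum-of-squares
point measures unclustered spread on a much larger scale and, for
well-separated data, drags τ far below where the clustered curve actually
flattens, so it is reported in the curve but excluded from the fit (set
`fit_k_min = 1` to include it). Non-decaying curves abort with a
recommendation to choose k manually.

**Similarity.** Subcluster (condition × cluster) or per-animal phenotypes are
compared by Pearson correlation across features. The dendrogram distance is
the Euclidean distance between *rows of the correlation matrix* — two
entities are close when they correlate the same way with everyone — with
`1 − r` available as an option; linkage is complete by default, Ward.D2
selectable. The cut count is user-supplied: branch heights are judged by
eye in this workflow, not thresholded automatically. Leaf order is
canonicalised by recursive merge traversal, tighter (lower) branch first,
ties broken by the lexicographically smallest leaf label, so relabeling
entities permutes the order consistently.

**Inference.** Two routes, matched to design size. The percentile
over-representation analysis (ORA) bootstrap-resamples the reference
cluster's rows (10,000 resamples, seeded), pools the resampled values and
takes pooled 5th/95th percentiles per feature; a group's feature is *over*
when its 25th percentile exceeds the reference 95th, *under* when its 75th
falls below the reference 5th (the box of a boxplot), with a stricter
10th/90th variant whose calls are provably a subset. The bootstrap
comparison resamples group and reference independently and tests the
difference of medians (medians summarise features throughout the workflow;
means selectable): two-sided p = 2·min(P(diff\* ≤ 0), P(diff\* ≥ 0)) with a
+1/(n_boot + 1) continuity correction. No multiplicity correction is applied
across features by default — calls are raw per-feature p < 0.05, as is usual
for this discovery-style readout — with Bonferroni/FDR flags available. All
quantiles are type 7 (linear interpolation), which matters at the n of 6–8
typical here.

## The synthetic generator

`generate_panel()` emulates the statistical structure the workflow assumes:
positive, right-skewed densitometry values produced as baseline ×
group effect × region effect × lognormal(0, σ_bio) per case × region ×
protein, plus independent additive Gaussian run noise per replicate
(truncated at zero), with optional missingness. Defaults σ_bio = 0.15 and
run noise 5% of the expected value are in the range of between-sample and
between-run variability typical of quantitative western blots. Ground truth
is recorded at the *feature* level — which indices and sums a group's
protein effects shift, and in which direction — because feature recovery is
what the downstream analyses are asked to demonstrate.

Four presets mirror the study designs the workflow targets. `cat_dev`:
24 cases over nine ages (2–24 wk) × 16 regions × 2 runs (768 rows), with
sums rising to a 4–6-week peak and the GluN2A:GluN2B and GABA_Aα1:GABA_Aα3
balances flipping with age. `human_dev`: 30 cases in five age bins × 3 runs
(210 cells after averaging), trajectories compressed toward early life.
`cat_recovery`: six rearing conditions (Normal, MD, RO, BD, ST-BV, LT-BV) ×
6 cases × 3 regions × 2 runs; each condition carries a *distinct*
receptor-balance signature at the default "strong" setting (roughly 1.5–2.5
fold shifts, the scale of deprivation-driven changes reported for these
proteins) — distinctness is part of the preset's contract, since the
cluster-recovery property asserts that planted conditions are recoverable.
`rat_flx`: four conditions of 6/6/8/8 animals × 3 runs on a 10-protein
panel, with protein effects balanced so that exactly five features shift
under MD, one under fluoxetine + MD and three under fluoxetine alone. The
"moderate" setting halves all log effects.

What the generator does **not** emulate: run-level batch structure shared
across proteins, heteroscedasticity across the dynamic range, correlated
biological variation between proteins, and region-by-condition interactions.
Passing tests therefore demonstrate that the pipeline recovers structure of
the planted kind at realistic noise, not that it is robust to every artefact
of real blots.

## Design choices made where the method was open

- The index formula is fixed as the normalised contrast: it is the only
  bounded, antisymmetric, scale-free form consistent with a diverging map
  anchored at zero.
- The rat nine-feature preset (five sums: whole panel, VGLUT1, receptors,
  scaffolding, VGAT; four indices: GluN2A:GluN2B, GlutR:GABA_AR,
  receptors:scaffolding, VGLUT1:VGAT) is a reconstruction from the original
  study's figure labels and is shipped as an editable preset, not a fact.
- Imputation is deterministic (ties by row order), so it takes no seed.
- k-means uses 25 restarts everywhere; the elbow fit excludes the k = 1
  point by default (above).
- Missing tokens in CSVs: empty string, "NA", "NaN", case-insensitive.
- Reference-group "simulation" in the ORA is a nonparametric bootstrap of
  reference rows — no distributional family is assumed.

## Problem sizes and numerical checks

The test-suite simulations use the preset sizes (108 recovery samples, 28
rat animals), 2,000-resample bootstraps, 200 null panels for type-I
calibration and 60 panels per effect size for power; at these sizes the
median-difference bootstrap at n = 8 per group rejects a true null in about
3–4% of feature tests at α = 0.05 — slightly conservative, as expected for
a discrete statistic at small n — and detects a +0.3 index shift
essentially always. Tolerances: centring to 1e-9·n, PCA against an
eigendecomposition oracle to 1e-8, correlation matrices to 1e-12. Degenerate
inputs (constant features, zero-variance proteins, all-zero index medians,
a + b = 0 in the contrast) warn and produce defined output rather than NaN;
genuinely unusable inputs (rows with every protein missing, non-decaying
WSS curves, constant similarity rows) abort with the offending entity named.

## Limitations

Heuristic feature proposal is assistive, not inferential: it inherits PCA's
blindness to variance off the retained dimensions, and the validated-feature
set depends on the amplitude quantile. tSNE geometry is seed- and
perplexity-dependent; only the seeded configuration is reproducible, and the
elbow's k\* inherits k-means stochasticity damped by restarts. The ORA is
descriptive — percentile rules at n < 10 are coarse — and the bootstrap test
makes no multiplicity correction by default. None of the inference steps
model region as a repeated measure within case; samples are treated as
exchangeable within groups, as in the workflow this package systematises.
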