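---
title: "Methods: cell-type-aware mega-analysis of multi-study bulk expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-type-aware mega-analysis of multi-study bulk expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `admega`, the
assumptions each step makes, the tunable parameters and their defaults, what
the synthetic generator does and does not emulate, and the design choices
made where the methodology was genuinely open.

## The model

Bulk tissue expression is a mixture. On the linear scale, the expected
signal of gene $g$ in sample $i$ is

$$ E_{gi} \;=\; \sum_{c} p_{ic}\, B_{gc}\, 2^{\,\delta_{gc}\,d_i}, $$

where $p_{ic}$ is the proportion of cell type $c$ in sample $i$ (summing to
one), $B_{gc}$ is the cell type's baseline expression of the gene, $d_i$ is
the disease indicator and $\delta_{gc}$ a within-cell-type regulatory effect
in log2 units. Two distinct mechanisms change bulk expression in disease:
shifts in $p_{ic}$ (neuron loss, gliosis) and true regulation $\delta_{gc}$.
The pipeline's purpose is to separate them: marker gene profiles (MGPs)
estimate the per-sample composition surrogates, and including them as
covariates in the per-gene model absorbs composition-driven signal so the
disease coefficient reflects regulation.

## Integration of heterogeneous studies

The integration order is fixed and logged in the provenance: probe collapse
(where data are probe-level) → per-study quantile normalization → outlier
removal → batch adjustment → shared-gene selection → joint combine and
quantile normalization → background-guided expression filter → blacklist.

* **Probe collapse.** Probes mapping to zero or several genes are dropped;
  among a gene's remaining probes the one with the highest median expression
  represents it. Ties keep the lexicographically smallest probe id — a
  deterministic, platform-independent rule.
* **Outliers.** For each sample the mean Pearson correlation to all other
  samples of its study is computed once; samples deviating from the grand
  mean of these values by more than `k = 2` standard deviations are removed.
  The rule is single-pass (no re-iteration after removal), and a guard
  aborts if it would remove more than half a study. Whether outliers should
  be removed before or after per-study normalization is not determined by
  the methodology we follow; this pipeline normalizes first, so correlations
  are computed on scale-harmonized samples.
* **Batch adjustment.** Per gene, each batch is centred to the gene's
  overall mean and rescaled to its overall standard deviation. This is the
  non-Bayesian location-scale core of empirical-Bayes batch correction;
  shrinkage of batch parameters across genes is deliberately not applied, so
  small batches are adjusted more aggressively than ComBat would.
* **Shared genes.** A gene is kept when measured on at least
  $\lceil 2/3 \times$ number of platforms$\rceil$ distinct platforms —
  platforms, not studies, because two studies on one array contribute the
  same gene set.
* **Joint quantile normalization with missing genes.** The reference
  distribution is the mean sorted profile of *complete* genes (observed in
  every sample). Each sample's observed values are mapped by interpolating
  the reference at their within-sample rank quantiles $(r-1)/(n_{obs}-1)$;
  ties receive the average of their interpolated values. Consequences:
  samples without missing genes end up with identical sorted vectors, and
  within-sample rank order is preserved exactly. Standard quantile
  normalization does not define behaviour under missingness; this
  interpolation rule is our documented choice.
* **Expression filter.** Sex-specific genes in the non-expressing sex
  (Y-linked genes in females, Xist in males) measure the array background.
  The filter threshold is that background median plus a margin of 0.8 —
  chosen so a background of 5.2 gives a threshold of 6.0 on the log2 scale.
  The gene-level statistic compared against the threshold is the gene's
  median across non-missing samples; the median (rather than the mean or a
  per-sample rule) is a deliberate choice, robust to a single highly
  expressing study.
* **Blacklist.** Genes whose probes are contaminated by transgene constructs
  (Thy1 in Thy1-promoter transgenic models) are removed last.

## Marker gene profiles

Markers are corrected for between-study variation (per gene, each study is
centred to the gene's grand mean), z-scored per gene across samples, and the
samples' scores on the first principal component of the marker matrix form
the raw MGP. The sign is set so the score correlates positively with the
mean standardized marker expression; scores are then min–max scaled to
[0, 1]. Unit scores are therefore *relative within one analysis set* — the
highest sample defines 1 — and are not comparable across runs, nor are they
absolute proportions. Markers missing in any sample are dropped for that
cell type (platform absence makes their study-wise values unusable for a
cross-study component); a single surviving marker degenerates gracefully to
that marker's standardized expression. Whether markers should be z-scored
before the PCA is not fixed by the method we follow; z-scoring prevents
high-variance markers from dominating the component and is the documented
assumption here.

Case-control MGP differences are tested per cell type by a two-sided
Wilcoxon rank-sum test — exact when both groups have at most 10 samples and
no ties, otherwise the normal approximation with midranks and continuity
correction — with Benjamini–Hochberg adjustment across the six cell types.

## Per-gene mixed models

For each gene, $y = X\beta + u_{study} + \varepsilon$ with
$u_s \sim N(0, \sigma^2_{study})$, $\varepsilon \sim N(0, \sigma^2_{resid})$,
fitted by maximum likelihood (not REML, so nested likelihoods are
comparable). $X$ holds the intercept, the disease indicator, and — in the
corrected variant — the six MGP unit scores. The implementation profiles
$\beta$ and $\sigma^2_{resid}$ out analytically and searches only the
variance ratio $\lambda = \sigma^2_{study}/\sigma^2_{resid}$: a coarse
log-spaced grid over $[0, 10^3]$ followed by golden-section refinement of
the bracketing interval, with the boundary $\lambda = 0$ always evaluated
explicitly. The grouped structure gives a closed-form
$V^{-1} = I - \tfrac{\lambda}{1+n_j\lambda}\mathbf{1}\mathbf{1}'$ per study
block, so each evaluation is $O(n)$; fits agree with `lme4::lmer(REML =
FALSE)` to numerical precision (this is verified in the test suite) while
being fast enough for jackknife-times-genes loops.

The disease p-value is a likelihood-ratio test of the nested ML fits
(chi-square, 1 df). The source methodology obtained p-values "by the anova
function", which for ML-fitted nested mixed models is exactly this test;
a single-model ANOVA F-test is the other possible reading, so the Wald
z-statistic is also reported as a secondary column for comparison. Two
caveats are accepted and documented rather than corrected: when
$\hat\sigma^2_{study} = 0$ the LRT null distribution sits on a boundary and
the test is conservative for the variance (not the fixed effect); and with
few studies the ML-based LRT for the disease effect is mildly
anticonservative — on null synthetic cohorts with three studies the
fraction of p < 0.05 sits near 0.06 rather than 0.05. A Satterthwaite or
Kenward-Roger correction would address this but requires REML, which would
invalidate the nested-likelihood comparison.

Genes are ranked within each direction of change (sign of the disease
coefficient) by ascending p, ties broken by larger absolute effect then gene
id; a coefficient of exactly zero joins neither list. BH FDR is computed
across all converged genes.

## Jackknife aggregation

One replicate ranking is produced per left-out study plus the all-study
ranking. A gene's aggregated rank is the **mean** of its per-replicate
directional ranks; final jackknife ranks re-number genes within their
all-study direction by aggregated rank, ties broken by all-study p. The mean
(not the median) is a deliberate choice: a gene whose signal lives in a
single study collapses in exactly one replicate, and a median over
replicates is insensitive to one aberrant value — dropping any *other* study
only concentrates the artifact's effect, so the median can never move
against it. The mean penalizes the inconsistency, which is the purpose of
the jackknife here ("more robust rankings"). Replicates in which a gene
loses all observations (platform absence) are treated as missing and
excluded from the mean. MGPs are estimated once on the full integrated set
and row-subset per replicate; re-estimating them per replicate would
re-anchor the [0, 1] scaling on different samples and make replicate
coefficients incomparable. Study-level (not sample-level) deletion is used,
as the study is the natural exchangeable unit of a mega-analysis.

Rankings before and after MGP correction are compared by Spearman
correlation of signed scores (up-regulated genes positive, most significant
largest; down-regulated negative) over the genes ranked in both.

## Enrichment

Gene sets are scored on the final ordered list by average precision: walking
the ranking, the precision at each member's position is recorded and
averaged. The null distribution is the same-size set placed uniformly at
random (shared across equal-size terms to keep permutations tractable), the
p-value uses the add-one estimator $(1 + \#\{null \ge obs\})/(1 + n_{perm})$
so it is never exactly zero, and BH runs across terms. Mean average
precision was chosen over an interpolated area under the precision-recall
curve; for member-position scoring the two differ only in interpolation
convention. No gene-multifunctionality adjustment is applied, and results
state so; annotation files must be pre-propagated GMT (no ontology-graph
propagation).

## The synthetic generator

The generator emulates the structure of multi-study microarray compendia:

* six cell types with Dirichlet-distributed per-sample proportions,
  baseline concentrations (30, 20, 8, 10, 6, 6) for (pyramidal, dentate
  granule, GABAergic, astrocyte, microglia, oligodendrocyte) — a
  neuron-dominated hippocampal mixture;
* late-phase disease multiplies case-sample concentrations by
  (0.7, 0.7, 0.7, 1.6, 1.8, 1.0): neuronal loss with astro- and
  microgliosis; early phase leaves composition unchanged;
* 20 markers per cell type, each at least 8-fold enriched in its own type;
* per-gene log-normal study bias (sd 0.2 log2), additive per-gene per-batch
  offsets (sd 0.15), residual log2 noise (sd 0.3) — the mixture acts on the
  linear scale and is then log2-transformed, matching how RNA abundances
  average, while noise is log-additive;
* platform gene masks (10% of regular genes absent per platform),
  sex-specific genes expressed at ~9 in the expressing sex and at a
  background of ~5.2 in the other, and a Thy1 gene inflated by 2 log2 units
  in case samples to emulate transgene-probe contamination;
* default cohorts: three studies on three platforms, 10 controls and 10
  cases each.

These defaults define the study conditions for all tests and for
`scripts/acceptance.R`; the magnitudes of true composition shifts are not
quantified by the methodology we follow and are labelled as tunable
generator parameters. Problem sizes were chosen as the smallest at which the
statistical contrasts of interest are comfortably identifiable: 600 genes
and 60 samples per cohort for pipeline properties, 2000 genes for null
calibration, 200 genes for fit-versus-oracle comparisons.

What the generator does **not** emulate: probe-level raw arrays (the
pipeline starts from normalized log2 matrices), correlated marker
co-regulation beyond the mixture itself, platform-specific intensity
response curves, sample-size imbalance as extreme as real compendia (4 to
110 samples), and any single-cell structure. Passing tests therefore
demonstrate the pipeline's internal correctness and its behaviour under the
mixture model's assumptions — not performance on real arrays, where probe
effects and annotation error add variance the generator does not model.

## Known limitations

* MGPs are relative surrogates; a shifted MGP can also reflect coordinated
  within-cell-type regulation of the markers, and residual composition
  effects can survive correction because composition is confounded with
  disease by design.
* The LRT is mildly anticonservative with few studies (see above).
* Location-scale batch adjustment without shrinkage over-adjusts small
  batches relative to empirical-Bayes correction.
* Quantile normalization under missingness assumes each sample's observed
  genes are an exchangeable subset; platform absence is not random with
  respect to expression, so incomplete samples are mapped slightly
  optimistically.
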