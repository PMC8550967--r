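---
title: "Epigenetic biotyping: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epigenetic biotyping: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylotype)
```

This vignette is the package's own account of the science it implements:
the generative assumptions of the synthetic cohorts, the statistical model
behind each pipeline stage, the numerical choices, and what the tests do
and do not establish about real data.

## The pipeline in one paragraph

A normalized beta-value matrix is reduced to stable, collapsed gene-region
methylation values; regions associated with clinical symptom structure but
not with confounders are selected by a resampled correlation screen; PCA
and CCA compress the selected regions and the clinical features into two
orthogonal gene–clinical composite pairs; a linear discriminant in that
latent plane separates a control-like cluster from a distinct cluster, and
its closed-form per-region weights define a biotype score whose sign labels
cases as G1 (control-like) or G2 (control-distinct). Downstream, moderated
t-tests call differentially methylated probes and genes per biotype,
pathway sets are grouped by overlap dissimilarity, and a resampling search
over candidate probes builds a diagnostic marker panel scored by linear
SVMs.

## The synthetic cohort generator

Real cohorts of this kind are access-restricted, so the generator is a
first-class, tested component: it emulates the statistical structure every
downstream stage assumes, with known ground truth.

**Methylation.** Each gene g has a baseline mᵍ on the logit scale
(standard normal, so betas concentrate in roughly (0.12, 0.88)); probe
values are logit-normal: a per-gene, per-sample latent draw (variance
share `within_gene_corr`, default 0.8) plus independent probe noise
(`probe_noise_sd`, default 0.2 logit units ≈ 0.05 beta at midrange),
squashed through the logistic function and clipped to [0.001, 0.999].
The correlation share is deliberately high: arrays of this family show
probe groups within a gene that are strongly correlated — that is what
makes correlation-graph collapsing meaningful — and the default places the
population correlation at the collapse threshold so both merged and
unmerged components occur.

**Biotypes.** Two planted case groups shift methylation on signal genes on
the beta scale: G2 by `delta_g2` (default +0.06, hypermethylation) on its
40 signal genes, G1 by `delta_g1` (default −0.06) on its 40. A fraction
`signal_overlap` (default 0.75) of G1's signal genes are *shared* with
G2's, carrying opposite-direction shifts in the two biotypes. This overlap
is what produces the pooled-contrast washout: on shared genes the pooled
case group's mean shift is (50·δ + 50·(−δ))/100 = 0, so the pooled
case-vs-control contrast calls strictly fewer genes than the per-biotype
contrasts. The washout cannot be produced by power alone in this design
space: with the screen needing region-level clinical correlations above
0.2 and the effect threshold at 0.02, any noise level low enough for the
screen leaves a pooled half-effect of 0.03 comfortably significant at
n = 200. Effect cancellation, not power, is the mechanism.

**Clinical features.** Two latent factors per sample — "Psychological" and
"Physical-Dissociative" — drive 34 named features (CAPS B/C/D, PCL, BDI,
MSC, PSQI, nine SCL-90 subscales, two SF-12 subscales, PDEQ, and generic
extras) through a fixed loading pattern; quality-of-life features load
negatively. The CAPS total is 30 + 18·F₁ plus noise. G2's factor shifts
are large (2.2, 1.0) and G1's mild (0.4, 0.15): G1 is the clinically and
epigenetically control-like biotype, which matches how the biotypes are
defined by the boundary (see below). The G2 signal genes additionally
track F₁ continuously (`methylation_factor_coupling`, 0.01 beta per factor
SD), and 20 separate "physical" genes track F₂ (0.015 beta per SD) so that
the *second* canonical pair has genuine structure — without it that pair
is pure noise and the boundary estimate destabilizes.

**Covariates.** Age, BMI, five cell fractions (Dirichlet-like, summing to
1), three ancestry PCs, smoking, alcohol and deployments are drawn per
sample; each probe receives small random logit-scale coefficients on the
standardized covariates, giving the confounder screen something real to
reject.

**Population vs sample seeds.** `population_seed` (default 100) fixes the
gene/probe layout, baselines, signal-gene identities and per-probe
covariate coefficients; `seed` draws the individuals. Cohorts sharing a
population seed share their biology, which is what makes cross-cohort
model transfer meaningful; two cohorts with different sample seeds are
then discovery and replication draws from one study population.

**What the generator does not emulate:** raw intensity chemistry, probe
type I/II effects, batch/chip structure, missing values, cellular
heterogeneity beyond linear covariate effects, and realistic genomic
autocorrelation along chromosomes. Passing tests therefore establish that
the pipeline recovers the planted structure under its own assumptions, not
that it would behave identically on a real cohort.

## Preprocessing

Filters run in a fixed order: (1) probe sd ≥ 0.05, mean beta in
[0.01, 0.99], non-intergenic; (2) genes keeping ≥ 2 probes are confident;
(3) per-gene correlation graphs (edges at r > 0.8) are collapsed into
averaged regions; (4) optional recall-stability filter at r ≥ 0.65 over
≥ 3 stable samples. Singleton graph components inside confident genes are
retained as single-probe regions so no confident gene silently vanishes.
Undefined correlations (zero variance) count as 0. The graph is scoped per
gene by default (`collapse_scope = "gene"`); a genome-wide scope is
available but regions are gene-level units everywhere downstream. Missing
betas are rejected outright — imputation is upstream's responsibility.

## The clinical screen

A region passes when max |r| against the 34 features exceeds `r_clin`
(0.2) *and* max |r| against every declared confounder stays ≤ `r_conf`
(0.2; making the confounder ceiling symmetric with the clinical threshold
is a package choice — "unassociated with confounders" has no canonical
numeric form). The leave-5-out resampling reruns the whole
scan (confounder screen included) on each subsample; regions are ranked by
pass frequency with ties broken by full-sample max clinical |r|, then id.
Each iteration draws from its own named substream of the master seed, so
early iterations are unchanged when `n_iter` grows. The top-100 cut is a
named constant; nearby values (80, 120) behave similarly in our synthetic
experiments, consistent with the robustness the screen is meant to buy.

## Latent composites (PCA + CCA)

Gene regions are centered but not scaled (shared beta units); clinical
features are z-scored (heterogeneous instruments). Four gene PCs and six
clinical PCs keep the subject-to-feature ratio high enough to stabilize
canonical loadings (a warning fires below ratio 20). CCA is fit on the PC
scores via `stats::cancor`, coefficients rescaled so training variates
have unit variance; the independent check in the tests is a whitened
cross-covariance SVD. Dimensions are tested sequentially by Wilks' lambda
with Bartlett's χ² approximation (exact F approximations were deferred —
at these block sizes the χ² approximation is accurate far beyond the 10⁻⁴
gate). Canonical signs are arbitrary, so each pair is flipped to make its
clinical-side variate correlate positively with the severity column
(`caps_total` by default): the Psychological axis points toward severity.

New-cohort projection reuses the discovery centering — no per-cohort
re-centering — because transferring biotype assignments to new samples
requires the frozen affine map.

## The boundary and the biotype score

The discriminant is a two-class LDA with pooled covariance and equal
priors; the normal is stored unit-norm and oriented so the control-like
class mean scores positive, making "score < 0 ⇒ G2" the distinct,
more-severe side. Two design choices matter here:

* **Cluster labels (default).** The boundary discriminates the two
  2-means clusters of the latent scores, not cases from controls. The
  control-like cluster (the one holding most controls) also contains the
  control-like cases — that is precisely what makes them G1. Training the
  LDA on diagnosis labels instead treats the case class as unimodal when
  it is by construction a mixture, and lets the boundary tilt into
  whatever direction happens to separate G1 from controls; across seeded
  synthetic cohorts the cluster-label boundary recovers planted biotypes
  at 0.98–1.0 versus 0.71–1.0 for the diagnosis-label boundary. The
  diagnosis mode remains available (`boundary_labels = "diagnosis"`).
* **Wilks-gated axes.** Only canonical pairs passing the significance gate
  enter the discriminant (the first pair is always kept); a
  non-significant pair is a noise direction the LDA would overfit.
  Configurable via `lda_significant_only`.

Since region → PC → canonical → discriminant is a chain of affine maps,
the score collapses to Σ wᵢ(regionᵢ − centerᵢ) + c with
w = P_gene·C_gene·normal; the package asserts the closed form and the
explicit three-stage projection agree to 10⁻¹⁰. A score of exactly 0 is
labelled G1 ("otherwise" reads literally). An exact-zero boundary
intercept is not imposed: with cluster labels the midpoint of the two
cluster means need not be the latent origin, so the training-grand-mean
sample scores near, not exactly at, zero. A `flip_sign` flag exposes the
axis-orientation convention.

## Differential methylation

Betas are modeled directly (the effect threshold is a beta difference;
an M-value mode was considered and left out of scope for the default
path). Per probe, least squares on [intercept, contrast, covariates];
residual variances are shrunk via the scaled-F empirical-Bayes model with
(d₀, s₀²) estimated by method of moments on log s² (trigamma inversion by
Newton iteration). The d₀ override (0 = ordinary t, ∞ = complete
shrinkage) exists because those limits are the natural correctness checks.
Δβ is reported as the raw case-minus-control mean — the threshold is on an
unadjusted beta difference even though the test statistic is covariate-
adjusted. A gene is a DMG when ≥ 1 member probe passes both cutoffs; its
direction is that of the largest-|Δβ| member DMP (a "majority" mode is
available). Enrichment is a one-sided hypergeometric test plus a
direction score (n_hyper − n_hypo)/√n — a documented functional substitute
for a proprietary enrichment tool's activation z-score, not a replication
of it.

## Marker panel

Linear SVM with cost 1 on features z-scored by training parameters (the
classifier family is fixed; its hyperparameters were not tuned). "Mean
validation AUC" is the unweighted mean over validation cohorts. The
forward-AUC cutoff takes the smallest k within 0.005 of the trajectory
maximum, with a manual override since a human analyst may prefer a
slightly larger panel. Collinearity pruning greedily keeps the higher-
ranked probe of any pair with |r| > 0.8 (mirroring the region-collapse
threshold). The biotype-aware refinement has no canonical recipe; the
package's choice is greedy forward selection on the mean of
per-biotype validation AUCs with the same 0.005 stopping tolerance.

## Problem sizes and runtime

The default desk-scale cohort is 200 samples × ~4,300 probes over 1,500
genes; the end-to-end experiments use 500 screen iterations and 1,000
panel-search runs (the full-scale analysis would use 5,000 and 100,000).
These sizes keep a complete discovery fit near a minute and the whole
test suite within a coffee break on one CPU while leaving every planted
effect detectable with margin.

## Known limitations

* The recovery guarantees are statements about the generator's world;
  real-data performance depends on structure (batch effects, cellular
  heterogeneity, nonlinear covariate effects) the generator omits.
* The 2-means step assumes exactly one distinct case cluster; more than
  two biotypes would require a different cluster model and label rule.
* Bartlett's χ² for Wilks' lambda is asymptotic; with very small cohorts
  the gate is approximate.
* The screen's correlation thresholds are raw (no multiplicity
  correction) by design — robustness comes from the resampled frequency
  ranking, not from per-correlation inference.
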