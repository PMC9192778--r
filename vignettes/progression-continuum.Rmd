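---
title: "Ordering ductal lesions on a progression continuum: methods and design"
author: "DCIScurve maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordering ductal lesions on a progression continuum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DCIScurve)
```

# The problem

Ductal carcinoma in situ (DCIS) is a non-invasive proliferation of ductal
epithelial cells. Many patients with DCIS never progress to invasive ductal
carcinoma (IDC), yet most receive invasive-disease treatment. A cohort of
micro-dissected ductal lesions — normal epithelium, benign lesions, atypia,
DCIS and IDC, with several lesions per patient and up to three adjacent
replicate sections per lesion — lets one ask where each lesion sits on the
road from normal tissue to invasive disease, and which transcriptional
programs turn on and off along the way.

`DCIScurve` implements that analysis end to end: sample quality control,
normalisation, differential expression with patient blocking, a
principal-curve pseudotime (the *principal curve projection*, PCP),
enrichment scans along the continuum, and a rule-based marker decision tree
that stratifies patients by progression hazard. Because the motivating
data are under restricted access, the package ships a synthetic-cohort
generator that reproduces the cohort's statistical structure together with
ground truth, so every claim the package makes about itself is tested
against planted truth.

# The model, stage by stage

## Normalisation

Raw counts are filtered to genes expressed (count > 0) in at least 5% of
samples, scaled by TMM normalisation factors (trimmed mean of M-values,
via edgeR: 30% two-sided trim on log-ratios, 5% on average log-expression,
inverse-variance weights, reference = sample whose upper quartile is
closest to the mean upper quartile), and expressed as
$\log_2\!\big((y + 0.5) / (N \cdot f + 1) \times 10^6\big)$ — log2
counts-per-million with the voom prior-count convention. The offset pair
(+0.5 count, +1 library) matters: CPM conventions differ between tools,
and downstream thresholds (receptor calls at log2-CPM 6 and 10.5) are
defined on this scale.

## Quality control

Four filters run in sequence, each on the survivors of the last, with
exact bookkeeping (`QCReport`):

1. **Library metrics** — fail on *any* of: < 1 million raw reads, < 15%
   uniquely mapping reads, < 5% of raw reads in genes. The criteria are
   strict "fail if below"; boundary values pass.
2. **Iterative cohort correlation** — within each tissue class, every
   sample's Pearson correlation to the mean log2-CPM profile of the
   *other* samples is computed; while any falls below its threshold the
   worst sample is removed and the mean recomputed. Default threshold
   0.70; IDC 0.65; basal-subtype DCIS 0.65; basal-subtype IDC 0.60
   (invasive and basal samples are genuinely more heterogeneous).
3. **Patient-vs-cohort** — a sample more correlated to the cohort mean
   than to its own patient's mean looks generic rather than
   patient-specific (a likely swap or contamination) and is removed.
   Single-sample patients are exempt.
4. **Iterative patient correlation** — as (2) but within each patient, at
   thresholds 0.80 / 0.75 / 0.75 / 0.70 for the same classes.

Design choices worth stating: the mean profile always *excludes* the
sample being scored (with three or four samples in a class,
self-correlation inflates the statistic enough to mask outliers); an
undefined correlation (zero-variance sample) counts as failing; ties for
"worst" are broken by smallest sample ID so runs are reproducible;
classes with fewer than 3 samples are skipped with a warning rather than
filtered.

## Differential expression and the pseudotime panel

The panel that defines the continuum comes from the DCIS-versus-IDC
contrast restricted to patients carrying usable samples of *both*
tissues, which cancels inter-patient variation. The fit is the
voom-style chain: precision weights from the fitted mean–variance trend
(limma's voom), a single consensus intra-patient correlation, and
generalized least squares with the patient as block, followed by
empirical-Bayes moderation of the residual variances (limma's
`squeezeVar`). The consensus correlation is the tanh-transformed mean of
per-gene intraclass correlations of the group-effect residuals over the
10% most-expressed genes: it is a single cohort-level number, and the
best-measured genes estimate it with the least noise at a fraction of
the cost of a per-gene REML estimate. Because the block structure is
compound symmetry (equal correlation within a patient), the GLS step has
a closed-form per-patient whitening — shrink the block mean, rescale the
rest — which is exact, vectorises across genes, and reproduces limma's
generic blocked fit to machine precision (a standing test asserts this).
One weight-estimation pass is used: re-estimating weights under the
block correlation changed them negligibly while requiring the generic
per-gene fit whose cost the whitening exists to avoid. With moderation,
weights and blocking disabled the fit reduces exactly to the ordinary
two-sample regression t-test, which is how the machinery is validated.

Genes with Benjamini–Hochberg adjusted p below `1e-5` form the panel
(the adjusted scale is the default; a flag exposes raw-p selection, since
either convention appears in practice). Positive log2 fold change means
higher in the *second* factor level.

## The principal curve projection

A PCA is fitted on the contrast samples only, using the panel genes; all
other samples (normal, benign, atypia, the remaining DCIS/IDC) are then
embedded with the fitting-set centring and loadings, so they cannot bend
the axes. A principal curve is fitted to the first two PC scores by the
Hastie–Stuetzle alternation: initialise positions by PC1 rank; smooth
each coordinate against position with a local-linear `lowess` (span 0.6);
discretise the smooth into a polyline (250 vertices); project every
sample orthogonally onto the polyline; re-parameterise by cumulative arc
length; repeat until the mean squared projection distance changes by less
than `1e-4` relatively. Two PCs are used because the second component
carries the transient (EMT-like) wave a PC1 ordering would fold away;
the dimensionality, span and vertex count are exposed as arguments.
Orientation is fixed by biology: the normal/benign end gets the smaller
arc-length positions. Ties in the ordering are broken by sample ID.

The alternation is not a strict descent method; near its fixed point the
mean squared distance oscillates by a fraction of a percent, so the
monotonicity test allows 0.5% relative slack and the fitter returns the
best iterate if the limit is reached.

Early/late segments (E1–E2, L1–L2) are placed at rank quantiles
(0.15, 0.45, 0.55, 0.85) by default — the study-defining publication
shows these regions graphically without printing numeric positions, so
the placement is configurable and intervals are left-closed (a sample
exactly at E1 belongs to E1–E2).

## Enrichment along the continuum

*ssGSEA* scores each sample against each gene set by the rank-weighted
running-sum statistic (exponent 0.25), followed by the standard min–max
normalisation of the whole score matrix; scores are rank-based and hence
invariant to monotone transformations of expression. The *window scan*
slides a 100-sample window in 50-sample steps along the PCP order (a
final partial window is dropped to keep power constant), calls genes
up-regulated in-window versus all remaining samples (moderated DE,
adjusted p < 0.05), and tests each set by one-sided hypergeometric
over-representation against the full gene background with BH adjustment
across sets; window/set pairs below `1e-5` are flagged. The within-window
DE cutoff is the package's explicit choice (the global DE convention) and
is configurable. Trend fits of any per-sample score on position use OLS
with percentile confidence bands from residual-resampling bootstrap
(default 10,000 replicates, seeded).

## Receptor calls and the hazard decision tree

ER/PR/Her2 status is called positive at log2-CPM ≥ 6 (ESR1), ≥ 6 (PGR)
and ≥ 10.5 (ERBB2); boundary values count as positive; triple negative
means all three negative.

The marker tree operates per patient on in-situ samples only. A patient
is called *IDC-associated* for a gene when at least two samples sit on
the IDC-associated side of the gene's expression cut (low for the anchor
CAMK2N1, the Progressor genes MNX1/HOXC11/ANKRD22/ADCY5 and the rescuer
THRSP; high for the refiner SCGB2A1); patients with a single usable
sample are Unassigned. The tree: anchor low → Higher Hazard; otherwise
3–4 Progressors down → Higher Hazard (with a still-high THRSP recorded
as a mitigating sub-label when SCGB2A1 is low); 0–1 down and SCGB2A1 low
→ Lower Hazard; 0–1 down but SCGB2A1 high → Higher Hazard; a tally of
exactly 2 is not covered by the printed rules and is returned as
Indeterminate rather than guessed. Per-gene cuts default to pooled
medians because the study's cut table is in unpublished supplementary
material; a config table overrides them. HOXC10 and HOTAIR are carried
as annotations but take no part in the tree (they added no
discriminatory power in the source analysis). Group enrichment is
reported as the ratio of outcome-wise membership proportions, to one
decimal; cumulative-frequency comparisons dichotomise at the pooled
median (again a package choice, exposed) and use the two-sided Fisher
exact test.

# The synthetic cohort

`simulateCohort()` draws, per patient, a number of lesions (default
uniform 1–16 over 145 patients) with tissue types at the cohort's
empirical mix (8% normal, 9% benign, 9% atypia, 60% DCIS, 14% IDC), and
per lesion a latent progression coordinate `t` uniform within
tissue-specific bands (normal 0–0.15, benign 0.08–0.30, atypia
0.25–0.50, DCIS 0.30–0.95, IDC 0.80–1.00); replicate sections (1–3)
share their lesion's `t`. Expression is negative-binomial (dispersion
0.15) around log2 means composed of: a gene baseline; a basal program
declining linearly in `t` (amplitudes 2–4); an EMT program with Gaussian
bumps at `t` = 0.25 and 0.90; a proliferation program rising only after
`t` = 0.30 (just past the first EMT peak); a per-patient, per-gene
random effect (SD 0.7 — patient identity is a dominant signature of bulk
biopsy expression, and weaker values make the patient-vs-cohort filter
remove far more clean samples than a real cohort loses); and
outcome-linked marker states. Outcome (Pure vs NotPure, default 37%
Pure) is assigned per patient independently of `t`; Pure patients carry
no invasive lesions, but their DCIS occupies the same `t` band as
anyone else's, so position on the continuum carries no outcome signal by
construction. Markers are bimodal at the patient level: each marker is
in its IDC-associated state with probability 0.65 for NotPure and 0.25
for Pure patients, shifting expression by ±3 log2 units — a mixture, not
a uniform shift, matching the skewed/bimodal distributions that motivate
the per-patient two-sample call rule. Receptor genes follow the
patient's molecular subtype (e.g. ERBB2 high only in Her2-type
patients). `injectLowQuality()` corrupts a configurable fraction of
samples (default 10%) by shuffling counts across genes and dividing
depth by ten, which reliably drops their cohort correlation below 0.70.

What the generator does *not* emulate: compositional library effects
beyond TMM's reach, gene–gene correlation within programs beyond the
shared latent coordinate, isoform structure, copy-number variation, or
any coupling between outcome and position. Passing recovery tests
therefore demonstrate that the pipeline recovers the structure it
assumes, not that real lesions obey that structure.

# Problem sizes used by the test suite

The recovery criterion runs five cohorts at the generator's default
scale (~2,400 retained sections × 5,000 genes) through QC, panel DE and
curve fitting; the 20-seed hazard-enrichment check uses cohorts with the
same rates and effect sizes at 60 patients × 2,000 genes; unit tests use
cohorts of 300–2,000 genes and 5–40 patients; the bootstrap coverage
experiment uses 200 replicate simulations of 200 points with 2,000
bootstrap resamples each. These sizes are the package's own choices,
large enough that each assertion's statistic is stable under its fixed
seed.

# Known limitations

* The Welch comparison of PCP positions between outcome groups treats
  sections as independent; with strong intra-patient correlation it is
  anti-conservative, and the pipeline reports it as a descriptive
  statistic only.
* The consensus intra-patient correlation is a single number; per-gene
  correlation structure is absorbed by the empirical-Bayes moderation,
  not modelled.
* The principal curve is one-dimensional by design; branching
  trajectories are out of scope.
* Marker cuts default to pooled medians, which is only sensible when the
  cohort mixes both outcome groups in reasonable proportion.

# A short worked example

```{r example, eval = FALSE}
cfg <- pipelineConfig(simulate = cohortConfig(nPatients = 40,
                                              nGenes = 2000),
                      seed = 3)
res <- runFullPipeline(cfg, "pipeline-out")
res$summary$pseudotime$truthSpearmanAbs  # ordering recovery vs truth
res$summary$hazard$lowerHazardFold       # marker-tree enrichment
```
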