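---
title: "Methods: slide classification and transformation scoring from segmentation outputs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: slide classification and transformation scoring from segmentation outputs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(odynr)
```

## Scope and model

`odynr` implements the analysis stages of a computational-pathology pipeline
for oral epithelial dysplasia (OED) that sit *downstream* of deep
segmentation. The inputs are per-slide epithelium and dysplasia label masks
(with a stated microns-per-pixel resolution), classified nuclear instance
polygons, and a clinical cohort table. From these it computes:

1. **OED classification.** The dysplasia–epithelium ratio
   $R_\mathrm{Epith} = |D \cap E| / |E|$, the fraction of epithelium-mask
   pixels also labelled dysplastic. Slides are called dysplastic when
   $R_\mathrm{Epith} \ge t$, where $t$ is selected on a training set as the
   F1-maximising candidate among midpoints of consecutive sorted unique
   ratios plus $\{0, 1\}$ (ties to the smaller threshold; the inclusive
   $\ge$ boundary is fixed for reproducibility). The numerator intersects
   dysplasia with the epithelium — the only reading that guarantees
   $R_\mathrm{Epith} \le 1$. Slides with an empty epithelium mask are flagged
   `no_epithelium` and excluded from classification metrics, never scored 0.

2. **Transformation risk (ODYN-score).** Slides are tessellated into
   512 × 512 px patches with 256 px overlap at 0.5 mpp, restricted to patches
   covered by dysplasia. Each patch yields 168 nuclear morphological and
   spatial features. A 168–64–2 multilayer perceptron (leaky ReLU, dropout
   0.2 after the hidden layer) scores patches; the slide score is the mean of
   the top 50 % ranked patch scores ($\lceil n/2 \rceil$ tiles, so odd counts
   round up and the set is never empty). Training is weakly supervised under
   slide-level labels by iterative draw-and-rank sampling (IDaRS): per slide
   and epoch, the $k = 5$ patches currently ranked highest for the slide's
   own label plus $r = 45$ uniformly drawn patches enter the pool, optimised
   in minibatches of 256 with Adam under a symmetric cross-entropy (SCE)
   loss.

3. **Evaluation statistics.** AUROC (rank/Mann-Whitney formulation with
   midranks), AUPRC (step-wise precision–recall integration), pixel mask
   metrics and specificity, Mann-Whitney U with rank-biserial effect size
   $r_{rb} = 2U_x/(n_x n_y) - 1$, permutation Spearman tests, Shapiro–Wilk
   gates, Benjamini-Hochberg FDR, Kaplan-Meier curves with log-rank tests,
   Harrell's C-index, multivariate Cox models (Efron ties), the conservative
   summary $p = \min(1, 2\,\mathrm{median}(p_\mathrm{repeats}))$, and the
   top-ten-tile nuclear count / area-ratio comparison between true-positive
   and true-negative slides.

## Coordinate and unit conventions

One convention is used everywhere: x = column, y = row, 0-based, pixel
centres at integer coordinates; patches are half-open windows
$[x, x+s) \times [y, y+s)$. Mask rescaling between resolutions uses
nearest-neighbour interpolation (labels stay categorical). Morphometrics are
reported in microns via the mask mpp, densities per mm².

## The patch grid

Origins advance by `patch_size - overlap`. When the stride grid leaves an
uncovered margin, one final origin per axis is shifted back so the last
patch ends exactly at the region border — preserving the stated patch size
without fabricating tissue by zero-padding. Regions smaller than one patch
yield a single origin at 0 with a logged `edge_padded` flag. A scoring patch
is retained when its dysplastic-pixel fraction is at least `min_coverage`
(operation default 0.5; see *Synthetic study conditions* for the pipeline's
default on synthetic cohorts).

## The 168-feature registry

The registry is data-driven (`feature_registry()`) and totals exactly 168
features per patch:

* **Morphological (72).** For each of the four compartment classes —
  dysplastic epithelial, normal epithelial, intra-epithelial lymphocyte
  (IEL: "other" nucleus whose centroid lies on an epithelium pixel) and
  peri-epithelial lymphocyte (PEL: "other" nucleus outside the epithelium) —
  the count, the density per mm², and mean and SD of eight shape measures:
  area, perimeter, circularity $4\pi A/P^2$, eccentricity and major/minor
  axes of the moment-equivalent ellipse, solidity, equivalent diameter.
* **Spatial (96).** Within-class 1st/2nd nearest-neighbour distance
  statistics, cross-class nearest-neighbour distances for all ordered class
  pairs, overall nearest-neighbour statistics, per-class Clark-Evans
  aggregation indices and centroid dispersion, Delaunay-graph degree and
  edge-length statistics (overall, per class, and class-pair edge mixing
  fractions), per-class nuclear area fractions, and the three-way tissue
  composition of the patch (dysplastic epithelium / normal epithelium /
  other), which partitions the patch exactly.

The exact feature list of the original study is not printed in its main
text; this registry reconstructs the stated family (morphological + spatial,
168 total) and is replaceable without code changes. Compartment assignment
uses the centroid-in-mask rule — unambiguous and cheap. Statistics over
empty sets are imputed as 0; class absence is always recoverable from the
count features, so the imputation is information-preserving for the MLP.
Nuclei on patch borders follow half-open membership: counted once on a
non-overlapping grid, possibly several times on the overlapping scoring grid
(patches are treated as independent instances, consistent with IDaRS).

Because no Delaunay triangulation routine is available in the supporting
stack used here, the package carries its own Bowyer-Watson implementation,
property-tested against the empty-circumcircle criterion.

## The SCE loss and its constants

$\mathcal{L} = \alpha\,\mathrm{CE} + \beta\,\mathrm{RCE}$ with
$\mathrm{CE} = -\log p_y$ and $\mathrm{RCE} = -\sum_c p_c \log q_c$, where
$q$ is the one-hot label and $\log 0$ is replaced by a finite clamp $A$, so
$\mathrm{RCE} = -A(1 - p_y) \ge 0$. Defaults $\alpha = \beta = 1$ and
$A = -4$ follow the loss's originating literature convention; with
$\beta = 0$ the loss reduces exactly to cross-entropy (asserted to 1e-12 in
the tests). Features are z-scored with training-pool statistics stored in
the model. The source study names the loss and sampler but not the epoch
count, learning rate, or what the inner 90/10 validation split is consulted
for; here the defaults are 30 epochs at Adam learning rate 1e-3, and the
validation slides select the checkpoint with the best slide-level AUROC.
An optional decoupled weight decay (`train_config(weight_decay =)`) is
exposed for small, high-dimensional cohorts where unregularised training
overfits noise features.

## Cross-validation protocol

Repeated patient-grouped stratified 5-fold CV, 3 repeats with derived seeds
(15 models). All slides of one patient share a fold; within each job the
non-test patients are split 90/10 by patient into training and validation.
Every slide receives one out-of-fold score per repeat; results are reported
per repeat, summarised as the mean over repeats (the protocol's headline
statistic for AUROC, AUPRC and C-index), and pooled (per-slide mean score
over repeats). External cohorts are scored by evaluating all 15 models and
averaging the per-model slide scores. The checkpoint criterion is the
validation slide-level AUROC with ties broken by the continuous slide-level
cross-entropy — on a handful of validation slides the AUROC alone saturates
after a few epochs and would freeze training at a heavily undertrained
model.
Risk groups dichotomise the slide score at 0.5 by default (the source study
does not state its cutoff; the value is config-exposed).

## Survival analyses

Follow-up is right-censored at 96 months (eight years) before any model
fit. Analyses run at slide level, mirroring slide-count reporting; a
patient-level collapse is possible by pre-aggregating scores. WHO grade
enters as two stratifications: G1 (mild vs moderate/severe) and G2
(mild/moderate vs severe). The Cox model incorporates the risk score with
age and sex (and site where available), with Efron tie handling — month
resolution ties are common. For the Mann-Whitney p-value the package uses
exhaustive enumeration of group assignments when
$\binom{n}{n_x} \le 20000$ — exact also under ties — and the normal
approximation with tie and continuity correction otherwise; full enumeration
at the commonly quoted $n_x n_y \le 400$ boundary (e.g. 20 × 20) is
combinatorially infeasible, so the cutoff is expressed in enumeration size
rather than in the product of group sizes.

## Synthetic study conditions

The generator (`synth_config()`, `generate_cohort()`) emulates the three
pipeline inputs with a controllable transformation effect. Chosen once, and
what they mean:

* Canvas 768 px at 0.5 mpp — the scoring resolution, so no rescale is
  involved; the 512/256 scoring grid yields 4 patches per slide.
* Epithelium: a thick smoothed band (sum of two sinusoids for the centre
  line, half-width 16–24 % of the canvas), mimicking mucosal architecture
  and guaranteeing dysplasia ⊆ epithelium by construction; dysplasia is a
  contiguous column sub-band hitting a drawn area fraction, default range
  (0.3, 0.6) *identical for both outcomes* so that at `nuclear_effect = 0`
  the outcome-conditional feature distributions are exchangeable — the
  transformation signal enters only through `nuclear_effect`.
* Nuclei: ellipses polygonised at 16 vertices, semi-axes scaled so the
  polygon area equals the drawn target exactly (closed-form morphometric
  oracles). Class morphology defaults: dysplastic epithelial 55 µm² (CV
  0.35, eccentricity 0.75), normal epithelial 35 µm² (CV 0.20, 0.60),
  "other" 18 µm² (CV 0.15, 0.40); stylised densities give roughly 400–600
  nuclei per slide with non-overlapping centroids (6 µm minimum
  separation). `nuclear_effect` shifts the dysplastic area mean by that many
  class SDs, widens its CV, and multiplies the stromal "other" (PEL) density
  by `1 + effect` in transforming slides — matching the direction of
  published feature analyses (more PELs in transforming cases).
* Outcomes: exactly `round(transform_fraction × n)` transforming patients by
  sorted draw; event times exponential with rate
  $\log(2)/30 \cdot e^{\text{effect}}$ months⁻¹ (a proportional-hazards
  generator enabling C-index and Cox recovery checks); non-transforming
  patients censored at the 120-month administrative horizon, or earlier with
  probability `censor_rate`.
* One integer seed drives per-slide derived substreams, so slides regenerate
  identically regardless of generation order.
* On these synthetic cohorts the pipeline default `grid.min_coverage` is
  0.1: the band geometry bounds the achievable per-patch dysplastic coverage
  near 0.2, so the 0.5 operation default (appropriate for whole-slide-scale
  dysplastic regions) would discard nearly all synthetic patches.

What the generator does *not* emulate: stain/texture appearance, scanner
variation, nuclear segmentation errors, spatially correlated architecture
(fronts of invasion, rete ridges), or non-proportional hazards. Passing
tests on synthetic cohorts therefore demonstrate correctness of the
computational pipeline and recoverability of planted effects — not clinical
performance.

## Numerical choices and degenerate inputs

* Masks: any nonzero pixel maps to 1 (tolerant of 255-valued PNG exports);
  colour images without a binarization rule are rejected.
* Degenerate nucleus polygons (< 3 vertices or zero area) are dropped with a
  logged count; self-intersecting contours are repaired by their convex hull
  with a logged count.
* Empty patches produce the all-zero feature vector and are flagged; slides
  with no epithelium or no dysplastic patches are flagged and excluded from
  the relevant stage with logged counts — never silently scored.
* Threshold selection ties break to the smaller threshold; `which.max`
  semantics make this deterministic.
* The Bowyer-Watson triangulation treats near-collinear triangles as having
  an unbounded circumcircle; fully collinear point sets fall back to the
  path graph along the line.

## Problem sizes used in the checks

The packaged tests and the acceptance script run the full pipeline on
cohorts of 60 single-slide patients (4 scoring patches per slide, ~500
nuclei per slide) for the effect-recovery and null conditions, a 40-patient
cohort (16 controls) for threshold classification, and n = 500 for Cox
parameter recovery. These sizes keep each full-pipeline run in the
one-to-three-minute range while leaving the planted effect comfortably
detectable.

## Known limitations

* The feature registry is a reconstruction at name level; the family and
  count match the published description, individual names may not.
* Out-of-fold AUROC on small cohorts is a noisy estimate; under a global
  null it is known to sit slightly below 0.5 (finite-sample anti-correlation
  between training-fold and test-fold feature–label associations), which is
  why the null band in the checks is [0.4, 0.6] rather than a point value.
* The MLP is trained full-batch-per-epoch at these cohort sizes (one
  256-patch minibatch); larger cohorts exercise the minibatch path.
* Survival analyses assume proportional hazards and independent censoring;
  no diagnostics beyond convergence checks are run.
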