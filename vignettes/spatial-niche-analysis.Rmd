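---
title: "Weakly supervised spatial niche analysis with cytoniche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised spatial niche analysis with cytoniche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Multiplexed proteomic imaging (CODEX, IMC and related platforms) yields,
after segmentation and annotation, a *cell table*: one row per cell with
planar coordinates, a few dozen marker intensities, a cell-type label and
a sample-level phenotype. The scientific question addressed here is
*which cell subsets, in which spatial contexts, are associated with the
phenotype* — without any cell-level labels. Supervision is weak: only the
patient's condition is known, and the subsets of interest may cut across
the annotated cell types.

cytoniche answers this with a three-stage procedure:

1. **Multi-cell inputs.** Every analysis unit is the unordered set of the
   k nearest neighbours (Euclidean distance on x, y, within one image) of
   an *anchor* cell, represented as a K x M matrix of marker values and
   carrying one label. Three anchor regimes give three analysis modes:
   random anchors labelled by condition (*global*), anchors of a chosen
   cell type plus a background class of random-anchor neighbourhoods
   (*local*), and typed anchors labelled by the mean expression of one
   marker over the neighbourhood, with that marker removed from the
   features (*functional*, a regression).
2. **A permutation-invariant single-layer network.** Each cell is passed
   through the same bank of affine filters with relu; responses are
   pooled across the cells of an input (mean by default, max available);
   a linear head produces class scores (softmax) or a real prediction.
   Because pooling is the only interaction between cells, the output is
   invariant to any reordering of the rows — the property the multi-cell
   design requires. Training runs a random hyperparameter search (number
   of filters, learning rate, dropout) and keeps the model with the best
   validation score.
3. **Characterisation.** The *filter response* of a single cell is the
   plain scalar product of its marker vector with one filter's weights
   (no bias, no activation); cells with positive response are *selected*.
   Selected cells are characterised by per-patient frequency comparisons
   (two-sided Wilcoxon rank-sum), by cell-type enrichment scores, and by
   per-marker Kolmogorov-Smirnov statistics between selected and
   non-selected cells.

## The enrichment scores

Per image, with N cells, N_T of type T, K cells in the union of the
anchor neighbourhoods and the superscript S marking selected cells, the
*local* score is

    ES_T = (K_T^S / E_T^S) / (K_T / E_T),
    E_T = K * N_T / N,     E_T^S = K^S * N_T^S / N^S.

The denominator measures how concentrated type T is in the anchor niche
at all; the numerator measures how concentrated the *selected* cells of
type T are. ES_T > 1 therefore means the selected subset of T is drawn
into the niche beyond the type's own spatial affinity. The *global*
variant drops the neighbourhood and reduces to a proportion ratio,
`(N_T^S / N^S) / (N_T / N)`. Cohort values are medians across patients
(each patient first reduced by the median over its images) with the
(unscaled) median absolute deviation as the error bar. Scores whose
expectations are zero are reported as undefined and excluded from the
medians — never imputed.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | swept, 10–100 | neighbourhood size (cells); chosen on validation, see below |
| `n_anchors_per_image` | 100 | random anchors per image (global mode) |
| `threshold` | 0 | filter-response cut for selection |
| `n_trials` | 200 | random-search trials |
| `n_filters` | 1–8 | filters per trial (sampled) |
| `learning_rate` | 1e-4–1e-2 | sampled log-uniformly |
| `dropout` | 0, 0.25, 0.5 | on the pooled layer (sampled) |
| `epochs` / `patience` | 50 / 5 | Adam, batch 64, early stopping on validation loss |
| `offset` | 1e-3 | in the `log(offset + x)` intensity transform |
| `alpha` | 0.05 | significance level for the local k-selection rule |
| `min_cells` | 10 | smallest group for which a KS row is scored |

The neighbourhood size is selected from the sweep as follows. Global
mode: the k with the smallest validation condition-vs-condition p-value.
Local mode, two steps: keep only the k at which the conditions differ
significantly, then rank the survivors by the significance of the winning
condition against background. Ties go to the smaller k, and no
multiple-testing correction is applied across k (reported as-is). With
several filters, each filter is analysed individually and the reported
filter is the one with the most significant validation frequency
comparison.

## Preprocessing and splits

Raw intensities are transformed as `log(1e-3 + x)` (natural log) and each
marker is standardised to mean 0, sd 1 across the *whole dataset* — the
convention of the lineage this method descends from. A
`scaling_scope = "train_only"` knob restricts the moments to chosen
samples for users who prefer strict train/test separation. Constant
marker columns are an error (naming the marker), not a silent drop.
Splits hold out whole patients: test samples are drawn per condition
without replacement, and only the remaining samples' inputs are
partitioned 80/20 into training and validation, so no patient straddles
the test boundary. Reported accuracy is input-level (not a
patient-majority vote).

## Numerical choices

* k-NN ties are broken by ascending `cell_id`, making every neighbourhood
  bit-reproducible; the anchor is excluded from its own neighbourhood
  (`include_anchor` flag to change).
* The Wilcoxon comparison is exact for untied groups of at most 12
  samples and a continuity-corrected normal approximation otherwise; a
  fully tied comparison returns p = 1 with no direction.
* The KS statistic is computed as the exact sup of |ΔECDF| over the
  pooled support, valid under ties; it is invariant to monotone
  transforms, so whether it is computed on raw, log or min-max-scaled
  intensities is immaterial (min-max scaling is only used for display).
* Training trials whose validation loss becomes non-finite are excluded
  from model selection rather than scored zero.
* All randomness flows through named seeds (anchor, split, training,
  generator); reruns with the same config reproduce output digests.

## The synthetic cohort generator

`generate_cohort()` emulates the schema of a segmented multiplexed
cohort: conditions, patients, images; cells on the unit square; types
from a frequency catalog with two identity markers each; latent marker
values = type signature + Gaussian noise; and a *planted effect* — in the
affected condition, a fraction of target-type cells lying within a radius
of an anchor-type cell get an additive shift (in latent sd units) on
chosen markers. `ground_truth_mask()` recovers exactly the shifted cells
so selection can be scored for recall against truth.

Raw intensities are lognormal, `exp(latent)`. This is a deliberate
choice: the heavy-tailed lognormal is the standard model for imaging
intensities, and the `log(1e-3 + x)` / Z-score preprocessing inverts it
almost exactly, so a planted "3 sd" effect is still a 3 sd effect on the
analysis scale. (A softplus link was evaluated and discarded because the
log step compresses planted effects by roughly a third, silently
de-calibrating every downstream power statement.)

Placement is uniform by default — the minimal spatial structure the k-NN
machinery needs. A `colocalized` option places chosen fractions of chosen
types near anchor cells (`colocalized_types`), evenly spread over anchors,
emulating tissue niches with a characteristic composition.

### Why the recovery experiment uses a colocalized, multi-type niche

Two structural facts, established analytically and confirmed with an
oracle classifier that sees true compositions, shaped the validation
cohort (`recovery_config()`):

* Under uniform placement, a typed anchor's neighbourhood in the
  *unaffected* condition is distributionally identical to a background
  neighbourhood from that condition — there is simply no signal — so
  three-class (condition/condition/background) accuracy is capped near
  0.83 no matter the classifier. Local-mode recovery is therefore
  evaluated under tissue-like colocalization, which is also the setting
  the local analysis exists for.
* Conversely, if the target type colocalizes *fully* with the anchor, the
  local enrichment score degenerates: the denominator `K_T / E_T`
  saturates and ES falls below 1 even for a perfectly recovered subset.
  The recovery niche therefore holds two types: a companion type carrying
  the compositional signature (for classification), and the target type
  at mild colocalization, keeping a large out-of-niche reservoir against
  which the selected subset's concentration is measurable.

The frozen study condition: 12 samples per condition, 4 images of 1000
cells each, anchors at 0.4 percent, companion/target colocalization
0.28 / 0.13, identity signatures at +3 latent sd, planted shift of 3 sd
on a signature-free marker for 80 percent of in-niche target cells, and
k = 12 with 20 search trials (120 epochs, patience 15). The null
calibration uses a smaller cohort — 6 samples per condition, 2 images of
100 cells, zero effect — with 60 replicates and a deliberately cheap
search (2 trials), since calibration concerns the test, not the
classifier. These sizes are the package's validation
design, chosen so the experiments are informative at desk scale.

### What passing tests do and do not show

The synthetic cohorts have iid Gaussian latent noise, exchangeable
patients (no patient random effects), perfectly annotated types and no
segmentation artifacts, spillover or batch structure. Passing the
end-to-end tests shows the machinery is correct and the statistics are
calibrated under the model's own assumptions; it does not certify power
or error control on real CODEX/IMC data, where intensity noise is not
lognormal-iid and patient heterogeneity inflates frequency variance.

## Known limitations

* When niche *composition* is discriminative (as it must be for the
  background class to be separable), trained filters load on identity
  markers as well as on shifted markers. The selected subset is then
  mildly niche-type-enriched in *both* conditions, which biases the
  control condition's enrichment score above 1. The planted contrast
  survives (affected exceeds control), but "control ES = 1" should not
  be expected exactly whenever the classifier uses composition.
* The functional (regression) mode can only explain label variance that
  is visible in the remaining M-1 markers; a functional marker
  uncorrelated with composition is unpredictable by construction, and
  the reported R² will honestly be near zero.
* Background inputs are drawn around random *cells*; in strongly
  clustered tissue a background anchor occasionally sits inside a niche
  and is then genuinely indistinguishable from a typed-anchor input —
  an identifiability limit of the three-class design, not a bug.
* Patient-level heterogeneity is handled only through the rank-sum test
  on per-patient frequencies; there is no mixed-effects model.

## A minimal run

```{r example}
library(cytoniche)

cfg <- recovery_config(seed = 1)
tab <- generate_cohort(cfg)
pp  <- preprocess_intensities(tab)

inputs <- build_local_inputs(pp, anchor_type = cfg$anchor_type,
                             k = 12, seed = 2)
inputs <- assign_sets(inputs, make_split(pp, 1, 0.2, seed = 3))

fit <- niche_train(inputs, task = "classification",
                  n_trials = 20, seed = 4)
glance(fit)

sel   <- select_cells(fit$model, pp, inputs, scope = "all")
freqs <- frequency_per_sample(sel, inputs)
compare_frequencies(freqs, "cond_a", "cond_b")

enrichment <- aggregate_es(local_es(tabulate_counts(pp, sel, inputs)))
autoplot(enrichment)

differential_markers(pp, sel)
```
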