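# cytoniche

Weakly supervised detection of condition-associated cell subsets in
tissue microenvironments, from segmented multiplexed-imaging cell tables
(CODEX, IMC and similar).

## Who this is for

You have a per-cell "flat table" — coordinates, M marker intensities, an
annotated cell type, and a patient-level phenotype (two survival groups,
disease stages, ...) — and you want to know *which cell subsets, in
which spatial neighbourhoods, distinguish the phenotypes*, without any
cell-level labels and without assuming the relevant subset matches an
annotated type.

## The method

**Multi-cell inputs.** The unit of analysis is the unordered set of the
k nearest neighbours (Euclidean, per image) of an *anchor* cell,
represented as a K × M marker matrix with one label. Three modes:

* **global** — random anchors, labelled by the sample's condition;
* **local** — every cell of a chosen anchor type, plus a background
  class ("BG") of random-anchor neighbourhoods, so the classifier must
  find signatures specific to that type's niche;
* **functional** — typed anchors labelled by the mean neighbourhood
  expression of one marker (removed from the features), a regression on
  local signalling.

**Model.** A permutation-invariant single-layer convolutional network:
per-cell affine filters + relu, pooled across the cells of an input
(mean or max), then a softmax or linear head. Training runs a random
hyperparameter search (number of filters `F ∈ 1..8`, learning rate
`10^U(-4,-2)`, dropout `{0, .25, .5}`) and keeps the model with the best
validation score; whole patients are held out for testing.

**Characterisation.** The *filter response* of a cell is the scalar
product `w_f · x` (no bias, no activation); cells with positive response
are *selected*. Selected cells are characterised by

* per-patient selected-cell frequencies, compared across conditions with
  a two-sided Wilcoxon rank-sum test (exact for small untied groups);
  the neighbourhood size k is chosen to optimise this p-value on
  validation (with a two-step rule against background in local mode);
* a per-cell-type **enrichment score**; for the local mode, with
  N/N_T/K/K_T counts of all and type-T cells in the image and the
  neighbourhood union, and superscript S marking selected cells:

      ES_T = (K_T^S / E_T^S) / (K_T / E_T),
      E_T = K·N_T/N,   E_T^S = K^S·N_T^S/N^S

  reported as the cohort median with MAD error bars; ES_T > 1 means the
  selected cells of type T concentrate in the anchor niche beyond the
  type's own spatial affinity;
* per-marker two-sample **Kolmogorov–Smirnov statistics** (an effect
  size in [0,1]) between selected and non-selected cells, overall and
  per cell type.

A synthetic cohort generator with planted, spatially localized,
condition-specific marker shifts (`generate_cohort()`,
`ground_truth_mask()`, `recovery_config()`) makes every stage testable
end to end without external data.

## Worked example

A planted-niche cohort: a rare anchor type whose niche holds a companion
type and a target type; in condition `cond_a` only, in-niche target
cells carry a +3 sd shift on marker `m11`.

```r
library(cytoniche)

cfg <- recovery_config(seed = 1)
tab <- generate_cohort(cfg)
pp  <- preprocess_intensities(tab)          # log(1e-3 + x), Z-score

inputs <- build_local_inputs(pp, anchor_type = cfg$anchor_type,
                             k = 12, seed = 2)
inputs <- assign_sets(inputs, make_split(pp, 1, 0.2, seed = 3))

fit <- niche_train(inputs, task = "classification", n_trials = 20,
                  seed = 4, epochs = 120, patience = 15)
glance(fit)
#>   task           n_trials n_failed best_trial val_score test_score
#> 1 classification       20        0         12     0.959      0.875

ranked <- filter_comparisons(fit$model, pp, inputs)
f <- ranked$filter[which.min(ranked$p_condition)]   # filter 4 here

sel   <- select_cells(fit$model, pp, inputs, filter_index = f,
                      scope = "all")
freqs <- frequency_per_sample(sel, inputs)
compare_frequencies(freqs, "cond_a", "cond_b")
#>   group_a group_b n_a n_b median_a median_b direction   p_value
#> 1 cond_a  cond_b   12  12    0.481    0.363 cond_a    0.0000364

enr <- aggregate_es(local_es(tabulate_counts(pp, sel, inputs)))
enr[enr$cell_type == "type_2", ]
#>   condition cell_type median_es mad_es n_samples n_excluded selected_ratio
#> 1 cond_a    type_2         1.59 0.0830        12          0          0.608
#> 2 cond_b    type_2         1.32 0.118         12          2          0.548

ms <- differential_markers(pp, sel)
head(ms[ms$scope == "all", c("marker", "ks", "rank", "direction")], 3)
#>   marker    ks  rank direction
#> 1 m11    0.731     1 higher      <- the planted marker
```

Reading the output: the three-class model (conditions + background)
reaches 0.96 validation accuracy; selected-cell frequency is
significantly higher in the affected condition (p ≈ 4e-5); the target
type's enrichment score exceeds 1 in the affected condition (1.59, and
it exceeds the control's 1.32); and the planted marker `m11` ranks first
by KS among all twelve markers. `autoplot()` methods exist for the
enrichment table, the marker-shift table and the fit; `run_pipeline()`
drives the whole sequence (k sweep included) from one config list or
YAML file, and `inst/cli/cytoniche.R` wraps `simulate` / `run-all` for
shell use.

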