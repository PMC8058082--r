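---
title: "Severity subtyping with random-forest proximities: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Severity subtyping with random-forest proximities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamforest)
```

## The problem

Psychiatric case-control cohorts are heterogeneous: among subjects who meet
a diagnostic threshold, symptom burden can differ enough that the "case"
label hides clinically distinct groups. `pamforest` implements a pipeline
for discovering such subtypes and asking whether they are biologically
real. The idea is to let a supervised learner define what "similar
patients" means: a random forest grown to separate cases from healthy
controls (HC) on a large bank of individual clinical items induces a
proximity between subjects — the fraction of trees in which two subjects
fall in the same terminal node — and `1 - proximity` is a dissimilarity
tailored to the clinical signal. Partitioning around medoids (PAM) on that
dissimilarity, restricted to cases, yields candidate subtypes, which are
then (i) profiled on clinical summary scales, and (ii) validated by
classifying them from feature classes that played no role in their
construction: multi-omic blood biomarkers, medical comorbidities,
neurocognitive scores, demographics, psychiatric history, and pre-military
trauma exposure.

## Pipeline and estimators

1. **Forest and proximity** (`fit_forest`, `rf_proximity`). Bagged CART
   with Gini splits (the `randomForest` engine), `floor(sqrt(p))` features
   per split, unlimited depth, minimum node size 1, and per-tree bootstrap
   samples of the full training size. The package stores the in-bag
   matrix, per-tree terminal-node assignments, and per-tree votes, and
   derives everything else from those: out-of-bag (OOB) vote scores, the
   tie-aware Mann–Whitney AUC, and the proximity matrix in two modes
   (`all_trees`, the classical definition and the default; `oob_pairs`,
   restricting each pair's tally to trees where both subjects are out of
   bag — the literature uses both and the original description does not
   pin one down, so the mode is a recorded option).
2. **Clustering** (`pam_cluster`, `discover_subtypes`). The k-medoid
   objective is solved exactly by deterministic enumeration whenever at
   most 10000 candidate medoid subsets exist — which covers the pipeline's
   own case-clustering step (74 cases, k = 2) — and by classical
   BUILD + best-improvement SWAP with lowest-index tie-breaks beyond that
   scale. The split exists because SWAP is a local search: on small
   random dissimilarities it returns a suboptimal medoid pair a few
   percent of the time (as does any faithful PAM implementation), and a
   deterministic pipeline should not owe its subtypes to a local optimum
   when the exact solution costs microseconds. `k = 2` is
   the default — with modest case counts, more clusters are rarely
   defensible — but is exposed. Clusters are named by their mean
   severity-scale total (`S1` = least severe), never by size.
3. **Diagnostics** (`silhouette_scores`, `embed_2d`). Silhouettes use the
   convention `s = 0` for singleton-cluster members and are reported for
   controls as a third group on the full-cohort forest distance — the
   natural joint construction when one forest produced all pairwise
   proximities. The 2-D view is a diffusion map by default (Gaussian
   kernel, bandwidth = median off-diagonal dissimilarity, eigenvectors of
   the normalized Markov matrix scaled by eigenvalues); classical metric
   scaling is available and exact for Euclidean input.
4. **Shaving** (`shave`, `select_optimal`). Iterative removal of the
   `max(1, floor(0.1 * |set|))` least Gini-important features with
   refitting, tracking OOB AUC per round; the selected model is the
   smallest set within `auc_tolerance = 0.005` of the best AUC (ties: the
   higher AUC, then the later round). The gradual 10% schedule and the
   small tolerance read "largest AUC with the smallest set of unshaved
   variables" as: within a hair of the optimum, prefer parsimony. Both are
   configurable and recorded in every trace. Per-round seeds are
   `seed + round - 1` so any round can be refit in isolation.
5. **Profiling** (`profile_subtypes`). For each summary scale: one-way
   ANOVA across HC/S1/S2 plus pairwise Wilcoxon rank-sum tests (exact
   enumeration for tie-free samples up to n = 25 per group, tie- and
   continuity-corrected normal approximation above), flagged at a
   family-wise threshold of `1e-4` — implemented as a hard cutoff rather
   than an m-dependent divisor, since that is how such tables are
   conventionally reported. The PCA of summary scales z-scores variables
   and orients PC1 so higher = more severe. Published-table comparisons
   are reproduced from summary statistics (`t_test_from_summary`, pooled
   variance by default since two-group ANOVA is the table convention, with
   Welch available) and counts (`chi_square_2x2`, Pearson, no continuity
   correction).
6. **Marker validation** (`classify_contrast`, `marker_direction_tests`,
   `cca`, `compare_marker_panels`). Each contrast (S2 vs S1, S1 vs HC,
   S2 vs HC, cases vs HC) is classified per feature class and with all
   classes pooled. The top-5 retained markers per contrast get Welch
   t tests of mean equality — Welch because biomarker variances are rarely
   equal across severity groups — with Bonferroni correction over the
   tests actually performed (5 markers x 4 contrasts = 20 gives the 0.0025
   threshold), and an up/down direction call in the more severe group only
   when significant. CCA uses column standardization, SVD whitening with
   relative-tolerance rank truncation, and an SVD of the whitened
   cross-product; panel comparison removes the intersection first and
   reports the leading three correlations.

## The synthetic cohort generator

No subject-level data are distributable for studies of this kind, so the
generator is a first-class module that emulates the statistical structure
the analysis assumes, at the study's scale: a discovery sample of 74 cases
and 71 HC, a validation sample of 26 cases and 36 HC, 16 clinical
instruments (a 17-item severity scale scored 0-8 per item — a CAPS
analog — and fifteen 10-item scales scored 0-4), 342 biomarkers in seven
subclasses, and five weaker auxiliary classes. Two case subtypes are
planted in proportions 0.35/0.65 (26 and 48 of 74 discovery cases).

**Item model.** Ordinal items follow a graded-response-style model,
`item = round(range * pnorm(l*(z - c) + g*(u - cu) + h*(v - cv) + e))`,
with three latent traits per subject:

- *severity* `z`: graded HC < S1 < S2; drives every scale, strongly the
  severity scale (loadings in the upper half of `item_loading_range`) and
  weakly the rest;
- *general distress* `v`: elevated in all cases; loads on ~30% of
  non-severity items with intermediate reliability;
- *severe-symptom profile* `u`: graded across subtypes from none (S1) to
  the full shift (S2); loads on ~40% of non-severity items with low noise,
  emulating severe-end symptoms (dissociation, phobic avoidance) that
  controls and milder cases rarely endorse and that are reported reliably
  when present.

A strictly unidimensional severity factor was tried first and discarded:
with a single factor plus independent item noise, a case-vs-HC forest
collapses all cases into pure terminal nodes after the first clean split
(between-subtype proximity near 1), and when items are degraded enough to
prevent that, the milder subtype's members are carved away from controls
along idiosyncratic noise-driven paths, so their mutual proximity falls
*below* their proximity to the severe subtype and no clustering method can
recover the plant. Real symptom data are not unidimensional — the severe
end of psychopathology differs in profile, not just level — and the
secondary traits encode exactly that, while preserving the severity
ordering of every scale mean (S2 > S1 > HC throughout) and leaving the
first principal component of the summary scales dominant with roughly
equal weights.

**Calibration.** The item bank (loadings, difficulties, noise) is frozen
from an internal constant — instruments are fixed questionnaires, so two
cohorts differ in subjects, never in items. The default latent severity
means `(0, 5.83, 7.30)` were solved once by Monte-Carlo root-finding so
the severity-scale totals average near 3.4 (HC), 54.3 (S1) and 75.6 (S2),
the characteristic spacing of a clinician-administered severity scale in
a deployed-population study; the group means are verified by simulation in
the test suite. With one planted subtype (`subtype_proportions = 1`) the
profile trait is absent, so any clusters PAM reports there are noise — the
null condition used to check that silhouettes stay low when nothing is
planted.

**Markers.** Biomarkers are Gaussian with equicorrelated residuals within
each subclass (`block_correlation = 0.2`) — the simplest covariance that
still stresses shaving with redundant features. Twenty markers are
informative with standardized shifts graded 0 / 0.6 / 1 times
`marker_effect_size = 0.8` across HC/S1/S2; most are down-regulated with
severity, and at least one up-regulated lactate-like metabolite is always
planted. The choice of many individually-weak markers makes the selected
panel's AUC grow with panel size, so shaving has a real optimum to find,
and reproduces the qualitative ordering of contrast AUCs (severe-vs-HC
highest, within-case lowest). Auxiliary classes use the same machinery
with smaller effects (0.3–0.7; demographics carry none), so biomarkers
out-classify every other feature class by construction.

**What the generator does not emulate.** Missing data (complete-case input
is required; the original studies' imputation is irrecoverable), realistic
assay noise and batch structure, demographic confounding, genotype-like
discrete features, and item-level distributions of any real instrument
(scale ranges come from published scoring ranges, not cohort data).
Passing tests on this generator show the pipeline recovers structure *of
the kind assumed*; they cannot certify behavior under messier real-world
violations.

## Numerical and testing choices

- AUC is computed by the pair-count identity, exact under ties; the ROC
  grid is the empirical score set, so no threshold grid is tuned.
- OOB scores for subjects in-bag in every tree are flagged `NA` and raise
  an error where an AUC is required — never silently imputed. At the
  4000-tree pipeline default such subjects cannot occur in practice
  (each subject is OOB in about 37% of trees).
- PAM asserts its cost is non-increasing across SWAP iterations at run
  time; ties everywhere break toward the lowest index for determinism.
- Per-stage pipeline seeds are fixed offsets from the global seed; two
  runs with the same configuration are byte-identical (checksummed
  manifests, no timestamps in artifacts).
- Problem sizes in the test suite are scaled for a desk-scale run: forests
  of 100–600 trees for unit properties, 1000 trees for the ten-seed
  subtype-recovery study (the pipeline default is 4000; at 1000 trees the
  proximity estimate is stable enough that recovery is limited by the
  data, not the tally), and 1500 trees for marker-panel shaving, matching
  the regime where importance rankings stabilize.

## Known limitations

- **Selection bias of OOB-guided shaving.** Importance-guided elimination
  re-uses every subject: features that spuriously separate the classes in
  this sample survive shaving, and the selected round's OOB AUC then
  validates on the same subjects. On pure-noise data the selected-model
  AUC is therefore optimistically biased (around 0.7 at n = 100 with 30
  candidate features), even though the *full* model's first-round OOB AUC
  is unbiased. This is the classical bias of non-nested feature
  selection; the shaving trace keeps every round's AUC so the honest
  full-model estimate is always available, and selected-model AUCs should
  be read as internally validated conditional on the selected panel, not
  as unbiased generalization estimates. Nested (cross-validated)
  selection is deliberately out of scope.
- The proximity geometry of Gini-greedy forests genuinely limits severity
  resolution among cases once nodes purify; subtype recovery therefore
  depends on severe-specific items existing in the bank. Cohorts whose
  instruments lack such items will show the saturation failure mode the
  generator's design section describes, and low silhouettes should be
  read as "no recoverable structure".
- PAM is run once (deterministic BUILD+SWAP), not with random restarts;
  for `k = 2` at these sizes the property tests show BUILD+SWAP reaches
  the global optimum, but for larger `k` that guarantee weakens.
- The family-wise threshold for the clinical tables is a reported
  convention, not an adaptive correction; with a different number of
  scales the `alpha_family` parameter should be reconsidered.
- `oob_pairs` proximity with few trees can leave pairs with no qualifying
  tree; the package flags them and refuses only at `n_trees >= 1000`,
  where such pairs indicate a real problem rather than bad luck.

## A short run

```{r example, eval = FALSE}
cohort <- generate_cohort(cohort_config(seed = 1))
fit <- discover_subtypes(cohort, n_trees = 1000, seed = 2)
print(fit)
profile <- profile_subtypes(cohort, fit)
print(profile)
groups <- analysis_groups(cohort, fit)
classify_contrast(cohort, groups, c("S2", "HC"), "biomarker",
                  n_trees = 1500, seed = 3)
```

The full pipeline, with artifact directory and manifest, is
`run_pipeline(pipeline_config(seed = 1))`, and
`scripts/acceptance.R` reruns the headline quantities from scratch.
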