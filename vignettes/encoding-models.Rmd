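---
title: "Voxel-wise encoding of sentence-level semantic structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise encoding of sentence-level semantic structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sentencode)
```

## The scientific problem

When a speaker produces "the musician kicks the pianist", the brain must bind
each noun to its thematic role: who acts (the agent) and who is acted upon
(the patient). Mirror sentences use the same words with swapped roles and
therefore mean different things; passivization swaps surface order without
changing the roles. `sentencode` implements a complete analysis pipeline for
asking *where* in the brain such sentence-level relational structure is
encoded, using voxel-wise encoding models over single-trial fMRI beta maps,
together with a synthetic-data generator so that every stage can be validated
against planted ground truth.

The pipeline has five stages:

1. **Stimulus design** — a balanced set of noun–verb–noun sentences;
2. **Featurization** — binary predictor vectors at several levels of
   relational specificity;
3. **Per-voxel encoding** — cross-validated linear prediction of single-trial
   betas and a diagonal-contrast generalization score;
4. **Group inference** — permutation + bootstrap cluster tests;
5. **ROI model comparison** — leave-one-participant-out voxel selection and
   linear mixed-effects contrasts.

## Stimulus design

The built-in lexicon has 16 nouns (8 sports people, 8 musicians) and 16
transitive verbs (8 contact verbs taking agent/patient roles, 8
experiencer-subject perception verbs taking experiencer/stimulus roles).
Excluding identical agent and patient, the pool holds
$16 \times 15 \times 16 = 3{,}840$ candidate sentences.
`select_balanced_set()` draws 288 of them under hard constraints: every verb
18 times; every noun 18 times as agent and 18 as patient; every (noun, verb)
pair at least once in each role; each of the eight
agent-category × verb-category × patient-category patterns exactly 36 times;
repeated unordered noun pairs minimized greedily.

Rather than searching randomly for a feasible set, the constructor schedules
per-verb category-cell counts cyclically (so cell totals are exact by
construction), builds per-verb agent and patient noun multisets from global
quota queues, and pairs agents with patients greedily by lowest current pair
usage, with a local swap repair to avoid identical-noun sentences. This makes
selection fast, exact and reproducible for any seed; infeasible targets
(fewer than 16 sentences per verb) are rejected with an explanatory error.

Half of the sentences are assigned active voice within every category
pattern; passives are split between the two Dutch word orders with a global
alternation so the overall split is exact. Voice never enters featurization —
it exists so that surface order and thematic roles are decorrelated, which is
the design's point. Scheduling distributes 42 production trials of interest,
6 question trials and 12 fillers into each of six 60-trial runs, with verbs
exactly balanced across runs and per-run noun-role counts within 2 of each
other (the tolerance is our reading of "similar distribution across runs";
it is checked, not assumed, by `audit_design()`). The 36 question-trial
sentences are drawn jointly with the production sentences so the 288-sentence
balance identities hold for the pooled set.

## Encoding models

`featurize()` maps a sentence to a binary vector; all role assignment is
*deep*: the agent slot is the deep subject (agent or experiencer), the
patient slot the deep object (patient or stimulus), so actives and their
passivized forms featurize identically.

| model | predictors | what it encodes |
|---|---|---|
| `bag_of_nouns_cat` | 2 | noun categories present (no roles) |
| `broad_roles` | 8 | category × thematic role |
| `narrow_roles` | 64 | category × verb × role |
| `bag_of_verbs` | 16 | verb identity |
| `bag_of_nouns_specific` | 16 | noun identity |
| `noun_specific_broad_roles` | 64 | noun × thematic role |
| `full_relational` | 512 | noun × verb × role |

`noun_specific_broad_roles` is built with 16 nouns × 4 roles, paralleling
`broad_roles`. `full_relational` is featurized and counted like the others
but is flagged at fit time with a warning: at ~240 training sentences a
512-predictor regression is heavily rank-deficient, and we fit it by
minimum-norm least squares rather than refusing. Column order within each
model is fixed and internal; design matrices carry labelled columns. No
intercept column is included — the regression stage owns the intercept.

## The generalization statistic

For each participant, `vw_encode()` runs leave-one-run-out cross-validation.
On the training runs it fits, per voxel, ordinary least squares with an
intercept (minimum-norm via SVD pseudoinverse when rank-deficient; no ridge
penalty, since the estimator is plain multiple regression). For a held-out
run with $n$ usable trials it forms the $n \times n$ matrix

$$D_{ij} = (\hat y_i - y_j)^2,$$

z-scores all $n^2$ entries jointly (population SD), and takes

$$s = \overline{D^{z}_{\text{on-diagonal}}} -
      \overline{D^{z}_{\text{off-diagonal}}},$$

the contrast between correctly matched prediction–observation pairs and
mismatched pairs. Scores are averaged over the six folds and multiplied by
−1, so informative voxels are positive. Three numerical choices are worth
stating:

* **z-scoring dimension.** All $n^2$ entries are z-scored jointly, per run
  and voxel, using the population SD. Row- or column-wise alternatives would
  change magnitudes but not the sign logic; the joint form is the simplest
  reading and is what the tests freeze.
* **Degenerate inputs.** If all entries of $D$ are equal the score is 0 with
  a `degenerate` attribute. If either vector is constant the contrast is zero
  by symmetry and is returned as exact 0.
* **Duplicate test sentences** (identical feature rows in a held-out run) are
  retained; their predictions tie, which only dilutes the diagonal contrast.

The implementation computes the statistic for all voxels at once from moment
sums ($\sum \hat y^k$, $\sum y^k$, $k \le 4$), which is algebraically exact
and is verified in the tests against a literal $D$-matrix implementation to
1e-12. Cross-validated predictions are likewise computed through a
precomputed fold matrix $A_{\text{test}} A_{\text{train}}^{+}$; permuting the
sentence→feature mapping within runs is then a column permutation, which is
what makes hundreds of permutation maps per participant affordable. The
algebraic identity with the refit-per-permutation route is asserted in the
test suite.

Trials marked unusable (attrition) are excluded before fold construction;
runs left with fewer than two usable trials are dropped with a warning, and
fewer than two surviving runs is an error.

Maps are smoothed *after* scoring (`smooth_map()`, default 8 mm FWHM,
$\sigma_{\text{vox}} = \text{FWHM} / (v \cdot 2\sqrt{2\ln 2})$ ≈ 1.359 voxels
at 2.5 mm). Smoothing is mask-aware and mass-preserving: each voxel's value
is redistributed with a kernel renormalized to the in-mask neighbourhood, so
edge voxels are not attenuated and the in-mask total is preserved to
numerical precision.

## Group inference

`permutation_maps()` rebuilds the full per-participant pipeline after
shuffling the sentence→feature assignment within each run (within-run, so
fold sizes are preserved and the null pipeline is exchangeable with the
observed one), 100 times per participant by default.
`bootstrap_group_null()` draws, 10,000 times by default, one permutation map
per participant uniformly with replacement and averages them, giving the
group-mean null. Voxelwise p-values use the add-one rule
$p = (r+1)/(B+1)$; suprathreshold voxels ($p < 0.005$) form connected
components (18-connectivity by default, configurable to 6 or 26). Each
bootstrap map is thresholded identically and its maximum cluster size
collected; observed clusters are tested against this max-size null and
Benjamini–Hochberg corrected at $q < 0.05$. The max-cluster-size completion
of "cluster threshold estimated via bootstrapping" is the standard one; a
pooled (global) height threshold is available behind
`analysis_config(height = "global")` for the alternative reading.

One statistical subtlety found during validation: binomial calibration
checks of the voxelwise false-positive rate are only valid on *unsmoothed*
maps, because smoothing correlates neighbouring voxels and invalidates the
independence assumption behind binomial bounds (the rate itself stays
nominal). The calibration tests therefore run unsmoothed; cluster-level
power tests run smoothed, as the full pipeline does.

## ROI analysis

`lopo_select_voxels()` selects, for each held-out participant, the ROI voxels
whose one-sample group t (score vs. 0 across the *remaining* participants)
exceeds 2.4, falling back to 1.68 when none survive, and to an empty
selection (row omitted, with a warning) when even that fails. The t statistic
is the one-sample t across the N−1 remaining participants' maps — the only
statistic computable from the stated inputs. Selection never reads the
held-out participant's own data; a perturbation test asserts this.
`roi_model_performance()` then averages each participant's own (smoothed, by
default, matching the whole-brain maps) map over their selection.

`compare_models()` fits a linear mixed model (performance ~ model × ROI ×
modality with by-participant random effects; factors with one level present
are dropped). Each term is tested with a likelihood-ratio chi-square by
refitting the ML model without that term's model-matrix columns under
sum-to-zero contrasts — dropping columns rather than formula terms keeps main
effects testable in the presence of their interactions. The default random
structure `(1 + roi | participant)` is automatically simplified to a random
intercept on singular or non-converging fits, with a message. Pairwise model
contrasts within ROI × modality cells are computed with **emmeans**
(asymptotic df, uncorrected by default, as is conventional for planned
pairwise follow-ups; `adjust` is exposed). The exact random-slope structure
is exposed as an argument rather than guessed.

## The synthetic-data generator

`generate_dataset()` emulates the study conditions: ~38 participants × 6 runs
× 42 production trials, one beta map per trial on a 20×20×20 grid of 2.5 mm
voxels (large enough for 8 mm smoothing and cluster inference, small enough
for minutes-scale simulation). Planted signal lives in spherical blobs
(default radius 3 voxels) whose voxels respond as a linear function of one
model's features; per-voxel weights are drawn i.i.d. standard normal and
rescaled so the signal SD over the design equals
`signal_amplitude × noise_sd`, making `signal_amplitude` the per-voxel SNR.
Noise is i.i.d. Gaussian per trial and voxel — the pipeline ingests beta
maps, not time series, so temporal autocorrelation, HRF convolution and
motion are deliberately out of scope. Production imperfection is emulated by
attrition (default 5% of trials unusable) and substitution (default 23% of
sentences replaced by a different lexicon-conforming sentence of the same
voice, mirroring the observed rate of acceptable-but-different productions);
substituted sentences drive the betas, as produced sentences do.

What passing tests on these data do and do not show: they validate the
estimator, its null calibration and its power under idealized noise; they do
not certify behaviour under spatially correlated noise, inter-subject
anatomical variability, or real preprocessing artifacts, and no real-data
effect size should be read off the simulations.

## Simulation sizes used by the validation suite

The calibration check uses 10 participants on the 20³ grid with 50
permutations per participant and 2,000 bootstrap draws. The recovery and
ROI-specificity checks use 20 simulated studies of 8 participants on a 12³
grid with 30 permutations and 500 bootstrap draws each, at SNR 2 — sizes
chosen once to give near-certain recovery for a real effect and stable
chance-level rates for null ROIs, while keeping the whole suite at
minutes-scale. The full-scale defaults (38 participants, 100 permutations,
10,000 bootstraps) remain the package defaults in `pipeline_config()`.

## Known limitations

* The balanced-set constructor targets the documented constraint family;
  other constraint systems (e.g. exact pair-repeat minimality) would need an
  ILP formulation it does not attempt.
* Minimum-norm OLS is the only estimator; there is deliberately no ridge
  option, to keep the estimator the plain regression it is specified to be.
* Cluster inference assumes exchangeability of within-run permutations; if
  trials within a run were strongly serially dependent this would be
  anticonservative. Beta-map inputs make this a minor concern.
* `full_relational` is provided for completeness and warns at fit time; its
  minimum-norm fit at ~240 training sentences has little power by design.
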