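# sentencode

Voxel-wise encoding models of sentence-level semantic structure.

## What this package is for

How does the brain represent *who did what to whom*? The sentences "the
surfer kicks the musician" and "the musician kicks the surfer" contain the
same words, yet mean different things because each noun is bound to a
different thematic role. `sentencode` is an analysis toolkit for fMRI studies
that probe this relational structure with **voxel-wise encoding models**: it
builds constrained noun–verb–noun stimulus designs, featurizes each sentence
into binary predictors at several levels of relational specificity,
predicts single-trial beta maps per voxel by cross-validated linear
regression, scores out-of-sample generalization, and performs group-level
cluster inference and ROI-level model comparison. A first-class
synthetic-data generator plants known signal in a voxel grid, so every stage
of the pipeline is testable against ground truth.

It is aimed at cognitive neuroscientists running sentence production /
comprehension experiments with single-trial beta images (one 3D volume per
sentence) and trial event tables, and at methodologists who want a fully
reproducible, seeded reference implementation of this class of analysis.

## The statistic at the core

For each participant, voxel and encoding model, a linear model with
intercept is trained on five of six runs (minimum-norm least squares when
rank-deficient) and used to predict the held-out run. With predictions
$\hat y$ and observations $y$ for the $n$ held-out sentences, the package
forms the matrix $D_{ij} = (\hat y_i - y_j)^2$, z-scores all $n^2$ entries
jointly, and computes

    run score = mean(on-diagonal) − mean(off-diagonal)

— correct sentence pairings versus mismatched pairings. The score is
averaged over folds and sign-flipped so informative voxels are positive.
Group inference shuffles the sentence→feature mapping within runs (100
permutations/participant), bootstraps 10,000 group-average null maps,
thresholds at voxelwise P < 0.005, and tests cluster sizes against the
bootstrap max-cluster-size null with Benjamini–Hochberg FDR at q < 0.05.
ROI analysis selects voxels per participant with a leave-one-participant-out
group t threshold (t > 2.4, fallback t > 1.68) and compares models with
linear mixed-effects likelihood-ratio tests and emmeans pairwise contrasts.

## Worked example

```r
library(sentencode)

## 1. a balanced design: 288 sentences of interest over six runs
des <- build_design(seed = 1)
des
#> Stimulus design: 360 trials in 6 runs
#>    trial_type
#> run filler production question
#>   1     12         42        6
#>   2     12         42        6
#>   3     12         42        6
#>   4     12         42        6
#>   5     12         42        6
#>   6     12         42        6

design_summary(default_lexicon())$length_stats
#>             class n mean_length sd_length
#> 1      noun music 8       7.500  1.118034
#> 2      noun sport 8       7.500  1.732051
#> 3    verb contact 8       7.875  1.053269
#> 4 verb perception 8       8.000  1.581139

## 2. featurization: deep roles, blind to voice and word order
x <- featurize(sentence_from_gloss("surfer", "kick", "musician"), "broad_roles")
x[x > 0]
#> M-as-patient   A-as-agent
#>            1            1

## 3. simulate 8 participants with a planted narrow-roles blob at SNR 2
grid  <- voxel_grid(c(12, 12, 12))              # 2.5 mm voxels
truth <- plant_blobs(grid, n_blobs = 1, radius = 3,
                     models = "narrow_roles", signal_amplitude = 2, seed = 1)
ds <- generate_dataset(des, truth, n_participants = 8, seed = 1)

## 4. per-participant cross-validated generalization maps
m <- vw_encode(ds, 1, "narrow_roles", fwhm_mm = 8)
m
#> Generalization map: sub-01 / narrow_roles (smoothed 8 mm FWHM)
#>   1728 voxels; mean 0.04519, sd 0.09183, max 0.5413

## 5. group cluster inference against the permutation/bootstrap null
maps <- lapply(names(ds$participants), \(p) vw_encode(ds, p, "narrow_roles", fwhm_mm = 8))
cfg  <- analysis_config(n_perm_per_subject = 30, n_bootstrap = 500, seed = 1)
pm   <- permutation_maps(ds, "narrow_roles", cfg, fwhm_mm = 8)
group_cluster_test(maps, pm, cfg)
#> Cluster test: 801 suprathreshold voxels, 2 cluster(s), 1 FDR-significant
#>  cluster size peak_x peak_y peak_z peak_value p_uncorrected       q_fdr significant
#>        1  800      8      6      8 0.54140936   0.001996008 0.003992016        TRUE
#>        2    1      3     12     10 0.00658586   0.746506986 0.746506986       FALSE
```

The planted blob (center near voxel 8,7,8) is recovered as the single
FDR-significant cluster; the size-1 cluster is a false positive correctly
killed by the cluster-level test. `roi_model_performance()` +
`compare_models()` then quantify which regions prefer which encoding model;
`run_pipeline(pipeline_config(...), out_dir)` orchestrates all stages with a
hashed manifest, and `inst/cli/sentencode.R` wraps design building/auditing
and pipeline runs for shell use.

## Package layout

- `R/lexicon.R`, `R/design.R` — lexicon, pool enumeration, balanced
  selection, voice assignment, run scheduling, audits.
- `R/featurization.R` — the seven encoding models.
- `R/synthetic_data.R` — voxel grids, planted ground truth, beta-map
  simulation, NIfTI/TSV serialization.
- `R/encoding_core.R` — per-voxel fitting, the generalization statistic,
  cross-validated maps, mask-aware smoothing.
- `R/group_inference.R` — permutation maps, bootstrap null, cluster tests.
- `R/roi_analysis.R` — LOPO voxel selection, ROI performance, mixed-model
  comparison.
- `R/pipeline.R` — end-to-end orchestration with seeds and manifest.

See the vignette (`vignettes/encoding-models.Rmd`) for the model, its
assumptions, and every numerical choice.
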