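# natisc

Leave-one-out inter-subject correlation (ISC) analysis for naturalistic
fMRI, with functionally localized networks, phase-randomization surrogate
inference, and mixed-effects network × condition contrasts.

## What problem this solves

Task-free, naturalistic paradigms (stories, films, conversations) have no
event model to regress against. The ISC approach instead uses the *other
participants* as the model: a region that tracks the stimulus produces a
time course correlated with the average time course of the remaining
participants. Combined with subject-specific functional localizers (e.g.,
sentences > nonwords for the language network; false belief > false
photograph for the theory-of-mind network), ISC profiles across conditions
that cross linguistic and mental-state content can test whether two
cognitive systems dissociate in rich naturalistic settings.

`natisc` is for researchers who want that analysis chain as tested,
reusable R functions:

* **Synthetic data** (`sim_config`, `simulate_naturalistic_run`,
  `simulate_localizer_run`): multi-subject BOLD with a band-limited shared
  signal per condition, network-specific coupling, subject-global and voxel
  noise, and known nuisance contamination — so the whole pipeline is
  testable with no data download.
* **Temporal preprocessing** (`build_nuisance`, `regress_nuisance`,
  `bandpass`, `clean_run`): motion parameters + derivatives, 5 temporal
  PCs and the mean of each noise compartment (WM, CSF), spike regressors
  for outlier frames (|Δ global| > 5 SD or framewise displacement
  > 0.9 mm), then zero-phase 0.008–0.09 Hz band-pass.
* **Localizer GLM and fROIs** (`build_design_matrix`, `fit_glm_contrast`,
  `define_froi`, `qc_subject`, `exclude_overlap`): canonical double-gamma
  HRF, boxcar blocks with temporal derivatives, top-10% of parcel voxels by
  contrast, 100-suprathreshold-voxel QC rule, cross-network overlap
  removal.
* **ISC core** (`extract_condition_timecourse`, `loo_isc`, `fisher_z`):
  fROI-mean time courses trimmed 6 s after stimulus onset, z-scored, each
  subject correlated with the average of the others, Fisher-transformed.
* **Surrogate inference** (`phase_randomize`, `subject_null`,
  `combine_null`, `isc_pvalue`, `fdr_bh`, `group_isc_test`): 1,000
  phase-randomized surrogates per subject, Gaussian fits combined
  analytically across subjects, one-tailed p values, BH-FDR.
* **Mixed-effects contrasts** (`fit_interaction`,
  `fit_condition_contrast`, `test_against_baseline`): maximal random
  effects (by-participant intercepts and slopes, crossed fROI and condition
  intercepts) with a principled simplification ladder and Satterthwaite
  degrees of freedom, via lme4/lmerTest.

## The statistics in brief

For subject *i* with z-scored regional series *x_i*, the leave-one-out ISC
is

    r_i = cor( x_i , mean_{j != i} x_j ),   z_i = atanh(r_i)

Under the generative model *x_i = a·s(t) + noise_i* with noise SD σ_n, the
large-T expectation is

    E[r] = a²σ_s² / sqrt( (a²σ_s² + σ_n²) · (a²σ_s² + σ_n²/(N−1)) )

(`expected_isc`; at a = σ_s = σ_n = 1, N = 30 it equals 0.695). Group
significance compares mean(z_i) with a null built from phase-randomized
surrogates — same amplitude spectrum, random phases — fitted per subject
with a Gaussian and combined as μ = mean(μ_i), σ = sqrt(Σσ_i²)/N. Critical
comparisons model all z values with linear mixed-effects regressions; the
network × condition-type interaction is the headline test.

## Worked example

Simulate a 20-subject study with four conditions and run the pipeline:

```r
library(natisc)
cfg <- sim_config(n_subjects = 20, seed = 1)
res <- run_isc_pipeline(cfg,
  conditions = c("story", "expository_text", "animated_film", "rest"),
  marginalize_voxels = TRUE)
aggregate(z ~ network + condition, res$table, function(x) round(mean(x), 3))
#>    network       condition     z
#> 1 language   animated_film 0.112
#> 2      tom   animated_film 0.375
#> 3 language expository_text 0.485
#> 4      tom expository_text 0.107
#> 5 language            rest 0.089
#> 6      tom            rest 0.084
#> 7 language           story 0.457
#> 8      tom           story 0.392
```

The planted dissociation is visible in the mean Fisher-z ISCs: the language
network tracks the linguistic conditions (story 0.457, expository text
0.485) far more than the silent film (0.112); the ToM network tracks the
mental-state conditions (story 0.392, film 0.375) but not the expository
text (0.107); rest is near zero in both.

The critical interaction (positive = language prefers linguistic conditions
more than ToM does):

```r
tab <- add_condition_flags(res$table)
fit_interaction(tab, c("language", "tom"),
                c("linguistic", "non-linguistic"), type_col = "linguistic")
#>                                             term  beta     se    t  df        p
#> 1 language vs tom x linguistic vs non-linguistic 0.485 0.0234 20.7 121 1.47e-41
#>   converged                                                re_structure
#>        TRUE (1 + net * ct | participant) + (1 | froi) + (1 | condition)
```

Surrogate-null inference at the network level
(`isc_group_inference(res, by = "network", n_sim = 1000, seed = 1)`) gives
group mean z, null parameters, and FDR-corrected p values per network and
condition. A caution that the package itself quantifies: the analytic
combination of per-subject nulls assumes independent leave-one-out ISCs,
which understates the null variance of the group mean by about a factor of
two — near-threshold rejections (such as rest conditions with mean z below
0.1 in the example above) should be read in that light. See the vignette
(`vignettes/naturalistic-isc.Rmd`) for the audit and for every modeling
choice, default, and limitation.

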