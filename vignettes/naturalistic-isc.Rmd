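---
title: "Inter-subject correlation analysis of naturalistic fMRI: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inter-subject correlation analysis of naturalistic fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis problem

When participants process the same rich naturalistic stimulus — a story, a
film, a conversation — brain regions that track features of that stimulus
produce time courses that are similar *across* participants, because the
stimulus drives them in lockstep. The inter-subject correlation (ISC)
approach quantifies this: each participant's regional BOLD time course is
correlated with the average time course of the remaining participants
(the leave-one-out variant). Combined with subject-specific functional
localization of networks of interest (e.g., the left-lateralized language
network and the bilateral theory-of-mind network), ISC profiles across
conditions that vary linguistic and mental-state content can reveal whether
two cognitive systems dissociate during naturalistic cognition.

`natisc` implements this analysis chain end to end — temporal preprocessing,
localizer GLMs and fROI definition, leave-one-out ISC, phase-randomization
surrogate inference, and linear mixed-effects contrasts — together with a
synthetic multi-subject BOLD generator with known planted structure, so that
every stage is testable without access to any imaging data.

## The generative model

For condition $c$ a single band-limited shared signal $s(t)$ (unit variance,
all spectral power in the 0.008–0.09 Hz passband) is common to all subjects.
Voxel $v$ of subject $i$ follows

$$ y_{iv}(t) = a(n(v), c)\,\sigma_s\, s(t) + g_i(t) + \varepsilon_{iv}(t)
   + \text{nuisance}_i(t), $$

where $a(n, c) \ge 0$ is the coupling of network $n$ to condition $c$,
$g_i(t)$ is subject-global noise — shared across all of a subject's
gray-matter voxels but independent across subjects — and
$\varepsilon_{iv}$ is iid voxel noise. The subject-global term is a
deliberate trap: it induces strong within-subject correlations between
regions that must *not* inflate ISC, because it carries no stimulus
information. Rest has $a = 0$ everywhere.

Nuisance contamination is injected with known ground truth so its removal is
verifiable: a linear drift per subject, a motion-locked artifact built as a
linear combination of the motion-parameter derivatives, and white-matter /
CSF compartment signals that also leak into gray matter. All three default
to half the shared signal's SD.

### Key parameters and defaults

| Parameter | Default | Meaning |
|---|---|---|
| `n_subjects` | 30 | subjects per condition (typical naturalistic cohorts run ~28–32 per condition) |
| `n_timepoints`, `tr` | 160, 2 s | ~5-minute runs at TR = 2 s |
| `passband` | 0.008–0.09 Hz | band of the shared signal and of the band-pass filter |
| `sigma_shared`, `sigma_subject`, `sigma_voxel` | 1, 1, 1 | SDs of shared signal, subject-global noise, voxel noise (BOLD a.u.) |
| coupling (language) | 0.35 / 0.10 | linguistic / non-linguistic conditions |
| coupling (ToM) | 0.30 / 0.10 | mental / non-mental conditions |
| nuisance amplitudes | 0.5 | × `sigma_shared`, for drift, motion artifact, compartment leak |
| `grid` | 14 × 14 × 8 | desk-scale voxel lattice (260 WM, 130 CSF, rest GM) |
| parcels | 5 language + 6 ToM, 50 voxels each | mirrors the mask counts of the two networks |

The couplings place Fisher-z ISCs in the 0.05–0.45 range, matching the
magnitudes reported for these networks; with $V$ voxels per parcel the
region-mean noise SD is $\sqrt{\sigma_g^2 + \sigma_v^2 / V}$.

### Closed-form expectation

For a region with coupling $a$ and per-subject effective noise SD
$\sigma_n$, the large-$T$ expectation of the leave-one-out ISC is

$$ \mathbb{E}[r] \approx
   \frac{a^2\sigma_s^2}{\sqrt{(a^2\sigma_s^2 + \sigma_n^2)
   \left(a^2\sigma_s^2 + \sigma_n^2/(N-1)\right)}}, $$

implemented as `expected_isc()`. It is strictly increasing in $a$ and in
$N$; at $a = \sigma_s = \sigma_n = 1$, $N = 30$ it equals 0.695. The test
suite verifies it against direct Monte-Carlo simulation before using it as
an oracle, and checks that the empirical mean leave-one-out ISC converges to
it.

## Temporal preprocessing

Each run is denoised by regressing out, per voxel: the six motion parameters
and their first temporal derivatives; the top five temporal principal
components of the white-matter and of the CSF compartment (after per-voxel
mean removal only — no variance normalization — following standard
component-based noise correction), plus each compartment's mean series; and
one spike regressor per outlier frame. Outlier frames are those whose
scan-to-scan global-signal change exceeds 5 SD or whose framewise
displacement exceeds 0.9 mm. Framewise displacement is computed as the sum
of absolute differences of the three translations plus the three rotations
converted to arc length on a 50 mm sphere (a documented package constant;
several conventions coexist in the field). Flagged frames are
regressed out rather than deleted: deletion would desynchronize subjects,
and ISC requires a shared time axis.

Residuals are then band-pass filtered to 0.008–0.09 Hz. The filter
realization is a design choice (the upstream toolchain's default was not
specified): the package implements a zero-phase forward–backward 2nd-order
Butterworth with antisymmetric reflection padding, and an exact DFT-mask
alternative behind `method = "fft"`. Both meet the same contract — passband
attenuation ≤ 1 dB, stopband attenuation ≥ 20 dB, no phase shift — and the
choice is recorded in the run provenance. Inputs are demeaned first so a
constant series maps exactly to zero. Because the planted shared signal is
spectrally confined to the passband, filtering cannot remove it; the test
suite confirms that the critical interaction's sign and significance are
unchanged with and without the filter.

One ambiguity is resolved as follows: compartment *mean* series are included
as regressors in addition to the five PCs (as separate columns), since the
method description lists both.

## Localizer GLM and fROI definition

Localizer blocks are modeled as boxcars convolved with a canonical
double-gamma HRF (response gamma shape 6, undershoot shape 16, ratio 6,
unit-sum normalized kernel), plus first-order temporal derivatives,
an intercept, and discrete-cosine drift regressors equivalent to 200 s
high-pass filtering (the localizer stream's high-pass; naturalistic runs get
the 0.008–0.09 Hz band-pass instead). Contrast effects and t statistics are
ordinary least squares per voxel.

Subject-specific fROIs are the top 10% of gray-matter parcel voxels by
contrast effect. The voxel count is `ceiling(fraction * parcel size)` with a
minimum of 1 — the ceiling guarantees a non-empty fROI in every subject,
which is the point of the top-n% rule — and boundary ties break by ascending
voxel index for cross-platform determinism. Selection is invariant to any
strictly increasing transform of the contrast values.

Subjects whose contrast map has fewer than 100 suprathreshold voxels at
uncorrected p < 0.001 across a network's masks are excluded. The
suprathreshold count uses the positive tail only (a package decision:
a positive contrast is what defines the network),
with the p threshold converted to a t threshold via the design's residual
degrees of freedom. Voxels claimed by fROIs of two or more networks within a
subject are removed from all of them, with a per-pair overlap report.

Multi-run localizers are combined by averaging contrast effects across runs
before fROI definition (fixed-effects combination; t maps combine by the
Stouffer rule).

## ISC computation

Regional time courses are extracted from 6 s after stimulus onset (3 frames
at TR = 2 s), to exclude the initial hemodynamic rise, averaged across the
fROI's voxels, and z-scored. The synthetic runs are stimulus-locked
throughout, so the default window is the whole run; for designs with
trailing fixation the `window` argument excludes it (trailing fixation is
not stimulus-locked; the hemodynamic-rise trim is applied at onset only).
Each subject's ISC is the Pearson correlation with the average of the
*other* subjects' z-scored series, averaged without re-standardizing
(Pearson correlation is unaffected by that choice). ISCs are Fisher-transformed (`atanh`) before any statistics, with
|r| clipped at 1 − 1e-7 so boundary values stay finite. Network-level
summaries average within subject across the network's fROIs.

## Surrogate-null inference

Significance of the group-averaged ISC is assessed against an empirical null
built from 1,000 phase-randomized surrogates per subject: each surrogate
preserves the amplitude spectrum (hence mean and autocorrelation) of the
subject's series while destroying stimulus alignment. Only the left-out
subject's series is randomized; the leave-one-out average stays veridical —
this nulls one subject's stimulus locking while preserving the reference,
which is what a per-participant null distribution should mean for a
leave-one-out statistic. Each subject's null is fitted
with a Gaussian by moment matching on the Fisher-z scale, the parameters are
combined analytically across subjects
($\mu = \bar{\mu}_i$, $\sigma = \sqrt{\sum_i \sigma_i^2}/N$), and the
observed group mean is converted to a one-tailed upper p value. Families of
tests are corrected with Benjamini–Hochberg FDR. Surrogate seeds derive
deterministically from a master seed and the (subject, region, condition)
labels.

### A documented limitation: the independence assumption

The analytic combination assumes the per-subject ISCs are independent under
the null. They are not: leave-one-out ISCs share data (subject $j$ appears
in subject $i$'s reference), giving pairwise correlation $\approx 1/(N-1)$
and hence a true null variance of the group mean about *twice* the combined
value, for any $N$. The package implements the combination as specified and
*audits* it: the acceptance suite and `scripts/acceptance.R` measure the
empirical rejection rate on zero-coupling simulations at nominal
$\alpha = 0.05$ and report it against the 95% binomial band. The audit is
the result; users drawing near-threshold conclusions from this test should
prefer the mixed-model baseline tests or treat the surrogate p values as
anti-conservative.

## Mixed-effects contrasts

The long ISC table (one Fisher-z value per participant × fROI × condition)
is modeled with `lme4`/`lmerTest` — the model construction, simplification
policy, and reporting schema are owned by the package; the solver is the
established library, as is conventional. Factors of interest are coded
±1/2 (sum-to-zero and symmetric in level order), so a main-effect beta is a
mean difference and the interaction beta a difference of differences, with
the first-listed level positive — the sign convention stated in each
result's `term`.

The maximal random-effects structure is fitted first: by-participant random
intercepts and slopes for the effects of interest, plus crossed random
intercepts for fROI and condition. On non-convergence the structure is
simplified stepwise — random slopes first (highest-order term first), then
the condition intercept, then the fROI intercept, finally a fixed-effects
fit — and the structure actually fitted is reported (`re_structure`).
Singular fits are retained (variance components on the boundary are
legitimate); only genuine optimizer failure triggers simplification.
Satterthwaite degrees of freedom are reported throughout; network and
condition-type contrasts are two-tailed, baseline (intercept > 0) tests
one-tailed to match the directional surrogate test, with FDR across each
family of cells. A constant response yields a flagged degenerate result
(beta exact, no test) rather than an error.

## Numerical and performance choices

* **Shared signal construction**: white Gaussian series, DFT bins outside
  the passband (including DC) zeroed, standardized; power is in-band by
  construction, so the signal is invariant under the pipeline's filter.
* **Phase randomization**: DC (and the Nyquist bin, for even length) kept;
  all other bins get uniform phases with Hermitian symmetry, so surrogates
  are exactly real with bin-wise identical amplitude spectra.
* **Region-level computation**: nuisance regression and filtering are
  linear and share one within-subject design across voxels, so they commute
  exactly with voxel averaging; the pipeline therefore preprocesses
  region-mean series by default (`level = "roi"`), with a voxelwise path
  available. Likewise `marginalize_voxels = TRUE` draws each parcel's
  voxel-noise *mean* (SD $\sigma_v/\sqrt{V}$) instead of $V$ voxel series —
  distributionally identical for the region-level pipeline — which is what
  makes replicate studies cheap.
* **Problem sizes in the test suite** (the package's own scaling choices):
  estimator consistency uses $N = 30$, $T = 2000$; the end-to-end
  dissociation study uses $N = 20$ with 100 replicate studies; the
  calibration audit uses 10 zero-coupling studies of 10 subjects with
  20 regions × 2 conditions (400 tests) at 1,000 surrogates each; the
  resting-state check uses $N = 10$, matching the size of the original
  rest sample.

## What the generator does and does not emulate

It emulates: stimulus-locked band-limited shared signal with
network-by-condition coupling; subject-global and voxel noise; drift,
motion-locked, and compartment nuisance; localizer block designs with
planted voxel effects; parcels, tissue masks, motion tables, and NIfTI/TSV
round-tripping at desk scale.

It does not emulate: scanner physics, spatial misalignment or registration
error, hemodynamic nonlinearity, spatially structured noise, graded
condition content, or surface-based data. Passing tests therefore certify
the *statistical machinery* — estimator correctness, null validity,
contrast recovery — not robustness to spatial artifacts, which are removed
upstream of this pipeline in real studies.

## Known limitations

* The analytic null combination is anti-conservative for leave-one-out ISC
  (see the audit above).
* Fixed-effect betas from any particular real study are not
  reconstructable from simulation — they depend on the real data and on the
  fixed-effect coding used — so the package validates *recovery of planted
  structure*, not numeric coincidence with published coefficients.
* Surrogate inference assumes second-order stationarity of the regional
  series; strong unremoved drifts would violate it (the preprocessing is
  designed to remove them).
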