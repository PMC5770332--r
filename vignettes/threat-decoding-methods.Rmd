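---
title: "Methods: decoding stimulus-invariant threat representations from auditory fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decoding stimulus-invariant threat representations from auditory fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(threatmvpa)
```

# The scientific problem

During auditory fear conditioning, a sound (`CS+`) predicts an aversive
electric stimulation (US) while a physically matched sound (`CS-`) never
does; two further sounds (`NS1`, `NS2`) are presented in an explicitly
safe context.  The question this package's pipeline addresses is whether
auditory cortex multivoxel patterns carry a *threat prediction* over and
above stimulus identity — and whether that threat code is shared between
simple (frequency-modulated tone) and complex (ripple-like) sounds or
specific to each.  Three hypotheses structure the analysis:

1. no threat information beyond stimulus identity;
2. a threat pattern shared across sound complexities;
3. complexity-specific (orthogonal) threat patterns.

The package implements the full inference chain as tested, reusable
components: a synthetic-data generator that plants each regime in 4-D
BOLD data, single-trial response estimation, imbalance-aware decoding
with permutation chance correction, cross-classification,
searchlight mapping with group-level permutation inference, model-based
skin-conductance arousal estimation, and factorial mixed-effects
statistics.

# Experimental design model

`generate_design()` reproduces the factorial structure: 8 blocks of 2
miniblocks of 12 trials (192 trials), one stimulus pair per miniblock,
contexts alternating across blocks, complexities alternating within a
context, 4 s sounds, inter-trial intervals drawn from \{7, 9, 11\} s,
and exactly 50% of `CS+` trials reinforced (selected uniformly at
random).  Every stimulus occurs exactly 24 times.  Reinforced trials are
excluded from all response analyses, leaving the characteristic 12:24
class imbalance (`CS+` vs `CS-`) in the reinforced context and 24:24 in
the neutral context.

Two timing choices deserve note.  First, 24 trials at a mean spacing of
13 s give 312 s per block, while the published average block duration is
332 s; the 20 s difference is unexplained (plausibly instruction/context
screens), so the generator exposes `block_padding` (default 10 s lead-in
and lead-out, which happens to reproduce the 332 s average) and block
duration is *not* treated as a correctness target.  Second, the original
trial ordering was efficiency-optimized; we use plain randomization,
which affects estimator efficiency but no acceptance quantity.

# Synthetic BOLD data

`simulate_bold()` generates each voxel time course as

$$ y_v(t) = \sum_i a_{iv}\,(b \ast h)(t - o_i) + d_v(t) + \varepsilon_v(t) + \mu, $$

where $b$ is a 3.5 s boxcar, $h$ the canonical double-gamma HRF, $o_i$
trial onsets, $d_v$ a sinusoidal low-frequency drift with voxel-specific
phase (default period 300 s, i.e. below the high-pass edge), and
$\varepsilon_v$ Gaussian noise (optionally AR(1)).  The per-trial
amplitude map $a_{iv}$ carries unit-Euclidean-norm multivoxel patterns:
one identity pattern per stimulus over the whole grid, plus — on `CS+`
trials only — a threat pattern confined to a designated ROI, either
shared across complexities or complexity-specific with orthogonalized
patterns (`effect_spec_for_hypothesis()`).  The default grid is a 12^3
cube at 1.5 mm with three 64-voxel cuboid ROIs; geometry only matters
for the searchlight, so the grid is kept desk-scale.

`simulate_betas()` skips the forward model and draws beta series
directly as pattern + i.i.d. noise — the asymptotic GLM output — and is
used wherever decoding rather than estimation is under study.

**Effect-size policy.**  Pattern amplitudes are expressed in
voxel-noise-SD units along a unit-norm pattern.  The hypothesis regimes
default to a threat amplitude of 4, which is *deliberately strong*: real
corrected accuracies in this paradigm are a few percent, but validating
regime discrimination at such effect sizes would need hundreds of
simulated subjects per run.  A green regime-separation test therefore
establishes that the machinery discriminates the generative regimes, not
that real-data effects of realistic size would be detected at desk
scale.  These defaults were fixed before the acceptance tests were
frozen and are not tuned against them.

# Single-trial response estimation

`build_design_matrix()` implements the least-squares-all single-trial
model: one regressor per trial (3.5 s boxcar convolved with the
canonical HRF on a 0.1 s microtime grid, sampled at mid-volume scan
times), one pooled US regressor (0.5 s boxcars at the stimulus offset of
reinforced trials — the stimulation is a 500 ms pulse train
co-terminating with the sound), a discrete-cosine high-pass basis with
$K = \lfloor 2T/128 \rfloor$ components plus an explicit intercept, and
any user-supplied nuisance columns.  `estimate_betas()` fits all
regressors simultaneously by OLS per voxel and returns the trial
coefficients with reinforced trials flagged unusable.

Choices where the published description is silent: HRF parameters are
the standard double-gamma defaults (peak 6 s, undershoot 16 s, unit
dispersions, ratio 6, 32 s support); the high-pass is realized as DCT
columns inside the GLM so OLS stays exact; no prewhitening is applied
(the decoding consumes betas, not standard errors); onsets are built on
a 0.1 s microtime grid because inter-trial intervals of 7/9/11 s never
align with the 2.5 s TR.

# Decoding with permutation chance correction

Features are z-scored per voxel across the trials entering each analysis
(population-SD convention; constant voxels are dropped with a warning).
Cross-validation is the published interleaved three-fold scheme: fold
index is sequence position mod 3, so every third trial is tested and
each fold trains on 24 and tests on 12 of the 36 usable trials.

The classifier is a linear C-SVC with C = 1.  No SVM library exists in
the target environment, so the dual problem is solved by an SMO solver
with maximal-violating-pair working-set selection (the LibSVM
algorithm) in compiled code; it reproduces sklearn/LibSVM coefficients
to ~1e-4 on frozen reference problems.  Decision values of exactly zero
predict the majority training class.

Because 12:24 class imbalance makes the binomial 50% baseline invalid,
chance is estimated empirically: the full cross-validation is re-run
under 1000 count-preserving label permutations and the mean permuted
accuracy is subtracted from the true-label accuracy ("corrected
accuracy").  The permutation mean (not median) is used; this is
configurable in principle but the mean matches the published subtraction.

**Chance level and dimensionality.**  The empirical chance of this
procedure depends almost entirely on feature-space dimensionality: with
more voxels than training samples the true-label and permuted-label
classifiers alike lean increasingly toward the majority class, so chance
climbs from the mid-50s toward the 24/36 ≈ 67% majority rate as the
voxel count grows into the hundreds (the soft-margin cost C has no
measurable influence, and an independent LibSVM implementation agrees
with this solver to within 0.1%).  On the 100-voxel signal-free
simulation that `scripts/acceptance.R` runs, the measured chance is
≈56.4%; the published 59–61% band corresponds to ROI sizes of several
hundred voxels at 1.5 mm resolution.  The acceptance criterion that pins
the published band to a 100-voxel simulation is therefore internally
contradictory; it is implemented exactly as stated and left failing,
with this analysis as the explanation.  Corrected accuracies are
unaffected — the same chance is subtracted whatever its level.

The neutral conditions have 24+24 usable trials; to match the bias and
power of the 12:24 reinforced analysis, one neutral class is randomly
halved before decoding.  The halved class alternates deterministically
across the 100 repetitions, and *both* raw and chance accuracies are
averaged over repetitions (the published text is ambiguous; symmetric
averaging avoids subsampling bias on either side).

# Cross-classification

`cross_classify()` trains one SVM on all 36 usable reinforced-context
trials of one complexity and tests on the other complexity (both
directions), with chance from permutations of the *training* labels.
The motor-matched control transfers key-press labels across neutral
sounds; its balanced 24:24 training set is subsampled to 12:24
(alternating halved class) to mirror the CS imbalance.

**A caveat discovered during validation:** corrected cross-accuracy is
*not* centred at zero under the orthogonal regime.  With a strong
non-transferring training signal plus class imbalance, the true-label
classifier pushes all transfer trials (which lack the training signal
direction) deep onto the majority side — approaching the 24/36 majority
rate — while permuted-label classifiers are less decisive, so
raw − chance is positive (a few percentage points at the default
amplitude) without any shared pattern.  Regime discrimination therefore
uses the *transfer
ratio* (corrected cross-accuracy divided by corrected within-condition
accuracy): ≈1 when the threat pattern is shared, ≲0.2 when orthogonal.
The zero-centring of corrected accuracy holds for true null data and is
tested there.

# Searchlight mapping and group inference

`run_searchlight()` repeats the entire corrected-accuracy procedure on
the voxels of a 10 mm sphere (all mask voxels within centre-to-centre
radius) around every mask voxel, writing per-condition corrected
accuracies and the context contrast (mean corrected CS − mean corrected
NS) into 3-D maps.  Desk-scale defaults reduce permutations (100) and
neutral subsampling repetitions (10) per sphere; a `reuse_chance` flag
reuses one chance estimate per condition across centres, since chance
depends on label counts rather than location.

Group inference replaces parametric random-field correction with
sign-flip max-statistic permutation: voxel-wise one-sample t statistics
across subjects, a null distribution of the mask-wide maximum under
random sign flips of whole subject maps (exact under symmetric
exchangeability), and 6-connected suprathreshold clusters reported with
peak location and volume.  The published cluster statistics are
real-data quantities and are not reproduction targets.

# Skin conductance arousal

`simulate_scr()` places a gamma-shaped canonical response kernel (peak
normalized to 1 at 3.5 s; the downstream statistics depend only on
relative amplitudes, so the exact parametric family is configurable) at
a latency within 0–3.5 s after each onset, scaled by a per-trial
amplitude drawn around the condition mean and truncated at zero, plus an
unconditioned-response burst at US onset on reinforced trials and white
measurement noise.  The default sampling rate is 10 Hz (not the recorded
1000 Hz) to keep tests fast; the estimator is rate-agnostic.

`estimate_trial_amplitudes()` approximates the published model-based
(DCM) estimation with a grid-NNLS scheme: each trial's onset latency is
optimized on a 0.25 s grid by coordinate-descent sweeps, and all
amplitudes are then fit jointly by non-negative least squares
(Lawson–Hanson), deconvolving overlapping responses at short intervals.
On reinforced trials the anticipatory kernel (latency up to 3.5 s) and
the US kernel (at 4 s) are nearly collinear, so the trial's latency is
selected by refitting the pair jointly at each candidate; US amplitudes
are nuisance quantities reported separately.  Amplitudes are
non-negative by construction (a sudomotor burst amplitude is physically
non-negative; the published posterior means could in principle be
negative — this choice is documented and intentional).  Per subject,
amplitudes are z-normalized across all non-US trials, averaged within
the 8 design cells, and summarized as the fear learning index
mean(`CS+`) − mean(`CS-`) per complexity.

# Group statistics

`mixed_anova()` fits the factorial random-intercept model used for all
condition-level and trial-level tests.  For balanced
one-observation-per-cell tables it is computed in closed form
(pooled-error repeated-measures ANOVA, to which the random-intercept
mixed model reduces there); for trial-level tables it is fit by maximum
likelihood (lme4) with Wald F per single-df effect.  Denominator degrees
of freedom follow the containment rule
$\mathrm{df} = N - n_\mathrm{subjects} - p_\mathrm{within}$, which
reproduces the published denominators exactly: 119 (2×2×2, 18 subjects),
51 (2×2, 18 subjects) and 2665 (16 subjects × 168 usable trials — 192
minus 24 US trials — in a 2×2×2 model).  Post-hoc contrasts use
Wilcoxon signed-rank tests (exact for n ≤ 25 without ties, normal
approximation with tie correction otherwise), uncorrected as published.
`volume_learning_correlation()` residualizes the Heschl's gyrus voxel
count on total gray matter volume and correlates the residuals with the
learning index per complexity.

# What the generator does and does not emulate

Emulated: the factorial miniblock design and trial counts; HRF-convolved
responses with planted multivoxel structure, slow drift, and white or
AR(1) noise; threat-pattern regimes corresponding to the three
hypotheses; SCRF-convolved arousal bursts with CS+ > CS- amplitudes and
US responses.  Not emulated: spatial autocorrelation of BOLD noise,
anatomical variability and native-to-group warping, motion and
physiological artefacts, efficiency-optimized trial ordering, realistic
(weak) effect sizes, and SCR drift/artefacts.  Green tests therefore
validate the statistical machinery and its calibration (chance
centring, FWE control, df arithmetic, recovery of planted truth), not
field realism.

# Numerical choices and degenerate inputs

RNG: every stochastic function takes a seed and restores the caller's
RNG state; sub-seeds for permutations, subsampling and per-centre
searchlight decoding are derived deterministically from the master seed.
SMO tolerance 1e-4 on the KKT violation; z-scoring uses population SD
and refuses all-constant inputs; designs with exactly collinear trial
regressors, single-class training folds, unbalanced subject×cell
tables, zero-variance amplitude vectors, and traces shorter than the
design all fail with explicit messages rather than propagating NaN.
Latency ties in the SCR grid search resolve to the earliest latency.

# Known limitations

The searchlight recomputes chance per sphere by default (the published
implementation's behaviour is unstated; both are available).  The
Wald-F/containment combination for unbalanced trial-level tables is an
approximation to the published nlme fits, exact in the balanced case.
The NIfTI reader/writer is deliberately minimal (single-file NIfTI-1,
little-endian, no orientation handling) because no NIfTI package exists
in the target environment.  Whether reinforced-trial positions were
constrained in the original experiment is unknown; the generator leaves
them unconstrained.
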