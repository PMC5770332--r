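# threatmvpa

Multivariate decoding of threat representations in human auditory cortex
fMRI, with a fully synthetic validation world.

## The problem

In auditory fear conditioning, one sound (`CS+`) predicts an aversive
electric stimulation while a matched sound (`CS-`) never does; two more
sounds (`NS1`, `NS2`) occur in an explicitly safe context. The scientific
question is whether auditory cortex multivoxel patterns encode a *threat
prediction* beyond stimulus identity, and whether that code is shared
between simple (frequency-modulated) and complex (ripple-like) sounds.
The package implements the complete inference chain for this question —
usable both on real data (NIfTI + BIDS-style events TSV) and on its own
synthetic generator, which plants each competing hypothesis as a
generative regime:

1. **Design generator** — 8 blocks × 2 miniblocks × 12 trials, one
   stimulus pair per miniblock, ITIs from {7, 9, 11} s, 24 trials per
   stimulus, 50% of `CS+` trials reinforced (and thereafter excluded).
2. **Synthetic 4-D BOLD** — HRF-convolved trial responses carrying
   unit-norm multivoxel patterns (stimulus identity everywhere; a threat
   pattern — shared or complexity-specific — in a designated ROI), slow
   drift, Gaussian/AR(1) noise.
3. **Single-trial GLM (least-squares-all)** — one regressor per trial
   (3.5 s boxcar × canonical double-gamma HRF), pooled US regressor,
   DCT high-pass at 128 s, OLS per voxel.
4. **Decoding** — per-voxel z-scoring, interleaved 3-fold CV, linear
   C-SVC (C = 1; an SMO solver written for this package and validated
   against LibSVM), empirical chance from 1000 count-preserving label
   permutations. Corrected accuracy = raw − chance, which is what the
   12:24 class imbalance of the reinforced context requires. Neutral
   conditions are subsampled (24+24 → 12:24, alternating halved class,
   100 repetitions) to match bias and power.
5. **Cross-classification** — train on one complexity's `CS+`/`CS-`
   distinction, test on the other, with a key-press-matched neutral
   control.
6. **Searchlight** — the full corrected-accuracy procedure in a 10 mm
   sphere at every mask voxel; group inference by sign-flip
   max-statistic permutation with 6-connected cluster reporting.
7. **Skin conductance** — per-trial anticipatory amplitudes by grid-NNLS
   deconvolution with a canonical response kernel (latency window
   0–3.5 s), within-subject z-normalization, fear learning index
   mean(`CS+`) − mean(`CS-`) per complexity.
8. **Group statistics** — factorial random-intercept models with
   containment degrees of freedom (reproducing the published
   denominators 119, 51 and 2665 exactly), Wilcoxon post-hocs, and the
   anatomy-corrected volume/learning correlation.

See `vignettes/threat-decoding-methods.Rmd` for the model details,
parameter choices, and known limitations.

## Worked example

```r
library(threatmvpa)
design <- generate_design(design_params(), seed = 7)
design
#> <experiment_design> 192 trials, 8 blocks, run length 2643.0 s
#>   reinforced trials: 24/48 CS+

spec  <- effect_spec_for_hypothesis(2)       # shared threat pattern in ROI 1
betas <- simulate_betas(design, spec, seed = 7)
roi   <- which(as.vector(spec$roi_labels) == 1)

roi_decoding_table(betas, voxels = roi, n_perm = 200, n_rep = 20, seed = 7)
#>      context complexity raw_accuracy chance_accuracy corrected_accuracy
#> 1 reinforced     simple        0.889           0.557             0.3314
#> 2    neutral     simple        0.475           0.549            -0.0744
#> 3 reinforced    complex        0.778           0.545             0.2326
#> 4    neutral    complex        0.506           0.551            -0.0454

cross_decoding_table(betas, voxels = roi, n_perm = 200, n_rep = 20, seed = 7)
#>   stimulus_set       direction raw_accuracy chance_accuracy corrected_accuracy
#> 1           CS simple->complex        0.889           0.546             0.3428
#> 2           NS simple->complex        0.457           0.499            -0.0421
#> 3           CS complex->simple        0.972           0.544             0.4279
#> 4           NS complex->simple        0.452           0.497            -0.0452
```

Reading the numbers: chance sits near 0.55 (not 0.50) because of the
12:24 imbalance — that is exactly why permutation correction is needed.
Under the shared-threat regime, `CS+`/`CS-` decodes far above chance in
the reinforced context, the neutral conditions carry no threat signal,
and the classifier transfers across complexities (corrected
cross-accuracy ≈ within-condition accuracy), the signature that
distinguishes hypothesis 2 from hypothesis 3.

```r
trace   <- simulate_scr(design, seed = 7)
arousal <- normalize_and_aggregate(estimate_trial_amplitudes(trace, design))
arousal
#> <scr_amplitudes> 192 trials (168 usable) [normalized]
#>   learning index: simple +2.031, complex +1.698
```

The positive learning indices recover the planted `CS+` > `CS-`
anticipatory arousal (generator default: means 1.0 vs 0.5 µS, z-scored
within subject).

A command-line front end (`inst/cli/threatmvpa`) exposes
`simulate | glm | scr | decode | group`; NIfTI images are read and
written natively (`read_nifti()`, `write_nifti()`).

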