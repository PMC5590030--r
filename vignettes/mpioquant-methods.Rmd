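---
title: "Quantifying targeted iron-oxide contrast binding after experimental stroke"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying targeted iron-oxide contrast binding after experimental stroke}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpioquant)
```

## The measurement problem

Antibody-functionalized micron-sized particles of iron oxide (MPIO) bind to
adhesion molecules such as ICAM-1 on inflamed brain endothelium. Bound
particles shorten T2\*, so they appear as focal signal loss (hypointensity)
on gradient-echo T2\*-weighted images. After experimental stroke (transient
middle cerebral artery occlusion in the mouse), the question is how much
agent accumulated in three regions: the lesion core, the perilesional
borderzone, and homologous contralesional tissue.

Because the brain moves slightly between scans, pre- and post-contrast
images cannot be compared voxel by voxel. All quantification in this package
therefore goes through region-of-interest statistics:

* **Absolute signal reduction**: `SI_pre − SI_post`, the difference of the
  ROI means of the pre- and post-contrast signal intensity.
* **Contrast-enhanced (CE) voxel rule**: a voxel is CE when its signal is
  *strictly* below `mean_pre − 2·SD_pre`, where mean and SD are the
  pre-contrast statistics of the *same* ROI.
* **CE volume percentage**:
  `100 · (n_CE(post) − n_CE(pre)) / n_ROI`. Counting CE voxels on the pre
  image with the same threshold gives each ROI its own noise/confound
  baseline, which makes the null unbiased around zero. Negative values are
  reported, never clamped, so that the null calibration is testable.
* **Hemispheric lesion fraction**:
  `100 · V_lesion / V_ipsilesional-hemisphere`, a pure volume ratio that is
  invariant to voxel spacing.

## The analysis chain

1. **T2 relaxometry** (`fit_t2_map`). The multi-echo spin-echo signal is
   modeled as `S(TE) = S0 · exp(−TE/T2)` per voxel. Two fitters are
   provided: a weighted log-linear fit (weights `S²`, compensating the noise
   amplification of the log transform) and, as the default, nonlinear least
   squares initialized from the log-linear result. NLLS is the default
   because magnitude (Rician) noise biases log-domain fits at low SNR; the
   implementation only accepts iteration steps that reduce the residual sum
   of squares, so the NLLS fit provably never fits worse than its
   initialization. The source study does not state its fitting algorithm;
   mono-exponential magnitude fitting is the field's default and is recorded
   here as an assumption.
2. **Lesion identification** (`segment_lesion_by_threshold`,
   `classify_lesion`). Ischemic tissue shows prolonged T2 at subacute
   stages. The threshold rule takes voxels of the ipsilesional hemisphere
   with `T2 > mean + k·SD` of the contralesional hemisphere; only
   "relatively high T2" is specified in the underlying protocol, so `k` is
   an explicit parameter (default 2) surfaced in every report. The
   supervised alternative is a seeded random-forest voxel classifier over T2
   and template-space location, mirroring a two-expert-consensus training
   protocol (`consensus_mask`, `train_lesion_classifier`).
3. **ROI construction** (`build_roi_set`). The borderzone is produced by a
   slice-by-slice twofold convolution of the binary core with a 3×3 all-ones
   kernel, binarizing after each pass — equivalently two successive
   8-connected in-plane dilations, i.e. an expansion ring of in-plane
   Chebyshev width 2 — minus the core and minus the ventricle and
   corpus-callosum masks. The contralesional ROI is the mirror image of the
   core across the midsagittal plane, clipped to the contralesional
   hemisphere.
4. **Quantification** (`quantify_rois`) applies the equations above per ROI,
   with baseline statistics computed per ROI (matching the per-ROI notation
   of the CE rule), at the nominal "30 min post-injection" time point when
   free circulating particles have largely cleared from the blood.
5. **Statistics** (`compare_cells`, `fdr_adjust`, `pearson_correlation`,
   `treatment_effect`, `required_sample_size`): per ROI×day cell contrasts
   between targeted and control agent with Benjamini–Hochberg adjustment, a
   Pearson correlation with Fisher-z interval, a one-way ANOVA on the
   relative day-1→day-3 change in hemispheric lesion fraction, and a
   noncentral-t sample-size routine.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| echo times | 12–96 ms, 8 echoes | ms | emulated multi-echo protocol (TR 2300 ms) |
| `gre_te` | 15 | ms | gradient-echo TE of the T2\*-weighted pair |
| `k` (lesion threshold) | 2 | ref. SD | "relatively high T2" made explicit |
| `n_sd` (CE rule) | 2 | ROI SD | the stated 2-SD hypointensity criterion |
| `ce_amplitude` | 0.4 | – | seeded voxels keep 40 % of their signal; strong focal T2\* loss |
| `noise_sigma` | 20 | a.u. | 2 % of `s0_background` = SNR 50, a typical high-field small-animal figure; the study reports no SNR, so this is a free simulation parameter swept in tests, not a claim about the study's data |
| `t2_background` / `t2_lesion` | 45 / 80 | ms | normal vs clearly prolonged tissue T2 at high field |
| grid / spacing | 64×64×16, 0.104×0.208×0.4 mm | – | acquisition-matched in-plane spacing and slice thickness at desk scale |
| classifier | 100 trees, depth ≤ 10 | – | unstated in the protocol; fixed in config |

## The synthetic world

`make_phantom` builds a uniform "brain" with a spherical unilateral lesion
of prolonged T2, mirror-symmetric ellipsoidal ventricles, a corpus-callosum
slab, and a hemispheric split; `simulate_contrast_pair` renders the
T2\*-weighted baseline `S0·exp(−TE*/T2)` and imposes MPIO binding as a
multiplicative signal drop on a seeded voxel subset of each target ROI
(count = round-half-away-from-zero of fraction × ROI size, sampled without
replacement). Rician noise — `sqrt((v+n₁)² + n₂²)` with Gaussian `n₁,n₂` —
is applied last; the noise model is a package choice, as magnitude MRI noise
is Rician and the study states none.

The chronic-stage confound is modeled by darkening a stated fraction of
lesion voxels in *both* the pre and the post image (phagocytosed blood
remains are hypointense before any contrast is given). Confound voxels are
excluded from the seeded CE truth. For the default amplitude and noise
level, the 2-SD rule's detection probability collapses across a transition
around a confound fraction of ≈ 0.2: below it the baseline subtraction
still cancels the confound (recovery stays ≈ 10 %), above it the inflated
baseline SD drags the threshold below the seeded voxel intensity and
recovery falls to ≈ 0. Tests sample confound levels 0 / 0.2 / 0.4 across
this transition to verify that detection strictly degrades — the day-21
masking phenomenology.

What the generator does **not** emulate: pulse-sequence (Bloch) physics,
susceptibility blooming around iron, anatomical lesion shapes, partial
voluming, coil inhomogeneity, inter-scan motion, or registration error. A
green recovery test therefore establishes that the quantification chain is
correct *given* the stated signal model — not that the chain is robust to
every artifact of real acquisitions. Adequacy of the spherical lesion is
judged by pipeline recovery, not anatomical realism.

## Numerical and design choices

* **Sample SD** (n−1) throughout; the estimator is unstated in the source
  protocol and the difference is negligible at these ROI sizes, but pinning
  it makes bit-exact tests possible.
* **Strict inequality** in the CE rule, as printed; a degenerate baseline
  (SD = 0) keeps the rule well-defined (threshold = mean) and is flagged.
* **"Twofold convolution"** is read as two convolve-then-binarize passes
  (two dilations). The alternative reading — one convolution thresholded at
  2 — would not be an "expansion" of the core; an exhaustive
  Chebyshev-distance oracle pins the chosen semantics in the tests.
* **Borderzone excludes the core** (the published ROI figure shows the
  borderzone surrounding, not containing, the core), and never crosses
  slices (2D multi-slice acquisition).
* **Contralesional source**: whether the original contralesional ROI
  mirrored the core alone or core + borderzone is unstated; the config flag
  `contralesional_source` defaults to `"core"` (the homolog of the lesion
  proper), with `"core_borderzone"` available.
* **Mirroring replaces manual outlining** of contralesional tissue: the
  phantom is symmetric, so the mirror image is the exact homolog; real-data
  workflows can supply manual masks instead.
* **Template registration is the identity** on phantoms. The published
  classifier used non-rigid registration to a template — a published-tool
  step, not a contribution of the analysis — so the desk-scale classifier
  takes native-grid coordinates and accepts externally computed template
  coordinates for real data.
* **Connected components** use 26-connectivity in 3D for mask cleanup; the
  protocol is silent on post-processing.
* **FDR** is fixed to Benjamini–Hochberg step-up ("FDR-adjusted" is all the
  protocol states); the implementation is hand-written and tested against
  both a brute-force step-up oracle and `stats::p.adjust`.
* **Mixed model**: the factor structure (ROI × agent × day and their
  interactions, post hoc per-cell agent contrasts) is known, the
  random-effects structure is not. The `"mixed"` backend fits a per-subject
  random intercept with lme4 and Wald-z contrasts and is labeled a
  reconstruction; the `"welch"` backend is the assumption-light fallback
  used for calibration simulations. Singular/boundary fits are tolerated
  because desk-scale tables often carry negligible between-subject variance.
* **Sample size**: "20 % standard deviation" is interpreted as an SD on the
  same percent scale as the 40–45 % reduction, giving a standardized
  `d = reduction/SD`. With d = 2.0, α = 0.05 and power 0.8 the exact
  noncentral-t calculation gives n = 6 per group unadjusted (power at n = 5
  is 0.7905) and n = 7 with Bonferroni adjustment for three pairwise
  comparisons — consistent with the protocol's "five to seven".
* **Seeding**: one root seed drives derived per-subject and per-stage seeds
  (`seed + 104729·offset mod 2³¹−1`), so cohorts and reports are bit
  reproducible and the caller's RNG stream is never disturbed.
* **NIfTI-1 I/O** is implemented in-package (the R stack available to the
  pipeline has no NIfTI package): single-file `.nii`/`.nii.gz`, RAS+
  axis-aligned sform, common scalar dtypes. Round trips are cross-checked
  against Python's nibabel in the test suite.

## Known limitations

* Signal drops are imposed multiplicatively; there is no susceptibility
  physics, so particle load cannot be related to R2\* quantitatively.
* The threshold segmentation assumes a unimodal contralesional reference;
  bilateral pathology would break it.
* The in-package random forest is adequate for four features at desk scale
  but is not a general-purpose learner.
* Animal-level results of the original study depend on unavailable in vivo
  data; nothing here reproduces those numbers, and the validation layer is
  deliberately property-based (exact recovery, calibration, oracles)
  instead.
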