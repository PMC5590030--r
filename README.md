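# mpioquant

Quantitative MRI analysis of targeted iron-oxide contrast-agent binding
after experimental stroke — with a synthetic phantom generator so every
stage is verifiable against known ground truth.

## The problem

Micron-sized particles of iron oxide (MPIO) functionalized with antibodies
against adhesion molecules (e.g. ICAM-1) bind to inflamed brain endothelium
and leukocytes after stroke. Bound particles shorten T2\*, producing focal
hypointensities on gradient-echo T2\*-weighted images. Quantifying that
binding from a pre-/post-injection image pair — per lesion core,
perilesional borderzone, and contralesional homolog — is the job of this
package. It is aimed at small-animal imaging groups who need a tested,
reproducible reimplementation of this analysis, and at methodologists who
want to probe its failure modes (noise, the chronic-stage pre-contrast
hypointensity confound) on simulated data.

Because slight inter-scan brain motion rules out voxelwise subtraction, all
quantification is ROI-statistical:

* absolute signal reduction: SI<sub>pre-CA</sub> − SI<sub>post-CA</sub>
  (difference of ROI means);
* CE-voxel rule: a voxel is contrast-enhanced when
  SI < SI<sub>ROI,pre</sub> − 2·SD<sub>ROI,pre</sub> (strict);
* CE volume percentage:
  100 · (V<sub>CE,post</sub> − V<sub>CE,pre</sub>) / V<sub>ROI</sub>;
* hemispheric lesion fraction:
  100 · V<sub>lesion</sub> / V<sub>ipsilesional hemisphere</sub>.

Supporting stages: mono-exponential T2 mapping from a multi-echo spin-echo
series (log-linear and NLLS fitters), lesion segmentation on T2 maps
(reference-relative threshold or a seeded random-forest voxel classifier),
borderzone construction by slice-wise twofold 3×3 dilation with ventricle /
corpus-callosum exclusion, midline mirroring for the contralesional ROI,
and a statistics layer (Welch or lme4 mixed-model per-cell contrasts with
Benjamini–Hochberg FDR, Pearson correlation with Fisher CI, one-way ANOVA
treatment test, noncentral-t sample-size calculation).

## Worked example

Simulate one subject with 10 % of lesion voxels seeded with contrast
uptake (signal retained: 40 %) at SNR 50, then run the full analysis:

```r
library(mpioquant)

ph   <- make_phantom(phantom_spec())
cs   <- contrast_spec(ce_fraction_per_roi = c(lesion = 0.10),
                      noise_sigma = 20, seed = 42)
pair <- simulate_contrast_pair(ph$t2_map, ph$s0_map, ph$rois, cs)

se   <- simulate_multiecho(ph$t2_map, ph$s0_map, noise_sigma = 20, seed = 42)
fit  <- fit_t2_map(se, method = "nlls", signal_floor = 0)
core <- segment_lesion_by_threshold(fit$t2_map,
                                    ph$rois$masks$ipsi_hemisphere,
                                    ph$rois$masks$contra_hemisphere, k = 2)
rois <- build_roi_set(core,
                      hemispheres = list(ipsi = ph$rois$masks$ipsi_hemisphere,
                                         contra = ph$rois$masks$contra_hemisphere),
                      exclusions  = list(ventricles = ph$rois$masks$ventricles,
                                         corpus_callosum = ph$rois$masks$corpus_callosum),
                      spacing = ph$t2_map$spacing)
quantify_rois(pair$pre, pair$post, rois)[, 1:6]
#>              roi eq1_signal_reduction eq3_ce_volume_percent ce_count_pre
#> 1           core           45.7666120             9.6774194           36
#> 2     borderzone           -0.4880570            -0.5685856           37
#> 3 contralesional           -0.7855705            -0.3121748           22
#>   ce_count_post n_voxels
#> 1           129      961
#> 2            29     1407
#> 3            19      961
```

Reading this: the segmented core (961 voxels) shows a mean T2\*-weighted
signal drop of ≈ 46 a.u. and a net CE volume of 9.7 % — recovering the
seeded 10 % within noise (the pre-image count of 36 CE voxels is the
~2.3 % noise baseline that the rule subtracts). Borderzone and
contralesional values sit at 0 within noise, as nothing was seeded there.

```r
hemispheric_lesion_fraction(rois$masks$core,
                            ph$rois$masks$ipsi_hemisphere,
                            ph$t2_map$spacing)
#> [1] 2.93                          # percent of the ipsilesional hemisphere

required_sample_size(40, 20, alpha = 0.05, power = 0.8, n_pairwise = 3)$n
#> [1] 7                             # per group, Bonferroni over 3 comparisons
```

A whole cohort (groups × subjects, with control-agent groups seeded at
zero), including segmentation, quantification, per-cell contrasts and a
JSON run report:

```r
report <- run_pipeline(default_run_config(seed = 1), "out/")
```

A command-line front end covering simulate / t2map / segment / roi /
quantify / run lives in `inst/cli/mpioquant.R` (YAML configs, NIfTI-1
volumes, RFC-4180 CSV outputs).

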