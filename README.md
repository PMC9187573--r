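# perfmismatch

Multiparametric MRI analysis of acute ischemic stroke in R: ADC-based
infarct-core segmentation, DSC perfusion quantification by block-circulant
truncated-SVD deconvolution, contralateral-normalised relative maps,
perfusion-diffusion mismatch ROI construction, per-ROI longitudinal
features, and two-arm cohort statistics — together with a digital stroke
phantom that supplies ground-truth hemodynamics so every stage is
verifiable without patient data.

## Who this is for

Imaging scientists who need a tested, scriptable reference implementation
of the classic stroke mismatch chain (the kind of processing clinical
tools perform interactively), and methodologists who want a ground-truth
phantom and a cohort simulator to study how threshold and deconvolution
choices propagate into group-level inference.

## The method in brief

* **Diffusion.** `ADC = ln(S_b0 / S_b1000) / b`. The infarct core is grown
  from every voxel with `0 < ADC <= 550e-6 mm^2/s` (26-connectivity,
  minimum component 5 voxels); CSF is `ADC > 2000e-6`.
* **Perfusion.** `C(t) = -ln(S/S0)/(k TE)`; the tissue curve is
  deconvolved against the arterial input function through the circulant
  matrix of the zero-padded AIF, truncating singular values below 0.15 of
  the largest. `CBF = max k(t)`, `Tmax = argmax k(t)`,
  `CBV = area(C)/area(AIF)`, `MTT = CBV/CBF` (central volume theorem).
* **Relative maps.** Division (rCBF, rCBV) or subtraction (rMTT, rTmax)
  against the mean of the contralateral hemisphere excluding CSF.
* **Mismatch.** Hypoperfusion: `rTmax >= 6 s` (inclusive). Penumbra =
  hypoperfusion minus core. Unaffected = affected-hemisphere brain minus
  core, penumbra and CSF. Baseline ROIs are applied unchanged at the 3-h
  follow-up.
* **Statistics.** Wilcoxon rank-sum for parameter levels, pooled-variance
  t-tests for 0h-3h changes of the relative perfusion parameters,
  Fisher's exact test for categorical data; two-sided alpha 0.05, no
  multiplicity correction (explorative design). NIHSS improvement >= 4
  points defines early clinical response.

See `vignettes/perfusion-diffusion-mismatch.Rmd` for the full model
description, parameter table and numerical caveats.

## Worked example

```r
library(perfmismatch)

# one synthetic stroke subject (noiseless), processed end to end
subj <- synthesize_subject(phantom_spec(), seed = 42)
res  <- run_subject(subj)

res$features$core_volume_ml      # 1.968
res$features$core_rcbv_baseline  # 0.896  (ground truth 0.9)
res$features$core_rcbv_delta     # 0.053  (configured arm effect 0.05)
res$features$core_adc_baseline   # 450    (10^-6 mm^2/s, below the 550 core threshold)
res$features$core_adc_followup   # 651    (ADC normalisation at 3 h)
```

The subject's infarct core is recovered exactly (Dice 1.0 against the
phantom ground truth), its baseline core rCBV of 0.896 matches the
configured contralateral ratio 0.9 to within the deconvolution's ~1%
area-quadrature error, and the extracted 0h-3h core rCBV change 0.053
reproduces the configured +0.05 treatment-arm effect.

A simulated 13-vs-11 cohort and its comparison table:

```r
co  <- synthesize_cohort(seed = 42)
tab <- run_cohort(co)$comparisons
tab[tab$variable == "core_rcbv_delta", c("mean1", "mean2", "test", "p")]
#   mean1   mean2        test      p
#   0.109 -0.0756 t_equal_var 0.0194
```

Here the active arm's core rCBV rises while the control arm's falls, and
the pooled t-test flags the difference — one random cohort drawn from the
configured effect distributions (population means +0.05 vs -0.14; at
these arm sizes the test's power is about 0.56, so not every simulated
cohort reaches significance).

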