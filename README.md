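# octavasc

Quantification of the retinal microvasculature on enface optical
coherence tomography angiography (OCTA) images, and covariate-adjusted
association modelling against brain imaging markers of cerebral small
vessel disease (SVD).

The retina offers a non-invasive window on the microcirculation: OCTA
resolves the superficial capillary plexus (vessels down to ~8 um) over a
3 mm field without contrast dye. `octavasc` is for researchers who want
the complete, reproducible chain from an enface image to per-eye metrics
and standardized effect estimates — plus a synthetic-data layer with
known ground truth, so every stage can be validated without patient
data.

## What it computes

**Vessel density (VD).** From the final binary vessel map,
`VD = 100 * n_vessel / n_total` (percent of image area occupied by
flowing vessels), an exact integer ratio.

**Segmentation.** Multiscale Frangi vesselness from the Hessian
eigenvalues (|λ1| ≤ λ2| ordering; for bright tubes, λ2 < 0):

    v = exp(-Rb² / 2β²) · (1 - exp(-S² / 2c²)),   Rb = λ1/λ2,  S = √(λ1² + λ2²)

followed by the dual-threshold rule: a global Otsu threshold and a local
adaptive (window-mean) threshold are applied to the enhanced image, and
the final map keeps pixels **where both agree**, then drops components
under 10 px.

**Branching complexity.** Generalized box-counting dimensions

    D(q) = slope[ log Σ μᵢ^q  vs  log ε ] / (q - 1)      (q ≠ 1)
    D(1) = slope[ Σ μᵢ log μᵢ  vs  log ε ]

with the least-squares slope anchored at the whole-image scale, which
makes D(q) non-increasing in q by construction. `summary_fd` is D(0),
the capacity dimension. A Guo–Hall skeletonizer provides 1-px
centerlines with component count preserved.

**Quality layer.** A two-rater ordinal-probit grading simulator,
ICC(2,1) (two-way random effects, absolute agreement) implemented from
the ANOVA mean squares with McGraw–Wong confidence bounds, and Spearman
correlation of consensus grade against the instrument Q index (dB).

**Associations.** Standardized betas (continuous variables z-scored,
binaries 0/1) from univariate and covariate-adjusted linear models of
brain outcomes on OCTA metrics, adjusted by default for age, eye
disease, diabetes, systolic blood pressure and image quality; WMH
volumes are ICV-corrected and log-transformed, PVS volumes corrected for
their region of interest. Eyes are analysed separately, complete-case
per model.

## Worked example

```r
library(octavasc)

gen <- generate_enface(enface_config(rng_seed = 42),
                       subject_id = "S0001", eye = "right")
seg <- segment_vessels(gen$image)
vessel_density(seg)
#> vessel density: 27.099% (67747 / 250000 px)
gen$truth
#> ground truth: 68943 vessel px (VD 27.58%), 46565 centerline px

multifractal_spectrum(seg)
#> multifractal spectrum: q in [-4, 4] (17 points), boxes {4, 8, 16, 32, 64} px
#>   D(0) = 1.9514, D(q) range [1.8327, 2.3848], summary_fd = 1.9514 (d0)

coh <- transform_variables(generate_cohort(cohort_config(n_subjects = 2000,
                                                         rng_seed = 7)))
fit_adjusted(coh[coh$eye == "right", ], "md_nawm", "vd_percent")
#> md_nawm ~ vd_percent + {age, eye_disease, diabetes, sbp_mmHg, image_quality}
#>   standardized beta -0.178 [95%CI -0.222 to -0.134], n = 1983
```

The measured VD (27.10%) sits within half a percentage point of the
generator's ground truth (27.58%). The adjusted standardized beta
recovers the cohort generator's planted VD-to-MD effect (-0.16, within
the confidence interval) after the deliberately planted confounding by
age, diabetes, blood pressure, eye disease and image quality has been
removed; the univariate estimate on the same data is roughly twice as
large in magnitude, showing the confounding the adjustment removes.

The rater-agreement layer works the same way:

```r
rec <- simulate_graders(coh$q_db[coh$eye == "right"], rater_noise_sd = 1.5,
                        seed = 3)
icc_two_way(as.matrix(rec[, c("grade_r1", "grade_r2")]))
#> ICC(2,1) two-way random effects, absolute agreement, single rater
#>   ICC 0.750 [95%CI 0.730 to 0.768], n = 2000 targets, 2 raters
#>   average-measures form: 0.857
```

An end-to-end run (images → masks → metrics → quality → associations,
with a manifest of parameters, seed and output hashes):

```r
run_pipeline(pipeline_config(list(out_dir = "demo_run",
                                  synth = list(n_eyes = 4, side_px = 200),
                                  cohort = list(n_subjects = 104)),
                             seed = 11))
```

Re-running the same configuration reproduces every output
byte-identically. A thin CLI wrapper over the same functions is shipped
at `inst/cli/octavasc` (subcommands: `run`, `synth`, `segment`,
`morpho`, `assoc`, `quality`).

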