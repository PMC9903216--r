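---
title: "Quantifying retinal microvasculature on OCTA enface images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying retinal microvasculature on OCTA enface images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octavasc)
```

## The problem

Optical coherence tomography angiography (OCTA) images retinal blood flow
without contrast dye, resolving the superficial capillary plexus down to
vessels of roughly 8 um caliber over a 3 mm x 3 mm field centred on the
fovea. Because the retinal and cerebral microcirculations share anatomy
and physiology, quantitative OCTA metrics — the fraction of the image
occupied by flowing vessels (vessel density, VD) and the geometric
complexity of the branching pattern (a fractal dimension) — are candidate
non-invasive markers of cerebral small vessel disease (SVD). `octavasc`
implements the full quantification chain and the statistical machinery to
relate the eye metrics to brain imaging variables (white matter
hyperintensity burden, perivascular spaces, cerebrovascular reactivity,
diffusion metrics), with a synthetic-data layer so that every stage is
testable against known ground truth without any patient data.

## The synthetic enface generator

`generate_enface()` grows stochastic branching vessel trees from seeds on
the image border. Each branch advances in short jittered steps; at a
bifurcation the child radii follow the Murray minimal-work rule

$$ r_p^{k} = r_1^{k} + r_2^{k}, \qquad k = 3 \text{ by default}, $$

with the flow split drawn uniformly from 0.3–0.7. Branches terminate when
tapering takes the caliber below `min_caliber_um`, when they leave the
field, or at the rim of the foveal avascular zone (FAZ) — centerlines
never enter the FAZ disc. The rasterized lumens form the ground-truth
mask, and `true_vd` is the exact pixel ratio by construction.

Key defaults and what they represent:

| parameter | default | meaning |
|---|---|---|
| `side_px`, `pixel_um` | 500, 6 | 3 mm field at 6 um sampling |
| `faz_radius_um` | 250 | typical foveal avascular zone |
| `min_caliber_um`–`max_caliber_um` | 8–40 | capillaries to arterioles/venules |
| `n_seed_vessels`, `branch_prob` | 14, 0.12 | yields VD in the high-20s to low-40s % |
| `quality_db` | 37 | healthy-eye signal strength Q (dB, floor 20) |
| `noise_sigma` | 0.5 | speckle spread at the 30 dB reference |

The intensity model is flow signal (0.80) over weak background (0.16),
blurred by a sigma = 0.6 px Gaussian point-spread, then degraded by
unit-mean Rayleigh-type multiplicative speckle and additive Gaussian
noise. The speckle weight is `noise_sigma * 10^((30 - quality_db)/20)`,
a fixed monotone map so that a lower Q index yields visibly worse images.
This emulates the dominant degradations of enface OCTA (decorrelation
speckle, signal loss) but **not** projection artifacts from overlying
vessels, layer-segmentation errors, motion/blink stripes, or media
opacities; fidelity results on synthetic images therefore bound what can
be said about real acquisitions.

`generate_cohort()` builds the tabular side: one row per participant and
eye, with retinal metrics, vascular covariates and brain metrics at
realistic locations and scales (age 68.1 +/- 9.9 y; SBP 149 +/- 19.7 mmHg;
VD 32.1 +/- 5.6 %; Q 37.3 +/- 2.9 dB; MD in normal-appearing white matter
0.76 +/- 0.02 x 10^-3 mm^2/s; WMH volume log-normal with median 8.17 ml,
and so on). Standardized effects of the latent retinal metrics on chosen
brain outcomes are *planted* (defaults: VD to MD -0.16, VD to CVR +0.19,
FD to FA +0.17), and the covariates load on both the retinal and brain
sides so that the unadjusted association is biased by a known, analytically
computed amount (stored as an attribute). Outcomes are built with unit
total variance, so the planted coefficient *is* the standardized beta the
adjusted model should recover. Within-subject eye-to-eye deviation
(`eye_dev_sd = 0.15` on the standardized scale) adds realistic asymmetry
at the cost of ~1% attenuation — negligible against sampling error at the
tested cohort sizes.

## Vessel enhancement and dual-threshold segmentation

`frangi_enhance()` computes the classic two-dimensional vesselness: at
each scale sigma the scale-normalized Hessian (Gaussian-derivative
convolutions, mirror boundary) yields eigenvalues ordered
$|\lambda_1| \le |\lambda_2|$, and for bright tubes ($\lambda_2 < 0$)

$$ v_\sigma = \exp\!\left(-\frac{R_b^2}{2\beta^2}\right)
   \left(1 - \exp\!\left(-\frac{S^2}{2c^2}\right)\right),
   \quad R_b = \lambda_1/\lambda_2,\; S = \sqrt{\lambda_1^2 + \lambda_2^2}, $$

taking the per-pixel maximum over scales and rescaling to [0, 1].
Defaults: scales sigma in {1, 1.5, 2, 3} px (covering 8–40 um calibers at
6 um/px), beta = 1, and c set per image and scale to half the maximum
Hessian norm.

`segment_vessels()` then applies a **global Otsu threshold** and a **local
adaptive threshold** (window mean minus offset, 25 px window) and keeps
only pixels where both agree, followed by removal of 8-connected
components smaller than 10 px. Two design points deserve explanation:

* **What is thresholded.** Thresholding the raw vesselness map
  systematically thins vessels: the Frangi response decays toward lumen
  edges, so the binary map loses the outer rim of every vessel and VD is
  underestimated by several percentage points. The package's default
  "filtered image" is therefore the convex blend
  `(1 - vessel_gain) * raw + vessel_gain * vesselness` with
  `vessel_gain = 0.5`: the vesselness term suppresses non-tubular
  background while the raw term preserves flow-signal contrast across the
  full lumen. Pure-vesselness (`vessel_gain = 1`) and raw-image
  (`use_frangi = FALSE`) modes remain available for comparison.
* **Otsu binning.** The global threshold maximizes between-class variance
  over a 256-bin histogram spanning the data range; ties go to the lowest
  maximizing bin, and the mask takes values strictly above the threshold.
  This makes the operation exactly reproducible and directly comparable
  to an exhaustive search oracle.

The regression tests verify, on synthetic images with known masks, that
the default chain achieves Dice overlap of at least 0.7 at Q >= 30 dB and
vessel density within +/-2 percentage points of truth at Q >= 35 dB; the
acceptance script recomputes both from scratch.

## Morphometrics

**Vessel density** is the exact integer ratio
`100 * n_vessel_px / n_total_px`, optionally within a region-of-interest
mask. No FAZ exclusion is applied by default (density is reported over
the whole field); pass an ROI to restrict it.

**Skeletonization** uses the Guo–Hall two-subiteration parallel thinning
algorithm. Its crossing-number condition preserves 8-connectivity, so the
skeleton has exactly as many connected components as the input map — a
property the tests check both on constructed fixtures and on segmented
synthetic images.

**Branching complexity** is summarized by generalized (Renyi) box-counting
dimensions. For box size $\varepsilon$, with $\mu_i$ the fraction of all
vessel pixels falling in box $i$:

$$ D(q) = \frac{1}{q-1}\,
   \mathrm{slope}_{\log\varepsilon}\,\log \sum_i \mu_i^q
   \qquad (q \ne 1), $$

and the Shannon limit $D(1) = \mathrm{slope}\,\sum_i \mu_i \log \mu_i$.
The slope is fitted by least squares **anchored at the whole-image
scale**, where the partition function is exactly 1 (one box holds the
entire measure). The anchor is not a convenience: it makes every $D(q)$ a
positively weighted average of normalized Renyi entropies, and since
Renyi entropy is non-increasing in $q$, the estimated spectrum is
non-increasing in $q$ *by construction* — the defining property of
generalized dimensions, which a free two-parameter fit does not
guarantee on finite noisy patterns.

Defaults: $q$ from -4 to 4 in steps of 0.5, dyadic box sizes from 4 px up
to a quarter of the image side, boxes overlapping the image edge counted
with their true pixel content. The scalar `summary_fd` is $D(0)$ (the
capacity dimension) by default, with `summary = "mean_dq"` as an
alternative; the choice is recorded in the result object. Two caveats are
documented rather than hidden: for $q < 0$ the box-counting moments are
dominated by boxes holding one or two pixels, and the estimate may exceed
the embedding dimension 2 on inhomogeneous patterns (a known property of
this estimator); and when box sizes do not divide the image side, the
ceiling effect can inflate $D(q)$ marginally above 2 even at $q \ge 0$.
The analytic oracles — filled plane $D(q) = 2$, straight line $D(0) = 1$,
Sierpinski carpet $D(0) = \log 8 / \log 3$ — are reproduced exactly or
within 0.03 by the test suite and the acceptance script. Fractal analysis
runs on the binary map by default (the skeleton is available as input for
a sparser variant).

## Image quality and rater agreement

The instrument's Q index (mean B-scan signal strength, dB, floored at 20
during acquisition) does not fully capture perceived interpretability, so
the quality layer models two human raters grading on a 5-level ordinal
scale (Inadequate to Excellent). `simulate_graders()` is an ordinal-probit
stand-in: each rater bins the latent quality plus independent Gaussian
noise against four ascending thresholds (defaults 33, 35.5, 38, 40.5 dB,
centred on the realistic Q range); consensus is the shared grade or, on
disagreement, the rounded mean with .5 ties going to the **higher** grade
(the direction is arbitrary and documented; real disagreements were
resolved by discussion, which no simulator reproduces).

`icc_two_way()` implements the two-way random-effects, absolute-agreement,
single-rater intraclass correlation ICC(2,1) from the ANOVA mean squares:

$$ \mathrm{ICC}(2,1) =
   \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)}, $$

with the McGraw–Wong F-distribution confidence bounds. The absolute-
agreement form is the defensible default when the question is whether two
raters assign the *same* grade; the consistency form and the
average-measures coefficients are reported alongside, since which form a
study used is often unstated. The implementation is verified against a
hand-computed 6 x 2 ANOVA table (to 1e-10) and against the realized
variance-components ratio in simulation. `spearman_vs_q()` gives the rank
correlation (average ranks on ties) between consensus grades and Q.

## Association models

`transform_variables()` applies the standard normalizations: WMH volume as
a percentage of intracranial volume, then natural log; perivascular-space
volumes as percentages of their region of interest (centrum semiovale,
basal ganglia); PVS counts pass through uncorrected. Zero denominators
leave the derived field missing with a warning; rows are never dropped.

`fit_univariate()` and `fit_adjusted()` report **standardized betas**:
continuous variables are z-scored, binary covariates stay 0/1 with the
outcome standardized (so a binary coefficient reads as outcome SDs per
category). On complete continuous pairs the univariate standardized slope
equals the Pearson correlation to machine precision — an identity the
tests assert on every dataset they touch. The default adjusted covariate
set is age, comorbid eye disease, diabetes, systolic blood pressure
(chosen as the concrete "blood pressure" measure; configurable) and OCTA
image quality entered as the numeric consensus grade 1–5 (Q in dB is an
alternative). Missing data are handled complete-case per model, with
`n_used` reported; rank-deficient designs fail loudly, naming the
collinear columns. No multiple-testing correction is applied by default,
matching common practice for pre-specified association panels; a
Benjamini–Hochberg flag exists on `run_association_suite()`, which fits
every OCTA-metric x brain-outcome pair (univariate and adjusted) for one
eye at a time — eyes are analysed as separate tasks, never pooled.

## Orchestration and reproducibility

`run_pipeline()` executes synthesis, segmentation, morphometrics, quality
simulation and the association suite under a single validated YAML/list
configuration (unknown keys are rejected before any compute), writing a
run directory `{images, masks, metrics, stats, logs}` plus a
`manifest.json` recording package and R versions, the seed, every
parameter and the MD5 of every output. All randomness flows from the
single seed through explicit per-stage offsets, and re-running the same
configuration reproduces every output byte-identically — the acceptance
script asserts this on each run. A thin command-line wrapper
(`inst/cli/octavasc`) exposes the same functions as subcommands.

## Problem sizes in the shipped checks

The test suite and acceptance script choose sizes that exercise the
science while staying quick to run: segmentation fidelity on twenty
500-px images across the 30–41 dB quality range; spectrum monotonicity on
twenty 250-px maps; planted-effect recovery on 100 replicate cohorts of
2000 subjects; the demo pipeline at 200 px with four eyes and a
104-subject cohort. Larger sizes change none of the conclusions, only the
runtime; all are plain function arguments.

## Known limitations

* The generator's trees are geometrically plausible but not
  hemodynamically simulated; capillary loops, anastomoses and the
  two-plexus depth structure are absent.
* Segmentation fidelity is quantified against synthetic truth only; no
  claim is made about agreement with any particular commercial device's
  proprietary quantification.
* The multifractal spectrum at strongly negative q is sensitive to
  near-empty boxes (see above); comparisons across images should rely on
  D(0) or the q >= 0 branch.
* The rater simulator cannot reproduce discussion-based consensus; it
  bounds, rather than replicates, human agreement behaviour.
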