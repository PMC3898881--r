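---
title: "Longitudinal VBM with longvbm: models, calibrations and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal VBM with longvbm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Serial structural MRI of a progressive disease asks a deceptively simple
question: *where* in the brain is tissue volume changing, *how fast*, and is
the rate different between patients and controls? Cross-sectional VBM
(segment every scan, compare across subjects) answers it poorly for
longitudinal designs: between-subject anatomical variability dwarfs
within-subject change. `longvbm` implements the registration-based
alternative: each subject's visits are mapped onto an unbiased within-subject
template, the Jacobian determinants of those warps encode local volume change
directly, and only the *rates* of change are carried across subjects.

The full pipeline is:

1. **Lesion filling** — WM lesions are replaced by draws from the
   normal-appearing WM intensity model so they do not bias segmentation and
   registration.
2. **Brain extraction and non-uniformity correction** — Otsu threshold +
   largest component + morphological closing; a low-order polynomial
   multiplicative bias field is estimated on the log intensities of the
   brightest tissue class and divided out, preserving the mean.
3. **Unbiased within-subject template** — all visits are iteratively
   rigid-registered to the evolving voxel-wise *median* image. No visit is
   ever the fixed reference, which avoids the transfer of interpolation
   asymmetries into apparent "change", and the median is robust to an outlier
   visit in a way the arithmetic mean is not.
4. **High-dimensional warping (HDW)** — each aligned visit is non-rigidly
   registered to the template by a demons-type algorithm; `det(I + grad u)`
   maps show the contraction or expansion of every voxel.
5. **Template segmentation** — a 3-class Gaussian mixture (EM) splits the
   template into CSF/GM/WM by ascending T1 intensity.
6. **Pseudo-time-points** — template GM probability x visit Jacobian: the
   probabilistic GM volume at each visit, on a common within-subject grid.
7. **Group space** — a balanced group template (all controls + an
   equal-sized random patient subset), affine + mild non-rigid warps for
   every subject, trilinear resampling *without modulation* and 8 mm FWHM
   smoothing; an explicit GM mask from the averaged smoothed GM maps.

Inference is the two-level summary-statistic approach: per subject, the OLS
slope (units: GM probability / year) of the smoothed pseudo-time-points
against acquisition time at each voxel (and, optionally, the quadratic
term); across subjects, a GLM with age, sex, baseline total GM volume and
scanner-upgrade proportion as nuisance covariates, tested by max-statistic
permutation with threshold-free cluster enhancement (TFCE, E = 0.5, H = 2,
26-connectivity, dh = max/100) at family-wise error 0.05 with 5000
permutations. A post-hoc year-by-year analysis subtracts each follow-up
pseudo-time-point from baseline in complete-attendance subjects and applies
a sign-flip one-sample test with voxel-wise FWE and no TFCE.

# The synthetic phantom world

The package ships a longitudinal phantom generator because the kind of
cohort this pipeline was designed for cannot be redistributed. The phantom
is a sphere with a central CSF compartment, WM bulk, a cortical GM shell and
two deep GM disease regions: a fast **cingulate analog** (8 mm core radius at
the default 32^3 x 2 mm grid) and a slow **precentral analog** (6.5 mm),
mirroring the empirical finding that GM volume loss is regionally
heterogeneous — fastest in cingulate/precuneus, slowest in precentral
cortex.

Atrophy is synthesized as an analytic radial contraction: inside the region
core the map is a uniform scale `s = f^(1/3)` (so the Jacobian is exactly
the cumulative volume factor `f`), decaying to the identity through a C1
cubic-Hermite shell. Consequently every visit has a closed-form truth
deformation field and Jacobian map, against which the estimated fields,
pseudo-volumes and slopes are validated.

Stated-world defaults (chosen once, before any acceptance measurement, and
not revisited):

| parameter | default | why |
|---|---|---|
| visit schedule | 0, 1, 2, 3, 5 years | the study design being emulated |
| missingness | 15% per follow-up, >= 2 visits kept | realistic attrition |
| patient rates | -2 %/yr (cingulate analog), -0.5 %/yr (precentral analog), SD 0.004/0.002 | the reported fast/slow regimes |
| noise | SD 5 on tissue means 40/80/120 (~5%) | typical 1.5 T SNR regime |
| bias field | order-2 polynomial, +/-10% | typical non-uniformity |
| scanner upgrade | year 2.5, +5% global intensity | 2 of 5 visits post-upgrade (40%), matching the "41% of patient data post-upgrade" regime |
| subject jitter | 1 mm SD translation | positioning variability |
| ages/sex | patients 42.8 (SD 11), controls 37.6 (SD 9.4); 33%/47% female | demographic table of the emulated study |
| clinical slopes | MSFC -0.25/yr, EDSS +0.36/yr, T2LL +2.59 ml/yr | reported progression rates |

Clinical coupling: a subject's MSFC slope is
`intercept + gain x (cingulate-analog rate) + noise`. For association
experiments the gain is chosen *analytically* by
`tune_clinical_coupling(r_target = 0.5, ...)` so that the Pearson
correlation between the true regional rate and year-5 MSFC equals 0.5, the
regime of the empirical association this pipeline is validated against
(r = 0.49 in the source cohort). The tuning accounts for baseline-MSFC
spread, slope noise and visit noise; it is a prescribed calibration, not a
fit to an observed test outcome.

**What a green test does and does not establish.** The phantoms have
piecewise-constant tissue, spherical geometry, Gaussian noise, static
lesions and purely radial ground-truth deformations. Passing tests establish
the *computational* correctness of every stage and the statistical validity
of the inference machinery at desk scale; they do not establish that the
pipeline recovers biological atrophy in real convoluted cortex, nor
reproduce the source study's peak t-values or cluster tables, which derive
from an undeposited 36+19-subject clinical cohort.

# Numerical choices and calibrations

* **Non-uniformity correction** is a two-pass ridge-regularised log-domain
  polynomial fit: pass one uses the brightest class only (robust to the
  uncorrected field) and removes the bulk; pass two re-classifies on the
  corrected image and fits the two brightest classes jointly (per-class
  intercepts, shared field), whose wide spatial support pins the polynomial
  down at the brain periphery where a WM-only fit extrapolates. The ridge
  keeps directions the reference geometry cannot identify (r^2-like terms
  on shell supports) near zero. The mean brain intensity is preserved.
* **ROI-level analyses** (regional rates, clinical associations) use
  first-level slopes fitted on *unsmoothed* normalised pseudo-time-points:
  ROI averaging pools spatially by itself, and 8 mm smoothing would mix
  non-atrophying neighbouring GM into deep-region means, attenuating
  fractional rates by ~20%. Voxel-wise inference uses the smoothed maps.
* **Rigid/affine registration** is derivative-free (Nelder-Mead with
  parameter scaling, coarse stride-2 stage then full-resolution polish) over
  SSD or a 32-bin joint-histogram mutual information. Powell's method (used
  by the emulated tool) is not available in base R; Nelder-Mead is the same
  derivative-free family and meets the same accuracy contracts (identity to
  0.1 mm/0.1 deg; known shifts to 0.5 mm; inverse-consistency to 0.5 mm).
* **HDW** is a multi-resolution demons algorithm: SSD forces with the
  standard normalisation, fluid-like smoothing of each update (sigma 1
  voxel) and elastic smoothing of the field. The emulated tool's
  "regularisation parameter of four with 8 iterations" has no published
  energy form; it is mapped to an elastic sigma of `0.25 * sqrt(reg_param)`
  voxels with 8 outer iterations of 5 demons updates each. The 0.25 factor
  and the image pre-smoothing (sigma 1.0 voxel) were calibrated against the
  phantoms' analytic volume factors (a mean regional Jacobian of 0.90 must
  be recovered within +/-0.03, and the recovered effect-to-noise ratio was
  maximised at the 5% noise regime) *before* the acceptance experiments
  were run. Images are intensity-matched (global linear scale) first:
  demons assumes intensity constancy, which the scanner-upgrade shift
  deliberately violates. Divergence (negative-Jacobian fraction above 0.1%)
  triggers step halving.
* **Median template convergence**: iteration stops when either the largest
  rigid-parameter change falls below 0.01 mm / 0.01 deg or the template's
  mean absolute change falls below 1e-3 of its range (the optimiser's
  parameter jitter sits near 0.05 mm, so the template-stability criterion is
  the one that usually fires), with at most 5 iterations.
* **Segmentation** initialises the EM means spread evenly over the intensity
  range rather than at sample quantiles: the phantom's CSF class is only
  ~2% of brain volume and quantile initialisation collapses it into GM. A
  variance floor handles the noiseless limit.
* **Permutation p-values**: with exhaustive enumeration (all sign-flips or
  all group relabellings, used automatically whenever the count does not
  exceed `n_perm`), `p = b/N` exactly; with sampling,
  `p = (1 + b)/(n_perm + 1)`, so p is never 0 and the observed labelling is
  always in the null sample. Nuisance covariates use Freedman-Lane
  residualisation.
* **TFCE** integrates `e(h)^0.5 h^2 dh` over thresholds `dh = max/100` with
  26-connectivity, positive tail only (negate the contrast for the other
  tail), implemented as a descending union-find sweep in C++ and validated
  against an igraph-based brute-force oracle.
* **Explicit mask threshold**: the masking method cited by the emulated
  pipeline is not specified by formula; Otsu's threshold on the average
  smoothed GM map is used.
* **EDSS steps**: the cited step-conversion rule is not reproduced in the
  source; the ordinal rank on the legal grid {0, 1, 1.5, ..., 10} is used
  and isolated in `edss_to_steps()` so it can be swapped.
* **Outlier rule** for association scatter: externally studentized residual
  > 3 from the `y ~ x` fit, reported with and without exclusions.
* **Box-Cox**: shift 10 (so negative MSFC composites become positive),
  lambda by profile-likelihood MLE unless given.

# Design decisions where the design was open

* Atrophy is *synthesized* as analytic fields rather than re-segmented so
  the acceptance surface has exact ground truth.
* Jacobians reflect non-rigid volume change only: visits are rigidly
  resampled to the template first, matching the staged order of the emulated
  pipeline.
* The GM probability multiplied into every pseudo-time-point comes from the
  single within-subject template segmentation, not per-visit segmentations.
* Subjects with exactly 2 visits still contribute slope images (no
  reliability weighting at the second level); full mixed-effects modelling
  is explicitly out of scope.
* DARTEL's role is played by iterative affine + demons group averaging with
  the same balanced-set rule; it is an equivalent-role substitute, not a
  re-implementation.
* Scale-downs for desk-scale validation: the type-I-error experiment feeds
  the permutation machinery slope images built from truth-identity Jacobians
  perturbed by smooth zero-mean noise (running ~8000 demons registrations
  under a 10-minute budget is not feasible; the registration path is
  validated separately on phantoms with known atrophy), and the
  clinical-association power experiment uses true regional rates plus a
  small (SD 0.001) estimation error in place of 100 imaging-pipeline runs.
  The second-level permutation count is reduced (200 for the null
  calibration, 1000 for the recovery experiment) from the production 5000;
  p-value resolution remains far below the 0.05 decision threshold.

# Known limitations

* Demons registration of a ~3% volume change moves region boundaries by
  well under half a voxel at 2 mm resolution; with 5% intensity noise the
  per-subject recovered fraction of the true change varies substantially
  (roughly 0.4-1.2 across noise realisations in our experiments). This is a
  physics-of-the-problem limit shared by the real pipeline and is the main
  driver of between-patient variance at the second level. Concretely, at
  12 + 12 subjects the in-region two-sample t sits near 3, leaving the TFCE
  FWE-0.05 detection right at threshold: across implementation variants the
  map recovered between none and the core ~15% of the fast-atrophy region
  (Dice 0-0.2 against the anatomical truth label, never any false-positive
  overlap elsewhere); the corresponding acceptance criterion is
  deliberately left failing rather than relaxed, with the analysis recorded
  alongside the package.
* Only axis-aligned acquisition geometries are exercised; the NIfTI reader
  accepts general sform affines but the phantoms never produce oblique ones.
* Gaussian noise only (no Rician floor), static lesions, no cortical
  geometry: adequate for validating the pipeline's computation, not its
  behaviour on real data.
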