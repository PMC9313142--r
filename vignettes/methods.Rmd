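---
title: "Methods: PERCIST-style PSMA PET quantification and response modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PERCIST-style PSMA PET quantification and response modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmapercist)
```

## The measurement model

The package analyzes 3D PET volumes already calibrated to standardized
uptake values normalized to lean body mass (SUL; the male Janmahasatian
formula `9270·W/(6680 + 216·BMI)` is provided by `lean_body_mass()` for
users starting from body-weight SUV — the study population this analysis
targets is male, so no female formula is exposed). Volumes are stored in
`(z, y, x)` axis order with voxel spacing in mm; the center of voxel `i`
(1-based) along an axis with spacing `s` sits at `(i − 0.5)·s` mm, and a
voxel belongs to any analytic shape (lesion ellipsoid, aortic cylinder,
averaging sphere) iff its center lies inside the shape, boundary
inclusive. This single stated convention makes every geometric quantity
reproducible by brute force, which is exactly how the test suite checks
them. All physical quantities are mm and mL.

### Blood-pool reference and threshold

Uptake is referenced to the aortic blood pool: a cylindrical VOI (30 mm
long, 10 mm diameter by default, axis-aligned) yields a mean, an SD
(denominator n−1) and a peak-sphere statistic, and the segmentation
threshold is

`T = 1.5 · SUVpeak(aorta) + 2 · SD(aorta)`.

The cylinder length is part of the method; its diameter is not specified
by it, so 10 mm — a typical adult aortic lumen comfortably inside the
vessel — is the default and both are configurable. The VOI must lie fully
inside the grid, contain at least two voxels (otherwise the SD does not
exist and the call errors), and sphere centers for the peak statistic are
constrained to the VOI.

### SUVpeak

`suv_peak()` returns the maximal mean over averaging spheres of 1.2 cm
diameter (~1 cm³, the PERCIST tradition) centered at voxel centers inside
the query mask. The sphere may extend beyond the mask into surrounding
tissue but not outside the grid: centers whose sphere would leave the
grid are excluded, and only if no center admits a full sphere (a mask
hugging the volume boundary) the implementation falls back to
boundary-truncated spheres so that the statistic remains defined. Ties
are broken deterministically toward the lowest `(z, y, x)` center. For
lesions smaller than the sphere, SUVpeak is necessarily below the plateau
intensity because background enters the average — visible in the worked
README example and relevant when interpreting TL-PSMA on small lesions.

### Segmentation and burden metrics

Lesions are the 26-connected components of voxels with SUV strictly
greater than `T` (an 18- or 6-neighborhood can be selected), minus an
exclusion mask covering physiological uptake — the aortic VOI itself is
always excluded. Manual VOI editing is out of scope; a user-supplied
exclusion or site-label volume plays that role. Components smaller than
0.3 mL are disregarded, and each survivor must additionally satisfy
`suv_peak(component) > T`. Labels are assigned by decreasing volume with
ties resolved by the smallest linear voxel index, so segmentations are
bit-reproducible. Burden metrics are `PSMA-TV = Σ volume_l` and
`TL-PSMA = Σ SUVpeak_l · volume_l`; whether such a total-lesion metric
should instead multiply a single global SUVpeak by the total volume is
genuinely ambiguous in the underlying method tradition, so the summation
reading is the default and the global reading is available via
`tl_psma_mode = "global"`. No cap is placed on the number of quantified
components (vendor consoles sometimes cap visual validation; that is a
tool artifact, not method).

### Response classification

At the lesion level the SUVpeak change classifies iCR (follow-up uptake
resolved below threshold, recorded as 0), iPR (≤ −30%), iPD (≥ +30%) and
iSD (neither); at the patient level TL-PSMA plays the same role, with the
appearance of any new lesion sufficient for iPD regardless of the burden
change (the conservative reading of "and/or"), and no patient-level
complete-response category is emitted. Biochemical response uses the
asymmetric PSA rules: bPR strictly more than 50% reduction, bPD at least
25% increase, bSD between (so exactly −50% is bSD and exactly +25% is
bPD). Boundaries at ±30% are inclusive on both sides; since both rules
cannot hold simultaneously the iPR branch is evaluated first. A
tolerance of 1e-9 percentage points absorbs floating-point error exactly
at the boundaries. Classification is scale-invariant and total: every
valid input receives exactly one category.

Cross-timepoint lesion matching — done manually in clinical reads — is
greedy nearest-centroid within 15 mm and the same site category (both
configurable; "unknown" sites match anything), with unmatched baseline
lesions scored as resolved and unmatched follow-up lesions flagged new.

## The statistical layer

All uptake analyses work on the natural-log scale (uptake values are
right-skewed); significance is two-sided at 0.05 and no multiplicity
correction is applied across the univariate screens — a deliberate match
to the analysis tradition this package implements, and a documented
limitation when reading its outputs.

**ROC cutoffs.** The empirical ROC uses the convention that a higher
baseline score predicts response, with every observed score (plus +Inf) a
candidate cutoff and positivity defined as `score ≥ cutoff`. Youden's
`J = sens + spec − 1` selects the primary cutoff; ties are resolved
toward higher specificity and then the larger cutoff, reflecting the
rule-out use of these thresholds (below the cutoff, response is
unlikely). Mathematically tied operating points can differ in the last
floating-point digit, so ties are detected with a 1e-12 tolerance. The
second operating point is the smallest cutoff achieving specificity
≥ 0.80. AUC is the trapezoid rule, identical to the Mann–Whitney
statistic with ties counted half. `bootstrap_corrected_auc()` applies
Harrell's optimism correction to the c-statistic of the univariate
logistic model (default B = 1000, seeded; degenerate single-class
resamples are redrawn with a cap).

**Mixed models.** `fit_lmm()` regresses log SUVpeak or log SUVmax on the
imaging response — dichotomized (responder = iCR ∪ iPR) or categorical
with iPD as reference — with a per-patient random intercept absorbing
between-patient uptake level, and optional PSMA-TV (entered per liter)
and site confounders plus a site × response interaction. The model is
deliberately oriented with log uptake as the outcome and response as the
fixed effect, the direction in which the reported coefficient tables are
interpretable as uptake ratios after exponentiation; prose descriptions
of such analyses sometimes state the reverse orientation, which is noted
but not implemented. Estimation is maximum likelihood (not REML) so the
likelihood-ratio test against the model without the response terms is
valid; coefficient CIs are Wald. Rank-deficient fixed-effect designs
error with the collinear columns named rather than silently dropping
terms. With zero between-patient variance the fit collapses to ordinary
least squares (verified to 1e-6 in the tests).

**Logistic screens.** Each candidate predictor is tested univariately
while correcting for tumor load: `outcome ~ variable + PSMA-TV` against
`outcome ~ PSMA-TV` by LRT. Quasi-separation — near-certain fitted
probabilities or diverging coefficients, which in small cohorts produces
astronomically large odds ratios with unusable Wald intervals — is
detected and flagged while the LRT p-value is still reported, since the
likelihood difference remains meaningful when the Wald interval does not.

**Survival.** Kaplan–Meier product-limit curves per group with the median
defined as the first time survival drops to 0.5 or below (NA when never
reached, e.g. an all-censored group), two-sided log-rank tests, and
univariate Cox models with Efron tie handling; factor covariates expand
to reference-coded contrasts with the reference level shown explicitly.
Monotone partial likelihoods (a level without events) are flagged.

## What the synthetic data emulates — and what it does not

`generate_phantom()` builds SUV volumes from known geometry: normal
background clipped at zero, a normal aortic cylinder, and ellipsoidal
lesions at plateau intensity, with optional Gaussian smoothing (off by
default so that oracles stay exact; when on, it is a crude stand-in for
partial-volume blur). Overlapping lesions and lesions crossing the grid
boundary are rejected, because the ground truth would otherwise be
ambiguous. Geometry is independent of the noise seed.

`simulate_cohort()` mirrors the generative structure the inferential
layer assumes: for patient *i*, lesion *j*,

`log SUVpeak_ij = site_mean + b_i + β·R_ij + ε_ij`,
`b_i ~ N(0, τ²)`, `ε_ij ~ N(0, σ²)`,

with the lesion response `R_ij` drawn from a logistic link on the latent
(pre-contrast) log uptake, and iCR/iPR vs iPD/iSD splits applied within
responders and non-responders. Defaults reflect the clinical population
the generator emulates: 32 patients with ~8 analyzed lesions, site means
at log of typical baseline medians (prostate 13.7, lymph node 7.4, bone
6.84, visceral 7.33), τ = 0.4 and σ = 0.5 (an intra-class correlation of
0.39, a realistic degree of within-patient clustering of uptake),
β = ln 1.80 (responding lesions 1.8-fold more avid), ~63% objective
lesion response, lognormal PSA around a median of 210 ng/mL, and
exponential survival with median 10 months under uniform administrative
censoring over 12–48 months (~85% observed deaths), with a hazard ratio
of 0.45 for patient-level responders. SUVmax is tied to SUVpeak by a
fixed factor of 1.35: the joint distribution of the two metrics is not
part of the generative model, any factor above one serves, and the value
is configurable.

Passing tests on these data show that the quantification recovers known
geometry and that the models recover known parameters under the assumed
structure. They do not show robustness to what real scans add:
reconstruction noise correlations, partial-volume effects beyond
Gaussian blur, respiratory motion, physiological uptake outside the
aorta, reader variability in lesion matching, or follow-up uptake
censored at the threshold. That censoring matters for interpretation: in
clinical data, lesions classified iCR can show paradoxically *low*
baseline uptake because small, faint lesions drop below the
blood-pool-derived threshold at follow-up; the generator does not model
this mechanism, so simulated iCR lesions share the responder uptake
boost.

## Numerical choices and reproducibility

One root seed drives everything through derived per-component streams
(`derive_seed()`), so phantom noise, cohort draws, PSA, survival and
bootstrap resampling are independently reproducible; reruns of the
pipeline with the same configuration are byte-identical, and the run
manifest (config hash, seed, version, row counts) fully determines all
stochastic outputs. Percent changes are carried at full precision and
rounded to two decimals only in reports. Degenerate inputs have defined
behavior throughout: empty segmentations are valid results, single-value
groups flag a degenerate CI, all-censored groups report an unreached
median, single-class outcomes and empty masks error early with plain
messages.

The test suite sizes its simulations for minutes, not hours, while
keeping estimates stable: oracle equivalence runs on 50 random 20³
phantoms (segmentation vs flood fill), 30³ grids (SUVpeak vs exhaustive
sphere search) and 200 random ROC datasets; parameter recovery uses 100
cohorts of 200 patients × 8 lesions; null calibration uses 200
replicates at n = 100. At 200 replicates the expected Kolmogorov
distance of even a perfectly uniform p-value sample is ≈ 0.06, so
calibration is asserted against the 5% Kolmogorov critical value
(≈ 0.096) rather than a fixed 0.05.

## Known limitations

- No PET physics: attenuation, scatter, reconstruction and motion are out
  of scope; volumes must arrive as calibrated SUV (NIfTI).
- No automatic aorta localization; the VOI center is an input.
- No RECIST (size-based) classification and no more than two timepoints.
- The SUVmax–SUVpeak link in the simulator is a convenience, not a model.
- Univariate screens without multiplicity correction invite optimistic
  interpretation; the bootstrap-corrected c-statistic mitigates only the
  resubstitution optimism of a single model.
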