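---
title: "Adaptive per-region ANCOVA for grey-matter volumetrics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive per-region ANCOVA for grey-matter volumetrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ahglm)
```

## The problem

Voxel-based morphometry (VBM) studies that compare grey-matter volume (GMV)
between two groups face a sensitivity dilemma. Voxelwise inference with
random-field cluster corrections is rigorous but conservative: a cohort can
show a large, significant whole-brain GMV difference while only a few small
clusters survive locally. Region-of-interest (ROI) analysis over a standard
atlas parcellation is the natural middle ground — but a *fixed* ANCOVA
(always age + TIV + interactions) wastes error degrees of freedom in regions
where a covariate has no relationship with volume, and a fixed two-sample
test ignores real covariate structure where it exists.

`ahglm` implements an adaptive compromise: each region's model contains
exactly the covariates and group-by-covariate interactions that pass
explicit screening rules, everything downstream (group F test, effect size,
FDR) is computed on that region-specific model, and the screening rules are
deterministic and auditable.

## Volumetrics

Regional volumes come from modulated tissue-probability maps: after spatial
normalisation, voxel intensities are scaled by the Jacobian of the
deformation, so summing voxel values over a region and multiplying by the
voxel volume recovers the subject's native tissue volume there.
`total_volume()` is exactly that masked sum (mL = mm³/1000); `compute_tiv()`
adds the GM, WM and CSF whole-image totals. Three deliberate choices:

* **No thresholding.** Every voxel value in the mask is summed as-is. A
  floor on GM density would bias small or low-density regions and no
  principled cutoff exists for modulated maps.
* **No resampling.** Maps and atlas must share the voxel grid; a mismatch
  is an error. Silent interpolation changes volumes, which is the very
  quantity under study.
* **Exact label membership.** The atlas is an integer label image; a voxel
  belongs to a region iff its label equals the region's id.

The voxel volume is derived from the image geometry (absolute determinant
of the 3×3 spatial part of the voxel-to-world transform), which equals the
product of voxel dimensions for axis-aligned grids. Upstream smoothing is
the acquisition pipeline's business; incoming maps are treated as final.

## The adaptive model

For subject *j* in group *i* (Med = 0 control, 1 meditator) the full
per-region model is

$$GMV_{ij} = \beta_0 + Med_i + \beta_1 Age_{ij} + \beta_2 TIV_{ij} +
\beta_3 (Med \times TIV)_{ij} + \beta_4 (Med \times Age)_{ij} +
\varepsilon_{ij}$$

with the plain two-group model $GMV_{ij} = \beta_0 + Med_i +
\varepsilon_{ij}$ at the other extreme. Which terms a region carries is
decided by screening:

* a covariate (Age or TIV) is included iff its pooled-sample Pearson
  correlation with the region's GMV satisfies **|r| > 0.4 and p < 0.05**
  (strict inequalities; the p-value is the standard t transform of r);
* an interaction is considered **only if its covariate is included**, and
  enters iff its coefficient in `GMV ~ Med * cov` has p < 0.05.

The four inclusion flags map onto a nine-cell **zone** taxonomy:

| zone | terms besides Med |
|------|-------------------|
| 1    | — |
| 2A   | TIV |
| 2B   | Age |
| 2C   | TIV + Med:TIV |
| 2D   | Age + Med:Age |
| 3A   | Age + TIV |
| 3B   | Age + TIV + Med:TIV |
| 3C   | Age + TIV + Med:Age |
| 3D   | Age + TIV + both interactions |

Only the endpoints (1, 3A, 3D) of this taxonomy are fixed by the method's
published description; the intermediate cells are this package's
reconstruction — they span exactly the models the screening rules permit,
and the code treats the table as the definition (`classify_zone()`,
`zone_from_code()`).

Three screening choices were genuinely open and are resolved as follows.
The correlation screen uses **|r|** rather than signed r because age–GMV
correlations are negative throughout the brain; a signed rule could never
admit Age. The screen is computed on the **pooled** sample (both groups
together): it asks whether a covariate relationship exists at all, which is
a group-blind question; within-group screening would halve the n behind
each r and couple model selection to the group labels. Thresholds are
strict (`>`, `<`), so r = 0.4 exactly fails.

## Estimation and testing

The zone model is fitted by ordinary least squares with **sum-to-zero group
coding** (−½/+½) and **mean-centred covariates** before interaction columns
are formed. With this parameterisation the Med coefficient is the group
contrast at average covariate values, so it stays interpretable in
interaction zones; in zones without interactions the partial F for Med is
identical under any coding, and those are the zones where essentially all
results land in practice. The group test compares the zone model against
the same model with the Med column removed (partial F, 1 numerator df);
`p` comes from F(1, n − k) where k is the zone's parameter count, so at
n = 46 a Zone 3A region has 42 error df and a Zone 1 region 44.

Effect size is partial eta-squared, $\eta^2_p = SS_{Med}/(SS_{Med} +
SS_{err})$, which for a 1-df effect is algebraically $F/(F + df_{err})$ —
an identity asserted on every fit and re-verified on every report row
before it is written. Group means, SDs and the relative difference
(`(mean_med − mean_ctrl)·100/mean_ctrl`) are **raw** per-group statistics,
not covariate-adjusted means, matching how regional volumes are tabulated.

Sex is never a model term: TIV absorbs it (the package reports the
sex-on-TIV two-sample t-test as a dataset audit instead, and the
group-balance audit covers age/TIV matching). Subjects with missing
covariates are dropped with a warning; no imputation.

### Diagnostics are advisory

Shapiro–Wilk on internally standardised residuals, median-centred Levene
across groups, an outlier count at |standardised residual| > 3, and a
slope-homogeneity p per included covariate are attached to every fit as
flags. They never trigger automatic refitting: assumption checking is a
post-hoc audit, and silent model switching would make the inference path
data-dependent in an unreportable way.

## False discovery rate

Multiplicity is handled per atlas family (the 16 lobar regions are one
family, a 116-region parcellation another, and {right hemisphere, left
hemisphere, whole brain} a third) with Storey–Tibshirani q-values:
$\hat\pi_0(\lambda) = \#\{p_i > \lambda\}/(m(1-\lambda))$ on the grid
λ = 0, 0.05, …, 0.90, smoothed by a cubic spline with 3 effective df and
evaluated at λ = 0.90, clamped into (0, 1]; q-values are the step-down
minimum of $\hat\pi_0\, m\, p_{(i)}/i$. Families smaller than 20 tests use
π₀ = 1, where the procedure reduces exactly to Benjamini–Hochberg — the
spline estimate of π₀ is unstable at tiny m, and for the 3-member
hemisphere family π₀ = 1 is also what reproduces the published common
q-value (0.007 from p = 0.004, 0.007, 0.005). Separate families are not a
convenience: the lobar and hemisphere blocks publish different q-values for
overlapping p-values, which is only consistent if each family was adjusted
on its own.

## The synthetic cohort

`generate_cohort()` + `generate_volumes()` emulate the statistical
structure of the study the method was built for: 23 + 23 subjects, 17 F /
6 M per group, ages uniform on 21–63 y (the published range; uniform gives
SD ≈ 12.1 y, close to the reported 11.4), TIV normal around sex-specific
means with both groups drawn from the same covariate distributions
(matched groups). Regional volumes follow the full model as a generative
equation, with a multiplicative group effect (`effect_pct` of baseline,
since group differences are reported as percentages throughout).

Calibration of the default whole-brain region
(`whole_brain_spec()`: baseline 611 mL, effect 6.93%, age slope −3.0 mL/y,
TIV slope 0.35 mL/mL, residual SD 42 mL) was done analytically against the
published control-group dispersion: with TIV's total SD ≈ 142 mL (within-sex
100 plus the sex-mean gap) and age SD 12.1 y, the implied control total SD
is $\sqrt{(0.35·142)^2 + (3.0·12.1)^2 + 42^2} ≈ 74.6$ mL — the published
whole-brain control SD — with pooled correlations r(GMV,TIV) ≈ 0.67 and
r(GMV,Age) ≈ −0.49, i.e. a region that screens into Zone 3A most of the
time. The lobar preset scales slopes and noise proportionally to baseline
(preserving those correlations) and plants the published effects in the
four affected regions; the brainstem-like regions carry no covariate
structure and screen into Zone 1.

The sex→TIV gap deserves a note. The generator's contract is that the
pooled sex-on-TIV t-test (34 F vs 12 M) comes out below 10⁻⁴ in ≳95% of
seeds, as in the source cohort. With a 150 mL gap at SD 110 the expected
t is ≈ 4.06 (df 44), while p < 10⁻⁴ needs t > 4.31 — such a cohort would
fail its own audit about half the time. The defaults therefore use
F 1370 / M 1600 mL at SD 100 (a ~17% dimorphism, at the upper edge of the
anatomical literature), giving expected t ≈ 6.9 and a comfortably
satisfied audit. This was fixed at design time from the power calculation
above, not tuned against test outcomes.

`generate_nifti_fixture()` closes the loop to image space: it builds a
block atlas and per-subject tissue maps whose masked sums reproduce a given
volume table exactly, so the volumetrics stage can be tested end-to-end
through real NIfTI files. What the generator deliberately does **not**
emulate: brain geometry, spatial autocorrelation and smoothing (regions are
blocks, values uniform within a block), inter-regional covariance (regions
are generated independently), and any non-Gaussian residual structure.
Passing tests therefore validate the statistical machinery, not the
upstream segmentation pipeline — the package consumes modulated maps, it
does not produce them.

## Numerical choices and degenerate inputs

* OLS is solved by QR (`lm.fit`); rank deficiency is reported as an error
  naming the collinear columns, never silently pivoted away.
* q-values with π₀ = 1 are computed in the operation order `(m/i)·p`, so
  they are bit-identical to `p.adjust(..., "BH")`.
* Zero-variance regions fail the covariate screen with a flag (r is
  undefined); a constant region degenerates to a flagged row while the rest
  of its family continues.
* Ties in p share the q of their rank block automatically through the
  step-down minimum.
* Volumes are generated strictly positive; negative draws (possible for a
  tiny-baseline region) are clipped to zero with a warning.
* All stochastic routines take explicit seeds; identical seed + config
  gives byte-identical report files. Generator arguments are forced before
  the RNG is seeded, so passing a generator call as an argument cannot
  perturb the stream.
* Reports are written twice: rounded like the published tables (2 decimals
  for F/mL/percent, 4 for p/q/η²p) and at full precision for machines.

## Known limitations

* The intermediate zone cells (2A–2D, 3B, 3C) are a reconstruction, as
  flagged above; results in those zones depend on the sum-of-squares
  convention (the sum-to-zero partial F here is Type-III-like), whereas
  Zone 1/3A results — where published findings lie — are coding-invariant.
* Screening and testing reuse the same data; the nominal p-values are
  conditional on the selected zone. The type-I simulation in the test
  suite (2000 screened-and-fitted null regions at the study's n, design and
  covariate structure; rejection rate within the 99% binomial band of 0.05)
  shows the selection step does not meaningfully inflate the group test at
  this design, but that is an empirical, not a theoretical, guarantee.
* Published-table arithmetic is reproduced from printed (rounded) values;
  three printed numbers are internally inconsistent at the last digit
  (a lobar relative difference of 19.68 recomputes to 19.76 from its
  printed means; one hemisphere η²p of 0.182 recomputes to 0.181 from its
  printed F; a 429.5 mm³ cluster summation recomputes to 429.6). Tests
  assert the recomputable values and note each case.
* Voxelwise statistics, random-field theory and non-stationary cluster
  correction are out of scope; so are XLSX ingestion (convert
  supplementary sheets to TSV first) and any resampling/registration.

## Problem sizes used in the checks

Simulation-backed tests run at the study's own scale (n = 46 cohorts):
2000 null region fits for the type-I rate, 500 replicates for effect
recovery, 500 seeds for the sex→TIV audit, 200 replicates of m = 5000 for
FDR control, 100 replicates of the 16-region family for ranking recovery.
These sizes put the Monte-Carlo error well inside each criterion's band
while keeping the default suite under a minute.
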