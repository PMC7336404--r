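---
title: "Methods: DSC-MRI radiomics for glioma stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DSC-MRI radiomics for glioma stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dscradiomics` implements a complete radiomic analysis of relative cerebral
blood volume (rCBV) maps from dynamic susceptibility contrast MRI of
gliomas: intensity normalisation against a contralateral reference region,
extraction of 29 shape/histogram/texture features over the tumour mask,
covariate-corrected nonparametric group comparison, random-forest
stratification of IDH mutation status and WHO grade under repeated
stratified cross-validation, and introspection of the misclassified cases.
Because multi-centre patient perfusion data cannot be redistributed, the
package ships a synthetic cohort generator with the class-conditional
statistical structure the analysis assumes, so that every stage is testable
end to end. This vignette records the model, the conventions, and the design
choices a maintainer or reviewer would want to see justified.

## Spatial and intensity normalisation

Raw rCBV intensities are not comparable across subjects or scanners. The
pipeline therefore

1. resamples volumes to an isotropic grid (default 1 mm) — trilinear
   interpolation for scalar maps, nearest-neighbour followed by a `> 0.5`
   re-binarisation guard for masks — so that 3D texture offsets have equal
   physical length in all directions;
2. restricts the basal-ganglia reference mask to the tumour-free hemisphere
   and removes any tumour voxels that cross the midline
   (`sanitize_reference()`); an empty result is a hard error since no valid
   normalisation is then possible;
3. z-scores the map against the clean reference:
   \(z(v) = (x(v) - \hat\mu_{\mathrm{ref}})/\hat\sigma_{\mathrm{ref}}\).

Conventions, chosen once and tested: the spread estimator is the *sample*
standard deviation (\(n-1\) denominator); the resampled grid is anchored at
the input origin with output size \(\lceil \text{extent}/\text{target}
\rceil\) per axis, voxel centres at \((i-\tfrac12)\,s\); resampling at the
input's own spacing is an exact identity, which also makes the operation
idempotent. Z-scoring happens *after* resampling; the declared order is
tested (the z-map is invariant under affine changes \(a + bx\), \(b>0\), of
the raw map, so the two orders differ only through interpolation of the
reference, and a fixed order keeps runs reproducible). Rigid registration is
out of scope: synthetic cases are generated pre-aligned and the pipeline
asserts grid identity instead.

The deeper brain hemispheres are modelled as the two half-spaces on either
side of the mid-plane of the first array axis. This is the simplest geometry
that honours "reference region in the tumour-free hemisphere" and is shared
by the generator and the sanitiser.

## The 29 features

**Shape (4).** On the isotropic grid with spacing \(s\):
volume \(= N s^3\); surface \(= F s^2\) with \(F\) the number of exposed
voxel faces (6-connectivity); SAV \(=\) surface/volume; non-compactness
\(= \mathrm{surface}^3 / (36\pi\,\mathrm{volume}^2)\), dimensionless and
minimal for a ball. Face counting is exact on boxes (the single-voxel and
cube fixtures in the tests are exact identities) and deterministic. Its
known bias is documented rather than hidden: a digitized ball's face-count
surface overestimates the continuum area by a factor approaching 3/2
(staircase effect), so voxelized spheres sit near \((3/2)^3 \approx 3.375\)
in non-compactness instead of 1. The measure remains scale-free and
monotone in boundary irregularity, which is what the analysis uses it for;
tests assert the scaling laws (volume ×8, surface ×4, SAV ×0.5,
non-compactness invariant under size doubling) and the scale-invariance on
spheres.

**Histogram (13).** Mean, skewness, kurtosis, standard deviation, min, max,
and the 1st/5th/25th/50th/75th/95th/99th percentiles of the z-scored voxel
values in the tumour mask. Conventions: moment-based (type 1) skewness
\(g_1 = m_3/m_2^{3/2}\) and *excess* (Fisher) kurtosis \(g_2 = m_4/m_2^2-3\)
— excess kurtosis is the only definition under which negative values, which
the cohorts produce for flat-topped distributions, are possible; sample
standard deviation; percentiles by linear interpolation between order
statistics (R type 7). Zero-variance input defines skewness and kurtosis as
0. These features depend only on the multiset of masked values (tested as a
permutation invariance).

**Texture (12).** Grey-level co-occurrence matrices are built at distance
1 voxel along the 13 unique 3D directions (half of the 26-neighbourhood up
to sign), counting only voxel pairs with *both* endpoints inside the mask
and accumulating symmetrically; each matrix is normalised to a joint
probability \(P(i,j)\). Values are first quantized to \(N_g = 32\)
equal-width bins spanning the per-tumour \([\min, \max]\) range (a
conventional radiomics default, configurable; a constant region maps to a
single bin and yields the degenerate texture ASM = 1, entropies 0). From
each direction's matrix the 12 statistics are computed — angular second
moment, contrast, correlation, sum of squares (variance), sum average,
inverse difference moment, sum entropy, entropy, difference variance, sum
variance, difference entropy, and the first information measure of
correlation (IMC1) — and each statistic is averaged arithmetically over the
non-empty directions. Averaging *features*, not matrices, makes the result
exactly invariant under 90° grid rotations (tested to 1e-9).

Numerical conventions, each of which the dual-route oracle tests pin down:
grey levels are 0-based (\(0..N_g-1\)) in every formula; logarithms are base
2 with \(0\log 0 := 0\); correlation with a zero marginal variance is 0; sum
variance is the variance of the level-sum distribution about the sum
average (the standard repair of the original formula's circular reference);
difference variance is the variance of the \(|i-j|\) distribution;
\(\mathrm{IMC1} = (H_{XY} - H_{XY1})/\max(H_X, H_Y)\) with \(0/0 := 0\).
Every statistic is verified against an independent, deliberately naive
double-loop transcription of the defining formulas on ≥100 random small
masks at tolerance 1e-10.

## Synthetic cohort generator

The generator is first-class, tested code, not a fixture. It emulates the
statistical structure the downstream analysis assumes:

- **Tumour masks** are digitized ellipsoids (semi-axes drawn from a
  per-class range, default 8–12 mm) perturbed by adding
  `irregularity × 0.35 ×` a unit-variance Gaussian-smoothed random field
  (correlation length 2 mm) to the implicit function, then clipped to the
  designated hemisphere and reduced to the largest 6-connected component.
  At irregularity 0 the mask is exactly the digitized ellipsoid; SAV and
  non-compactness grow monotonically along an irregularity sweep at fixed
  noise (tested).
- **rCBV volumes**: background noise everywhere, reference voxels
  \(\sim \mathcal N(\mu_{\mathrm{ref}}=1, \sigma_{\mathrm{ref}}=0.5)\), and
  tumour voxels \(\mu_c + \delta_{\mathrm{centre}} +
  g_\lambda(h\,\varepsilon + \sigma_{\mathrm{corr}} G)\) where
  \(\varepsilon\) is i.i.d. Gaussian, \(G\) a unit-variance field with
  Gaussian correlation length `corlen_vox`, and
  \(g_\lambda(x) = (e^{\lambda x}-1)/\lambda\) a monotone skewing transform
  (\(g_0 = \mathrm{id}\)). The heterogeneity parameter \(h\) controls
  voxel-wise disorder: joint co-occurrence probabilities spread as \(h\)
  grows, so realized GLCM entropy increases with it, whereas a longer
  correlation length concentrates mass near the diagonal and raises the
  GLCM correlation feature (both tested as paired comparisons over seeds).
  This is why heterogeneity acts on the unstructured component: amplifying
  the *correlated* field would lower joint entropy, the opposite of what a
  "heterogeneity" knob must do.
- **Class effects** (defaults in `default_class_effects()`) encode the
  reported direction of group differences: IDH-mutant tumours get lower
  mean rCBV, positive skew (which also raises kurtosis), slightly lower
  heterogeneity, longer correlation length and smoother boundaries; higher
  grades get higher mean, higher heterogeneity and rougher boundaries, with
  grade IV also getting a shorter correlation length. Only signs/directions
  are targeted — the source analysis reports medians of covariate-corrected
  features from data that are not available, so there are no quantitative
  effect sizes to calibrate against.
- **Centres** supply an additive intensity offset and a realistic scanner
  profile (manufacturer, field strength, TR, TE, FA, slice thickness,
  matrix, in-plane resolution) chosen so the standard dichotomization bins
  are populated on both sides. The default cohort mixes 6 class cells so
  that grade II is mostly IDH-mutant and grade IV mostly wildtype, with
  grade and mutant marginals near 30/22/48% and 46%, and ages drawn older
  for higher grades.
- **Reproducibility**: class cells are apportioned by largest remainder;
  each subject draws from an RNG stream whose seed is derived
  arithmetically from the master seed and the subject index, so a subject's
  volume does not depend on cohort size, and a fixed configuration
  reproduces volumes and manifest bit-for-bit (tested).

What the generator does *not* emulate: brain anatomy, raw DSC time series
and contrast kinetics, arterial input functions, leakage, registration
error, or segmentation noise. Tests passing on this generator therefore
demonstrate the *computational* correctness and statistical calibration of
the pipeline, not clinical performance on real data: the synthetic classes
are cleaner and better separated than patient cohorts, so classification
accuracies on synthetic cohorts are far higher than anything achievable on
real multi-centre data and must not be read as such.

## Group statistics

Features are corrected for acquisition effects by ordinary least-squares
residualization on: the dichotomized acquisition covariates (field strength
1.5/3 T; TR ≤1499 / ≥1500 ms; TE 25–44 / 45–55 ms; FA 90 / <90°; slice
thickness <5 / ≥5 mm; matrix <128 / ≥128; in-plane ≤1 / (1,2) / ≥2 mm) as
indicator terms, manufacturer and centre as factors, age continuous, and
sex. Least squares is the simplest model honouring "corrected for"; the
residuals have mean zero by construction and the operation is idempotent
(both tested to 1e-9). Constant covariates are dropped with a warning;
aliased columns are handled by the rank-revealing QR inside the fit. Shape
features are corrected too by default (`correct_shape = FALSE` exempts
them — the alternative reading in which only intensity-based features are
corrected).

Group comparison uses the two-sample Wilcoxon rank-sum test, two-sided:
exact null distribution when the pooled sample has ≤12 untied values,
otherwise the normal approximation with mid-ranks and tie correction; two
samples sharing one common value give p = 1. No multiple-testing adjustment
is applied — significance is flagged at unadjusted p ≤ 0.05, matching the
analysis pattern this package reproduces, and the type-I consequences are
quantified instead of adjusted away: under the null generator the fraction
of features reaching p ≤ 0.05 is verified to sit at the nominal level
(0.05 ± 0.01 over 200 small cohorts).

Effect sizes are Cliff's delta,
\(\delta = (\#\{a_i > b_j\} - \#\{a_i < b_j\})/(n_a n_b)\), computed via a
rank identity in \(O(n\log n)\) and verified against exhaustive pair
counting; positive delta means the first group is stochastically larger,
and group order is fixed as wildtype-vs-mutant and lower-vs-higher grade.

## Classification

Both tasks use probability random forests (`ranger`) with the published
tuned settings as fixed defaults — IDH (binary): 200 trees, maximum depth
10, minimum 4 samples per leaf; grade (3-class): 800 trees, depth 50, leaf
4 — under stratified 2-fold cross-validation repeated 250 times. Per
repeat, each class is dealt to folds cyclically after shuffling, so fold
class counts differ by at most one; each subject is predicted exactly once
per repeat. Radiomic features plus the one-hot-coded dichotomized
acquisition covariates, age and sex are the classifier inputs. Per-repeat
and per-fold RNG seeds derive from the master seed, making the whole CV
result reproducible.

The consensus label of a subject is the class with the highest mean vote
proportion across repeats, ties resolved toward the lower ordinal class
(the "average classification" rule, isolated in `consensus_confusion()`).
From the consensus-vs-truth confusion matrix the package reports accuracy;
for the binary task sensitivity and specificity with IDH-mutant fixed as
the positive class; for the grade task the fraction of subjects within one
grade of the truth, using the inclusive reading |predicted − true| ≤ 1 on
the ordinal encoding II/III/IV → 2/3/4 (the strict variant is a one-line
change on the reported distances). The classifier itself is nominal
3-class; the ordinal encoding is used only for the error metric.

Prediction error (predicted − true, per repeat) is summarised per subject
and compared between the bins of each dichotomized acquisition parameter
with Welch's two-sample t-test, on both signed and absolute error.
Hyperparameter search is deliberately absent: the published values are
treated as part of the method.

## Misclassification introspection

For each error category (truth \(a\), consensus prediction \(b\ne a\)) with
at least 2 members, features — standardized to cohort-wide z-scores — are
contrasted against the correctly classified subjects of the *true* class
\(a\) (mean z difference plus rank-sum p). The reference-group definition
is ambiguous in principle, so the alternative (correct subjects of the
*predicted* class) is selectable via `reference = "predicted"`; the default
was chosen because "how do the errors differ from the cases that were
gotten right" reads most naturally against the same true class.
Undersized categories are skipped with a warning; a run with no
misclassifications returns an empty table, which is success, not an error.

## Problem sizes and runtime

The test and acceptance suites run on deliberately desk-scale problems: a
64³ / 1 mm grid for single-subject and default-cohort checks, 32³ grids
with 4.5–6 mm tumours for the replicated statistical suites (200 null
cohorts of 40 for calibration, 20 cohorts of 80 for effect-sign recovery,
one cohort of 120 for classification sanity), and 50 of the 250 CV repeats
in the test suite (the acceptance script runs the full 250). These sizes
were chosen so the complete suite runs in minutes on one CPU while keeping
every statistical assertion adequately powered; all thresholds were fixed
together with these sizes.

## Known limitations

- The surface estimator's staircase bias (above) makes non-compactness
  comparable *between* masks on the same grid, not against continuum
  values.
- The IMC1 sign convention differs between software implementations; the
  one used here is declared above and pinned by the oracle tests, but
  cannot be cross-checked against the source analysis.
- Quantization to a per-tumour [min, max] range makes texture features
  invariant to affine intensity changes but sensitive to single extreme
  voxels; this mirrors common radiomics practice and is left as-is.
- The generator targets directions of group differences, not magnitudes;
  nothing in the package should be read as reproducing patient-data
  accuracy figures.
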