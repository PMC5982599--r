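---
title: "Dual-modality multispectral lesion analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-modality multispectral lesion analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melspect)
```

## The problem and the pipeline

Melanomas and benign nevi differ in how much light they reflect and in how
heterogeneous that reflectance is across the lesion. `melspect` implements
an analysis chain for two co-registered multispectral camera systems — a
12-bit silicon CCD imaging eight LED bands between 414 and 995 nm
(VIS-NIR, 1280x960 px) and a 16-bit InGaAs camera imaging six bands
between 995 and 1613 nm (exNIR, 320x256 px) — that turns raw
digital-level (DL) stacks into a melanoma/nevus call:

1. **Calibration**: raw DLs to reflectance against a gray reference.
2. **Segmentation**: quadrant-wise Otsu thresholding at 414 nm, mask
   transfer to the exNIR grid.
3. **Descriptors**: seven first-order histogram statistics per band and
   image variant (392 descriptors in total).
4. **Selection**: greedy accumulation of per-descriptor interval rules.
5. **Classification**: z-scoring, PCA by SVD, and a maximum-margin SVM on
   a principal-component pair, reported as sensitivity/specificity.

Because no public image archive exists for this kind of paired
acquisition, the package also ships a phantom generator
(`generate_phantom()`, `generate_cohort()`) that simulates the full
acquisition, so that every downstream stage is exercised end to end by
the test suite.

## Calibration model

For each band the reflectance at pixel $(i,j)$ is

$$R(i,j) = k\,\frac{I(i,j) - I_D(i,j)}{I_N(i,j) - I_D(i,j)},$$

where $I$ is the raw capture, $I_N$ and $I_D$ the gray-reference and
dark-current images acquired at the same exposure time, and $k$ the
calibrated reflectance of the reference tile ($k = 0.20$ by default; it
is a manufacturer property of the tile, configurable and optionally
per-band). Calibration stacks exist at ten exposure times; acquisition
targets a mean DL of half the dynamic range, and `select_exposure()`
reproduces that rule (ties go to the shorter exposure). Pixels whose
reference signal $I_N - I_D$ is not positive, or whose reference is at
full scale (saturated), are flagged invalid rather than propagated.

Four image variants feed the descriptor stage:

* `R` — reflectance as above;
* `R_minus_skin` — $R$ minus the mean of $R$ over a healthy-skin region,
  restricted to the lesion;
* `A` — absorbance $-\log_{10} R$ (the sign is chosen so absorbance
  increases as reflectance falls, the usual optics convention; values
  below $\varepsilon = 10^{-4}$ are clamped before the logarithm and the
  clamp count is recorded);
* `A_minus_skin` — by default $A - \operatorname{mean}(A\ \text{over
  skin})$, i.e. the skin subtraction happens **after** the logarithm.

The ordering in `A_minus_skin` was a genuinely open choice: taking the
logarithm of the reflectance *difference* is undefined wherever the
lesion is brighter than the average skin (the difference is negative,
which happens routinely). Subtracting mean log-reflectance keeps the
operation defined everywhere and preserves the "remove the patient's
baseline" intent; the other ordering remains available via
`make_variants(..., absorbance_order = "subtract_first")`, which clamps
negative differences.

The healthy-skin region is the complement of the lesion mask dilated by
5 px (scaled by the grid ratio on the exNIR side), keeping a guard band
around the uncertain lesion boundary out of the skin average.

## The phantom generator

`generate_phantom()` simulates the exact inverse of the calibration
equation: a pixel with true reflectance $R$ is recorded as
$\mathrm{DL} = \operatorname{clip}(\operatorname{round}(I_D + (R/k)(I_N -
I_D) + \text{noise}))$, with the reference signal proportional to
exposure time and calibration stacks generated at all ten exposures. The
raw capture uses the exposure whose predicted mean DL is closest to half
scale among exposures where the reference itself is not saturated. With
noise off, calibrating a phantom recovers the configured reflectance to
within one DL quantum — the round-trip identity the test suite asserts.

The scene is healthy skin plus one elliptical lesion. Default spectra
were chosen once to reproduce the qualitative clinical contrast: both
lesion classes darker than skin in the visible (melanin), nevi brighter
than melanomas at every band, and the largest nevus-melanoma gap inside
the 995-1350 nm water-transparency window (0.135 reflectance units at
1081-1214 nm, against VIS gaps of 0.02-0.09). All tissues darken sharply
beyond 1400 nm, where water absorbs.

Within-lesion texture is a smoothed Gaussian random field (correlation
length 3% of image height) added multiplicatively to the class spectrum.
Nevi keep the Gaussian marginal at small amplitude (relative SD 0.04);
melanomas use the same spatially correlated field rank-mapped to a
uniform marginal at larger amplitude (relative SD 0.10). The uniform
marginal makes the in-lesion histogram broad relative to its range,
which is what drives the malignant texture signature downstream: lower
histogram energy and higher Shannon entropy. No published quantitative
texture statistics exist for these systems, so realism is limited to
that qualitative contrast.

Modality misregistration is a similarity transform (default: 3 degrees
rotation, scale equal to the grid ratio 0.25, ~1 px translation),
applied analytically to the lesion ellipse so the exNIR truth mask is
exact rather than resampled. Sensor noise is Gaussian read noise (SD 2
DL on the 12-bit CCD, 40 DL on the 16-bit InGaAs, which is the noisier
technology) plus an optional Poisson shot-noise term, off by default.

Cohorts add per-lesion uniform jitter: a global scale on the lesion
spectrum (±18%, the dominant within-class variance source), ±6% on skin,
shape centre ±0.05, axes ±25%, free orientation, texture amplitude ±20%
and small misregistration perturbations. The ±18% profile jitter sets
the planted between-class gap at the informative bands to roughly three
within-class standard deviations — the regime in which the recovery test
demands ≥90% sensitivity and specificity; collapsing the class spectra
and textures to a common value removes the signal and drops the pipeline
to chance, which the suite also asserts.

What the phantoms deliberately do **not** model: photon transport in
tissue (no Monte-Carlo optics), spectral mixing across LED bandwidths,
LED warm-up drift, vignetting or other flat-field structure beyond the
dark frame, and irregular (non-elliptical) lesion borders. Passing the
recovery tests therefore shows the chain is correct and sensitive to the
planted contrast at realistic noise levels — not that the planted
contrast magnitudes match clinical cohorts.

## Segmentation

Lesions absorb strongly at 414 nm (melanin), so that band carries the
best contrast and is the segmentation input. To tolerate uneven skin,
the image is split into four equal quadrants (odd dimensions give the
extra row/column to the bottom/right), each thresholded independently by
Otsu's criterion over a 256-bin histogram; pixels **below** their
quadrant's threshold become lesion. Ties in the between-class variance
go to the lower threshold; a constant quadrant contributes
all-background instead of erroring.

Reassembling four independent thresholds can leave speckle, so the mask
keeps only the largest 8-connected component and fills holes; both steps
are toggles, and the suite checks the full pipeline against a
brute-force per-quadrant exhaustive-search twin pixel for pixel. When
the lesion straddles quadrant borders, conflicting local thresholds are
reconciled by that same largest-component merge — a package choice, as
no canonical merge rule exists.

exNIR masks are obtained by transferring the VIS-NIR mask through the
inter-camera similarity transform with nearest-neighbour resampling
(`transfer_mask()`). In the clinic that transform comes from the shared
positioning ring plus manual tracing; the package takes it from the
phantom ground truth (or user configuration) — automatic
intensity-based registration estimation is out of scope. On default
phantoms the transferred mask agrees with the exNIR truth mask to Dice
≥ 0.95; a transfer-and-back round trip covers the source mask eroded by
the grid ratio (the coarser 4x grid bounds the attainable resampling
accuracy).

## First-order descriptors

For every (system, band, variant) image, seven statistics are computed
over the in-mask pixels: mean, maximum, minimum and population standard
deviation on the raw values, and three histogram functionals on an
N = 256 equal-width histogram spanning the in-mask range (N is not
dictated by the method; 256 matches the 8-bit display convention and is
configurable):

$$E_n = \sum_i P(i)^2, \qquad
  E_p = -\sum_i P(i)^2 \log_2 P(i)^2, \qquad
  \mu_3 = \sum_i (i - \mu)^3 P(i)^2,$$

with $P(i)$ the relative frequency of bin $i$ and $\mu = \sum_i i\,P(i)$
the index-weighted mean. Two conventions deserve comment:

* The squared frequencies in $E_p$ and $\mu_3$ follow the source
  formulation but are non-standard, and the package also implements the
  textbook forms (`mode = "standard"` Shannon entropy
  $-\sum P \log_2 P$, and `mode = "normalized"` skewness
  $\mu_3 / \sigma^3$). Only the standard entropy attains $\log_2 N$ on a
  uniform histogram, and only the normalized skewness is confined near
  $[-1, 1]$. More importantly, the squared-frequency entropy is **not**
  a disorder measure: because small $P$ contribute $O(P^2)$, it
  *decreases* as the histogram broadens, tracking energy rather than
  opposing it. The class contrast "melanomas are less uniform, with
  higher disorder" therefore manifests as lower energy *and lower
  as-printed entropy but higher standard entropy*; the texture-contrast
  test asserts the standard mode for exactly this reason. Both modes are
  computed into the descriptor table via configuration; the default
  remains `"as_printed"` for fidelity to the source formulation.
* $\mu$ and $\sigma$ inside $\mu_3$ live on bin indices, not pixel
  values — the two cannot be the same object, since the formula is
  dimensionless in intensity. Mean/max/min/std are computed on raw
  values for precision rather than on bin centres.

Energy, entropy and $\mu_3$ are invariant under positive affine
intensity maps (the equal-width binning of the mapped range reproduces
the same bin occupancies), mean/max/min map affinely and std scales by
the gain — properties the suite checks, alongside agreement with naive
loop oracles to 1e-10.

With 8 VIS-NIR bands, 6 exNIR bands, 4 variants and 7 statistics the
descriptor table has exactly $8\cdot4\cdot7 + 6\cdot4\cdot7 = 224 + 168
= 392$ columns, ordered system, band, variant, statistic.

## Threshold rules and greedy selection

A rule is a closed benign interval $[\text{lower}, \text{upper}]$ on one
descriptor; a lesion is flagged malignant when any selected rule's value
falls strictly outside (boundary values are benign). Rules are ranked by
how many true melanomas they flag (ties keep column order), then
accumulated greedily in one pass: a rule is kept only if it flags at
least one melanoma not already flagged, so the per-step cumulative
sensitivity is strictly increasing. The suite checks this against an
independent forward-search oracle.

The shipped default rule set (`default_rules()`) carries eight intervals
set by eye on clinical scatter plots of a 53-lesion pilot cohort — they
are supplied constants, not fitted by the package. One of them (the
reflectance-skewness rule) is attached to the 671 nm band; its published
wavelength label is inconsistent, and 671 nm is the only matching LED in
the set. On synthetic cohorts those clinical intervals mostly flag
everything (the synthetic absorbance scale differs), so
`fit_rules()` can re-derive intervals from the cohort's nevus quantiles
under a false-positive budget — a clearly-labelled calibration aid, not
part of the reference procedure. Note the method applies no
multiple-testing control over the 392 candidate scatter plots; with 39
nevi per plot, intervals that exclude all nevi by chance are common, so
fitted rules should be read as descriptive, not inferential.

## PCA and the SVM boundary

The descriptors named by the rule set (eight by default) form a
$d \times n$ matrix, z-scored per descriptor with the **population**
standard deviation (the $1/n$ convention; with $n = 53$ the difference
from $1/(n-1)$ is below 1%, but the choice is fixed for
reproducibility). The full SVD $Y = U D V^t$ yields principal-component
scores $\mathrm{PC}_k = D_{kk} V_{\cdot k}$ and explained-variance
fractions $D_{kk}^2 / \sum_j D_{jj}^2$. Each $U$ column is oriented so
its largest-magnitude entry is positive (the paired $V$ column flips
with it), making score plots reproducible across platforms.

A soft-margin SVM (penalty $C = 1$ by default) is trained on each
candidate PC pair — (1,2), (1,3), (2,3) — and the pair with the best
balanced accuracy wins (ties: higher sensitivity, then enumeration
order). The kernel is linear by default, matching the maximum-margin
hyperplane formulation; an RBF kernel is available by configuration.
SVMs are trained on raw PC scores (not re-standardized ones), since the
singular values already encode the variance ordering that the PCA step
is meant to expose.

Evaluation is by resubstitution — train and test on the same cohort —
which mirrors the pilot-study setting of a cohort large enough to train
but not to hold lesions out; resubstitution estimates are optimistic,
and `evaluate_cv()` provides stratified k-fold cross-validation as the
honest alternative. Sensitivity is the true-positive rate over melanomas
and specificity the true-negative rate over nevi; percentages are
reported to one decimal.

## Problem sizes and numerical choices

The cohort analyses and the recovery test run the generator at 1/8 of
the native grids (160x120 and 40x32 px) with the full 39 + 14 cohort;
segmentation quality is assessed at 1/4 scale (320x240 and 80x64 px)
over 20 jittered phantoms. These sizes keep a full pipeline run around
half a minute while leaving hundreds of in-mask pixels per lesion at the
coarsest grid; native-resolution runs use the same code paths.

Numerical conventions collected in one place: pixel coordinates are
0-based, row-major, origin top-left; histogram maxima fall in the last
bin and constant inputs occupy a single bin; $0 \log 0 = 0$; Otsu ties
resolve to the lower threshold, exposure ties to the shorter time, PC
pair ties to the enumeration order; absorbance clamps at
$\varepsilon = 10^{-4}$; reflectance pixels with non-positive or
saturated reference are invalid (NA) rather than infinite; constant
descriptor columns abort standardization with the offending descriptor
named; an empty transferred mask and an all-saturated exposure ladder
are errors, while a constant Otsu quadrant is not.

## Known limitations

* Phantom realism is qualitative; absolute descriptor scales (notably
  absorbance SDs) differ from clinical cohorts, which is why the shipped
  clinical intervals saturate on synthetic data.
* The exNIR mask is only as good as the supplied transform; there is no
  data-driven registration fallback.
* Resubstitution headline figures are optimistic by construction.
* The greedy selector optimizes sensitivity only, mirroring the
  reference procedure; specificity enters only through the manually (or
  quantile-) set intervals.
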