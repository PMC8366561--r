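---
title: "Filtration-histogram texture analysis and its prognostic screen: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filtration-histogram texture analysis and its prognostic screen: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(texhist)
```

## The procedure

texhist quantifies tumor heterogeneity on single 2-D lesion slices — CT in
Hounsfield units and PET in SUV — and screens the resulting markers against
survival. The chain is:

1. **Filtration.** The whole CT slice is convolved with a
   Laplacian-of-Gaussian (LoG) band-pass kernel at spatial scale filter
   (SSF) values of 2 mm (fine), 3, 4 and 5 mm (medium, three separate
   maps) and 6 mm (coarse), plus the unfiltered slice as a control. PET is
   analyzed unfiltered only: at a typical 4 mm pixel pitch the 2–6 mm
   band-pass scales are unresolvable (the kernel builder refuses a sigma
   below 0.4 pixel), which mirrors how low PET resolution is handled in
   practice.
2. **Quantification.** Each map is summarized over the ROI by six
   first-order statistics — mean, SD, entropy, mean of positive pixels
   (MPP), skewness, kurtosis — giving 36 CT and 6 PET texture features,
   alongside SUVmax, SUVmean and the uptake area in pixels.
3. **Aggregation.** Within a patient, lesions are ranked by their in-mask
   PET maximum and up to the five most avid contribute; each feature is
   averaged over lesions where it is non-missing.
4. **Screening.** Every marker is dichotomized at the cohort median,
   groups are compared with Kaplan-Meier estimates and a log-rank test,
   p-values are Benjamini-Hochberg corrected per endpoint at FDR
   q = 0.30, and the survivors enter stepwise forward-Wald Cox selection.

Masks and images share one grid per modality and no CT-to-PET resampling
is performed: features are computed on each modality's native grid, since
ROIs are delineated per modality on corresponding slices and inventing a
registration step would add an uncontrolled degree of freedom. Image
interchange is NIfTI-1 (integer CT round-trips bit-exactly as int16; masks
are uint8 labelmaps); the cohort manifest is a plain CSV.

## The LoG kernel

The kernel is the negated, scale-normalized LoG sampled on the pixel grid:

$$K_\sigma = -\,\sigma_x \sigma_y\, \nabla^2 G_\sigma, \qquad
\sigma_{\text{mm}} = \texttt{sigma\_ratio} \times \text{SSF}, \quad
\sigma_{x,y} = \sigma_{\text{mm}} / \text{spacing}_{x,y}.$$

Three choices deserve justification:

* **Sigma mapping** (`sigma_ratio`, default 1/2). The proprietary software
  that popularized this technique does not publish its SSF-to-sigma
  constant. With the scale-normalized kernel, a Gaussian object of
  diameter $2\sigma_{\text{obj}}$ produces its maximal center response at
  the scale with $\sigma = \sigma_{\text{obj}}$, so `sigma_ratio = 1/2`
  makes an object of diameter ≈ SSF respond at peak — the natural reading
  of "fine/medium/coarse object size". Absolute feature values depend on
  this constant; the rank ordering of lesions (all the survival analysis
  uses) is far less sensitive. The ratio is exposed in `filter_config()`.
* **Scale normalization.** Without the $\sigma^2$ factor the LoG center
  response to any blob decreases monotonically with scale and "coarse"
  maps would simply be attenuated fine maps; with it, the filter bank is a
  true band-pass family (the test suite verifies that a blob of diameter
  $d$ mm peaks at the SSF nearest $d$ for $d = 2, \dots, 6$).
* **DC removal.** After truncation at 4 sigma per axis the kernel is
  shifted by its mean so it sums exactly to zero. Filtration therefore
  annihilates constant images and is invariant to intensity offsets —
  filtered-map statistics do not depend on the CT calibration baseline.

Convolution is exact linear convolution via FFT on a reflect-padded field
(pad width = kernel radius, so circular wrap-around never touches real
data); constant padding is available for phantoms with a known background.
Responses smaller than 64 machine epsilons times the operator norm are
snapped to zero, so a constant input yields an identically zero map rather
than FFT roundoff noise — this matters because entropy of pure roundoff
noise would be arbitrary.

## Histogram statistics

All moments are population (1/n) moments, the classical texture-analysis
convention; no small-sample bias correction is applied. Entropy uses 64
equal-width bins spanning the observed [min, max] of the ROI values, in
bits. The bin count is not standardized anywhere in the field; 64 is wide
enough that typical ROIs (hundreds to ~1300 pixels here) do not saturate,
and the analysis only consumes the cross-patient ordering. Entropy is
invariant under increasing affine rescalings (bin occupancies are
preserved), so CT calibration and PET SUV scaling do not affect it.
Kurtosis is reported as excess (normal → 0) by default — consistent with
coarse-CT kurtosis cut-offs near zero reported in the clinical literature
— with the Pearson convention selectable. Degenerate cases are explicit,
never silent: a constant input has entropy 0 and missing (NA) skewness and
kurtosis; MPP is missing when no value is strictly positive. On unfiltered
CT/PET, where all ROI values are typically positive, MPP degenerates to
the mean; it is computed anyway so the feature vector always has exactly
36 + 6 + 3 entries.

CT pixels below −50 HU (air, gas) are excluded. Eligibility is decided
once on the *unfiltered* HU and the same pixel set is reused on every
filtered map, so all six scales summarize the same tissue. Whether the
exclusion should instead be applied before filtration is unknowable from
published descriptions; applying it at the statistics stage keeps the
convolution translation-invariant, and the point is exposed for
sensitivity analysis simply by masking the image before filtering.

## Survival screen

* **Median dichotomization**: threshold = sample median; values strictly
  above go to the "above" group, ties go below. Markers whose non-missing
  values are all equal cannot be split and are skipped with a log entry.
* **Kaplan-Meier median**: the smallest event time with $S(t) \le 0.5$,
  reported as "not reached" when the curve never falls that far.
* **Poor-prognosis direction**: the side of the cut-off with the shorter
  median survival ("not reached" counts as longer; exact ties are broken
  by the smaller restricted mean). This reproduces the direction-of-effect
  column of the usual univariate summary tables.
* **BH family**: one family per endpoint, spanning whatever marker list
  the caller screens (by default all 45 features plus clinical
  covariates). Published applications of this workflow do not enumerate
  their exact tested family — indeed their corrected p-values are not
  always consistent with a single textbook BH pass — so the family is an
  explicit argument rather than a hidden constant. `bh_adjust()` itself is
  the textbook step-up procedure: adjusted p ≥ raw p, always.
* **Cox selection**: pure forward selection on the Wald statistic
  (largest qualifying statistic enters; entry p < 0.05; no removal step),
  with Breslow tie handling by default (Efron selectable). Candidates
  enter as median-dichotomized binaries, which is what makes the
  resulting hazard ratios directly comparable to median-split KM tables.
  An exactly collinear candidate produces a singular conditional fit
  (reported NA, never entered), and monotone-likelihood fits trigger a
  diverging-coefficient warning.

KM, log-rank and Cox numerics are delegated to the survival package; the
test suite validates them against hand-computed product-limit and
observed/expected tables and an independent 1-D partial-likelihood grid
scan, so the wrappers' conventions (medians, tie rules, CI = exp(coef ±
1.96 SE)) are pinned by tests rather than assumed.

## The synthetic generator: what it does and does not emulate

`phantom_spec()` renders a lesion as an elliptical ROI (default semi-axes
18 × 14 mm) on a 64 × 64 CT grid at 0.98 × 0.98 mm — the in-plane
resolution typical of low-dose PET-CT — with a soft-tissue background of
40 HU and additive Gaussian noise (SD 8 HU). A per-patient latent
heterogeneity variable $z \sim N(0,1)$ drives texture: the number of
Gaussian blobs is Poisson with mean interpolating 2 → 14 as $\Phi(z)$ goes
0 → 1, and blob amplitudes are signed normal with scale
$60 \cdot (0.25 + 0.75\,\Phi(z))$ HU, diameters uniform on 2–8 mm. With
probability 0.15 a lesion contains 1–3 air pockets at −1000 HU, exercising
the −50 HU exclusion. The PET lesion is a smoothed hot disc (radius 12 mm,
lognormal avidity around SUV 8) on a 32 × 32 grid at 4 × 4 mm with
z-scaled internal texture — deliberately coarser than CT, honoring the low
intrinsic resolution that motivates unfiltered PET analysis.

By construction, SD at all scales, coarse-scale kurtosis and PET entropy
increase with $z$ (verified by Monte-Carlo contrast through the real
extractor). One instructive non-monotonicity: *unfiltered CT entropy can
decrease with $z$*, because extreme blob amplitudes stretch the
equal-width bin range so the background concentrates into fewer bins.
This is a real property of range-normalized histogram entropy, not a
generator artifact, and it is why the end-to-end tests anchor on
statistics whose direction is construction-guaranteed.

`cohort_spec()` simulates survival from a constant-baseline (exponential)
hazard $h(t) = \lambda \exp(\beta z_{\text{std}})$, with $z$ standardized
across the cohort so $\beta$ is the log hazard ratio per SD of
heterogeneity. Defaults mirror a 44-patient metastatic NET cohort:
baseline median PFS 22 months ($\lambda_{PFS} = \log 2 / 22$), baseline
median OS 37 months, administrative censoring at the 82-month follow-up
horizon plus independent uniform dropout on (0, 164) months, true PFS
capped at true OS, and 1–7 lesions per patient all sharing the patient's
$z$. A Weibull baseline was considered and rejected: the exponential keeps
every analytic check (median, censoring fraction, HR recovery)
closed-form.

What the generator does **not** emulate: PET reconstruction physics and
partial-volume effects, anatomical context, inter-observer ROI
variability, and correlation between lesion count and hazard. Passing the
end-to-end tests therefore demonstrates that the *pipeline* recovers a
heterogeneity signal it is fed — not that any particular statistic is
prognostic in real patients.

## Problem sizes and numerical settings

The shipped tests run the statistic-vs-oracle comparison on 1,000 random
pixel sets (tolerance 1e-10 relative), the log-rank null calibration at
n = 50/arm over 2,000 replicates, Cox recovery at true HR 2.5 with
n = 500 and ~30% censoring over 200 replicates, and the end-to-end
recovery on a 300-patient cohort with $\beta_{OS} = \log 2.5$. The null
calibration of the full screen re-draws outcomes independently of a fixed
150-patient feature table over 40 replicate screens — a single null cohort
cannot measure a rate — and checks the family discovery fraction against
the FDR-level bound with binomial slack. Cox fitting uses the survival
package's Newton iterations at eps 1e-9, max 50 iterations; the forward
selection trace records every candidate's conditional Wald statistic at
every step for auditability.

## Known limitations

* Single-slice 2-D analysis only; volumetric texture and shape features
  are out of scope.
* DICOM input is not parsed; convert to NIfTI-1 upstream.
* The SSF-to-sigma constant of the reference commercial implementation is
  unpublished, so absolute feature values are not comparable to its
  output — orderings and the downstream survival analysis are the
  portable quantities.
* The screen treats markers marginally; correlated features (e.g. SD at
  adjacent scales) enter the BH family as-is, which is conservative for
  discovery counting but means "number of significant markers" should not
  be read as independent signals.
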