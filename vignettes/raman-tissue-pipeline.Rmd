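---
title: "From raw frames to tissue calls: the methods behind neuroraman"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw frames to tissue calls: the methods behind neuroraman}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A fiber-optic Raman probe inserted through the nasal corridor returns, for
each contact measurement, a stack of CCD accumulation frames plus a dark
frame. The analysis task is to turn those counts into a normalized spectral
fingerprint on the 800–1800 cm⁻¹ fingerprint window and to decide which
anatomical structure was probed — most critically to separate pituitary gland
from the sella turcica bone and dura that surround it. This vignette explains
the models and procedures the package implements, the assumptions behind
them, and the choices made where the method descriptions left the design
open.

## Signal model and preprocessing chain

A raw frame is modelled as

> counts = dark + autofluorescence baseline + Raman bands + noise + sporadic
> cosmic-ray spikes,

with the baseline a smooth curve one to two orders of magnitude broader than
any Raman band, and noise approximately shot-like (sd proportional to the
square root of the expected counts). The chain in `preprocess()` inverts this
model stage by stage, in a fixed order (dark subtraction, despiking, axis
calibration, response correction, accumulation averaging, baseline removal,
smoothing, truncation, SNV). The order is part of the contract:
`preprocess_params(stage_order = ...)` refuses any permutation, and the chain
is invariant to the ordering of the accumulation frames because averaging and
per-pixel medians are symmetric in the frames.

**Cosmic-ray removal.** The protocol acquires 10 accumulations per record, so
a spike confined to one frame is an extreme outlier at its pixel across
frames. For each pixel we compute the across-frame median and MAD and replace
values exceeding the median by more than 8 MAD (default,
`despike_threshold`). Under Gaussian noise this touches far less than 0.1% of
clean pixels, while a single-frame spike of any realistic amplitude is
removed exactly. A documented blind spot: a spike present at the same pixel
in half or more of the frames moves the median itself and survives. A
single-spectrum fallback (running-median despiker) covers inputs with one
frame.

**Axis calibration and response correction.** Pixel-to-wavenumber mapping is
a least-squares polynomial (degree 2 by default) through the detected
acetaminophen reference peaks; the fit must be strictly increasing over the
pixel range or a calibration error is raised, and at least degree + 1
reference peaks are required. The relative response curve measured on an
intensity standard is rescaled to unit mean before division, so response
correction changes spectral shape but never overall scale — a flat response
of any level is an exact identity.

**Rolling-bubble baseline.** The autofluorescence background is estimated as
the upper envelope of circular arcs ("bubbles") grown from below the
spectrum, in a coordinate system where the intensity range is rescaled to the
bin range so that "circle" is meaningful. On each interval the spanning arc
(a half-bubble with its apex at the boundary when the interval touches a
spectrum edge) is lifted until it first touches the spectrum; the touch point
splits the interval and recursion continues on sub-intervals at least
`bubble_min_width` (50 cm⁻¹) wide. Three numerical refinements matter in
practice and are part of the implementation:

* the endpoint chord (tilt) is removed before growing bubbles and re-added
  afterwards, so a pure straight-line input returns an identically zero
  Raman signal;
* a touch at an interval endpoint cannot split the interval; the interval is
  re-queued shrunk by one bin, which lets the envelope climb structure wider
  than the bubble floor (a 300 cm⁻¹-wide hump is > 99% absorbed into the
  baseline; without this rule almost none of it is);
* between adjacent contact points closer than the bubble floor no bubble can
  be grown, and the convex arc would bulge above the straight chord; the
  envelope is therefore capped by the chord there — the minimal admissible
  featureless bridge.

The estimator guarantees baseline ≤ spectrum everywhere (so the Raman
remainder is non-negative), contains no feature narrower than the bubble
floor, and is exactly scale-equivariant. Its accuracy limits are worth
stating. Away from peaks the envelope tracks a smooth baseline to a few
tenths of a percent (RMS). Under a peak the envelope can only bridge between
the nearest contact points, which for a pseudo-Voigt band (50% Lorentzian,
FWHM 15 cm⁻¹) sit on tails that are ~2–4% of the peak height at ±25–35 cm⁻¹;
recovered peak heights are therefore biased low by ~4–4.5%, a floor set by
the line shape and the 50 cm⁻¹ bubble width, not by the implementation.
Likewise the envelope of a *noisy* signal rides the local noise minima, so
the baseline is biased low by a noise-dependent offset; this is inherent to
all under-envelope baseline estimators. Re-applying the estimator to its own
output changes it by well under 1% relative RMS (small arc scallops between
contact points prevent exact idempotence).

**Smoothing, truncation, SNV.** The protocol's Savitzky–Golay setting is
order 3 with window 1 — a window of 1 smooths nothing, and the package
honours that as the default while keeping the window configurable (any odd
window larger than the order). Spectra are truncated to 800–1800 cm⁻¹
inclusive and SNV-normalized. SNV uses the population (1/N) standard
deviation; the convention matters because the quality factor's bounds assume
`sum(r^2) = N`, and it is enforced (to 1e-9) by the `processed_spectrum`
and `raman_set` constructors. A constant spectrum cannot be SNV-normalized
and raises a degenerate-input error.

## Quality factor

`quality_factor()` computes the average signed squared intensity of an SNV
fingerprint. Its algebraic range under the SNV contract is
(−1, (N−2)/N]: the upper bound is attained by a one-hot spike and the
statistic is antisymmetric (QF(−r) = −QF(r)) and permutation-invariant. Pure
noise centres on 0; spectra dominated by a few narrow peaks approach 1.
`gate_quality()` eliminates records with QF below 0.3 (default); the keep
rule at the boundary is *inclusive* (QF ≥ threshold keeps), a choice the
package states and tests because "cutoff" alone does not fix boundary
semantics. The gate is applied after truncation and SNV, since the statistic
is defined on the SNV fingerprint. Under the default synthetic conditions the
gate removes well under 10% of records and never empties a class; an
all-eliminating threshold is a warning, not an error, and the pipeline halts
gracefully before training.

## Spectral angle mapper

`sam()` returns the angle between two spectra viewed as vectors,
`arccos` of the normalized dot product, in degrees. The arccos argument is
clipped to [−1, 1]; because SNV fingerprints have negative entries, record
pairs can exceed 90° and anti-parallel inputs reach 180°. SAM is computed on
SNV-processed spectra throughout (mean fingerprints included); it is
invariant to positive rescaling and symmetric, and `pairwise_sam()` reports
the full matrix with a zero diagonal plus the grand mean of off-diagonal
angles. Mean spectra and per-bin variances use the population (1/N)
convention, matching SNV.

Record-level SAM is a deliberately weak classifier — baseline residuals and
noise rotate spectra without changing band content — and
`within_between_sam()` quantifies that: under low noise every within-tissue
angle sits below every between-tissue angle, while at high noise the
distributions overlap (the `overlap_fraction` output). This motivates the
supervised models below.

## Two-stage classification

The modelling scheme mirrors probe-guidance practice:

1. **Head-disjoint split** (`split_by_head()`): subsets of heads are
   enumerated and the one whose record share falls in [0.33, 0.40] and lies
   closest to the midpoint becomes the hold-out; ties break by a seeded draw
   and no head ever contributes to both sides. If no subset is feasible the
   nearest plan is returned flagged, with a warning. `evaluate_model()`
   re-checks disjointness and raises a hard leakage error on violation.
2. **Peak-region pre-selection** (`peak_mask()`): candidate features are the
   bins within ±25 cm⁻¹ of a band center of any tissue in the task,
   preventing the sparse stage from latching onto noise-only bins.
3. **L1 feature selection** (`select_features_l1()`): a lasso-penalized
   linear classifier (grouped multinomial for more than two classes) is fit
   over a logarithmic penalty grid, 10^3 down to 10^-3 in 25 steps — the grid
   is applied to the lasso penalty directly, the natural parameterization for
   this stage. Each penalty is scored by class-stratified, seeded fivefold CV
   accuracy; the winner is the best-accuracy penalty whose active set has
   between 1 and 19 features, ties resolving toward the stronger penalty
   (sparser set). If no penalty meets the bound, the largest-|coefficient|
   19 features at the best-accuracy penalty are taken, ties toward lower
   wavenumber for determinism. A selection whose CV accuracy is within two
   binomial standard errors of the majority-class rate is flagged
   uninformative.
4. **L2 decision stage** (`fit_l2()`): an L2-regularized linear SVM on the
   selected bins, cost tuned over 10^-3..10^3 by the same stratified seeded
   CV; the validation confusion matrix aggregates out-of-fold predictions at
   the chosen cost. Multi-class tasks use one-vs-rest linear SVMs with an
   argmax decision, keeping the per-class scheme identical to the binary
   case. Inverse-frequency class weights are available but off by default.
   ROC curves for binary tasks use the signed distance to the separating
   hyperplane — the canonical score for a linear SVM — with trapezoid-rule
   AUC.

`raman_svm()` wires these together and returns a classed fit with `print`,
`summary`, `coef`, `predict` and `plot` methods. Only in-situ records enter
training and testing; `transfer_to_methods()` separately scores ex-situ and
in-section gland records with the in-situ-trained model, deliberately
*without* the head-disjointness requirement (the question there is
robustness to the acquisition method, not to new subjects). `run_model_I()`
builds the seven binary tasks — gland versus each of sella bone, sella dura,
optic chiasm, sphenoid bone, white and gray matter, plus gland versus
everything else. No dedicated binary is built against the nasal septum or
mucosa (too few records per the acquisition protocol to support a hold-out),
but both are included in the pooled "rest" class. Per-task seeds are offset
deterministically from the suite seed.

Fivefold CV is stratified by class only, matching the plain reading of the
protocol; fold assignment is seeded, and identical seeds reproduce identical
fits bit for bit.

## The synthetic generator: what it emulates, and what it does not

No instrument data ship with the package, so `generate_raw()` stands in for a
measurement session. What it emulates:

* nine tissue classes whose band centers and graded (1–5) relative
  amplitudes come from the band registry, mapped linearly to counts
  (grade k → k × 200 counts by default; the grades are ordinal, so linearity
  is the least-assumption choice and the unit is configurable);
* pseudo-Voigt bands (50% Lorentzian, FWHM 15 cm⁻¹ — typical condensed-phase
  linewidths, safely below the 50 cm⁻¹ bubble floor);
* a dominant positive autofluorescence baseline (4th-order polynomial plus a
  600 cm⁻¹-wide Gaussian, ~5000 counts against ≤1000-count bands);
* shot-like heteroscedastic noise, dark counts (100), cosmic-ray spikes
  (Poisson, 0.05/frame), and a 16-bit saturation ceiling;
* one multiplicative log-normal effect per (head, band) — sdlog 0.03 — which
  creates the between-subject variation the head-disjoint split is designed
  to expose, and per-record band jitter (sdlog 0.08);
* bone bleed-through in the sella dura: each dura record mixes in a fraction
  of the bone signal, 0.35 on average with per-record sd 0.04, making
  dura/bone the hardest — but still separable — pair, as the anatomy
  (a sub-millimetre membrane over cortical bone) dictates;
* three gland preparation methods: record-level variability (band jitter,
  mixing jitter, effective measurement noise) scales with strictly ordered
  multipliers (1 / 0.6 / 0.3 for in situ / ex situ / in section), and gland
  records mix in surrounding-tissue (dura) signal with method-dependent mean
  fractions 0.15 / 0.06 / 0.01. In-place measurements pick up neighbouring
  structures and residue from the exposure dissection; sectioned glands
  expose clean inner tissue. These two mechanisms jointly produce the total
  variance ordering in situ > ex situ > in section and make the ex-situ and
  in-section mean spectra the most similar pair.

Default session size is 6 heads × 9 tissues × 5 replicates (plus the extra
gland preparations on three heads), ~300 records — the scale of a real
acquisition session. The free parameters above were fixed once, against the
qualitative structure the generator is required to reproduce (dura/bone the
modal confusion, four-class hold-out accuracy ≥ 0.95 in nearly all seeds,
the preparation-method orderings), and are not re-tuned per analysis.

What it does **not** emulate: radiative transport and tissue optics (the
depth-sampling physics), absolute photon counts, wavenumber-dependent
instrument response drift, detector etaloning, autofluorescence
photobleaching over the accumulation stack, or real biochemical variability
beyond band-amplitude jitter. Consequently, passing synthetic-recovery tests
shows the *pipeline* is correct and well-calibrated under its stated model;
it does not certify classifier accuracy on real tissue, where band overlap,
anatomical mislabelling and optical confounds are harsher.

## Numerical conventions and degenerate inputs

* CSV/JSON interchange writes 17 significant digits; a write→read round trip
  reproduces doubles bit-exactly and two writes are byte-identical.
* SNV and all variances use the population (1/N) divisor.
* SAM clips its arccos argument to [−1, 1]; zero vectors are degenerate
  errors, not NaNs.
* Bubble intervals of fewer than two interior bins keep the straight chord;
  constant spectra return a zero Raman remainder.
* All tie-breaks (split candidates, penalty ties, coefficient ties, argmax
  over classes) are deterministic or seeded; the whole pipeline is a pure
  function of (config, seed), which `run_pipeline()`'s manifest records as a
  config hash plus seed.
* Chain-versus-oracle comparisons in the tests normalize RMS error by the
  fingerprint's dynamic range (range-normalized RMSE): SNV spectra have unit
  variance by construction, so sd-relative error wildly overstates
  disagreement for sparse, peaky fingerprints.

## Known limitations

* Peak-height recovery after baseline removal is biased low by ~4–4.5% for
  Lorentzian-tailed bands at the 50 cm⁻¹ bubble floor; this is a property of
  width-limited under-envelopes, not a tunable.
* The baseline envelope under noise is biased low by a noise-floor offset;
  class means therefore converge to the *expected processed profile*, not to
  the SNV of the noise-free truth. Tests compare independent replications
  for exactly this reason.
* The across-frame despiker cannot remove a spike present in at least half
  of the accumulations at one pixel.
* Record-level SAM is a descriptive tool; its within/between distributions
  overlap under realistic noise, which is why classification uses the
  supervised two-stage scheme.
* The L1 stage uses lasso-penalized logistic loss rather than an L1 hinge
  loss; both promote sparsity in a linear decision function, and the
  decision stage is an exact L2 hinge-loss SVM.

## Problem sizes used by the shipped tests

Unit tests run on reduced grids (401–801 pixels) and small sessions (2–6
heads, 2–4 replicates); the acceptance suite runs the full default session
(1601 pixels, ~300 records) once for the model suites and twenty four-tissue
sessions for the classification-recovery surface. These sizes were chosen so
the full suite exercises every contract at realistic scale in a couple of
minutes on a laptop core.
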