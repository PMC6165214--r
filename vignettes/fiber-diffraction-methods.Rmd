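---
title: "Models and methods behind fibreXRD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fibreXRD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibreXRD)
```

# The problem

Small-angle X-ray fiber diffraction of intact striated muscle encodes the
disposition of the myosin heads in a handful of measurable features.  The
hexagonal A-band lattice produces equatorial reflections whose intensity
ratio I~1,1~/I~1,0~ tracks mass moving from the thick-filament surface
toward the thin filaments; the quasi-helical arrangement of resting heads
on the 43 nm thick-filament repeat produces myosin layer lines (MLL)
whose integrated intensity falls as heads leave the ordered configuration
and whose first radial maximum encodes the head center-of-mass radius
R~m~; and the actin-based layer lines report thin-filament activation.
fibreXRD implements the quantitative chain from a 2D detector image to
these quantities, together with a forward model that renders synthetic
patterns with known ground truth so that every stage is verifiable by
parameter recovery.

# The equatorial model

The five reflections (1,0), (1,1), (2,0), (2,1), (3,0) are modelled as
Gaussians whose centers are hard-constrained to the lattice,
$R_{hk} = \theta_{hk}/d_{10}$ with
$\theta_{hk} = \sqrt{h^2 + k^2 + hk}$, and whose radial widths follow the
disorder decomposition

$$\sigma_{hk} = \sqrt{\sigma_c^2 + \sigma_d^2\,\theta_{hk}^2 +
  \sigma_s^2\,\theta_{hk}^4},$$

where $\sigma_c$ is the instrumental beam width (fixed, default
0.84×10^−3^ nm^−1^, about one detector pixel), $\sigma_d$ reflects
heterogeneity of the interfilament spacing among myofibrils and
$\sigma_s$ liquid-like (paracrystalline, second-kind) disorder of the
filaments within the lattice.  The free parameters are $d_{10}$,
$\sigma_d$, $\sigma_s$ and the five Gaussian areas; centers are not free
because the five orders index one lattice.  Reported "intensity" is the
Gaussian **area**: amplitude × width × √(2π).  Areas are robust to
exposure and to the width differences between orders, whereas amplitudes
are not.  The intensity ratio is the (1,1)/(1,0) area ratio, reported
with a delta-method standard error.

Assumptions: the trace is a baseline-removed projection over an
equatorial band wide enough to contain the reflections; disorder
broadens peaks but does not attenuate their integrated intensity
(no Debye–Waller factor — a stated simplification shared by the
generator and the fit); no Z-line or other non-lattice peaks are
modelled; and no disorder correction is applied to the ratio itself,
matching how such ratios are reported in practice.

## Numerical choices

* Fitting is Levenberg–Marquardt (`minpack.lm::nls.lm`) with cost
  tolerance 10^−10^ and up to five deterministic re-initializations from
  a fixed table of width/spacing perturbations, so results are exactly
  reproducible.
* Initialization takes the two largest local maxima of the lightly
  smoothed trace as (1,0) and (1,1).  Tie-break: if those maxima are
  closer than three beam widths, $d_{10}$ is re-seeded from the global
  maximum taken as (1,0).
* A trace in which only one reflection rises above noise is an error,
  never a silent ratio of zero; a (1,1) area below three of its standard
  errors is flagged `low_confidence_11`.
* Standard errors use a heteroskedasticity-consistent sandwich
  covariance with a smoothed variance function (squared residuals,
  leverage-corrected, regressed on the fitted curve).  Counting noise
  scales with intensity, so the homoskedastic formula understates the
  uncertainty exactly at the peaks; the smoothed variance proxy keeps
  the estimate stable where peaks span only a dozen samples.  On
  repeated synthetic fits the 1-σ intervals cover the truth at roughly
  the nominal rate (the test suite checks 55–85% at 50 seeds).
* The convex-hull baseline is the lower convex hull of the
  (coordinate, intensity) point set (Andrew's monotone chain), linearly
  interpolated and subtracted; it is exactly zero at the endpoints and
  at every contact point, and removes any smooth concave-up residual
  background left after circular-background subtraction.

# The layer-line model

A radial trace across a layer-line band (MLL4 default: axial
0.088–0.097 nm^−1^, chosen to minimize actomyosin contamination) is
fitted with four components: three background Gaussians centered on the
meridian — the meridional peak itself, a narrower meridian-proximal
background, and a broad diffuse background — plus one Gaussian for the
layer-line intensity around its first maximum, which supplies the
integrated intensity.  The background widths are
constrained to ordered, non-overlapping windows (meridional <
proximal < broad) to keep the four components identifiable; the fit is
restarted from eight fixed initializations of the width decomposition
and the lowest-deviance solution kept, because the three-Gaussian
background admits genuine local minima.

For the first-maximum **position** the package goes beyond the Gaussian:
when the Bessel order n of the line is known (the normal case — model
and analysis share one order convention), the position comes from a
joint fit in which the layer-line term has its physical shape, a scaled
$J_n(2\pi R_m R)^2$.  The first lobe of $J_n^2$ is asymmetric — a long
rise from the meridian, a fast fall to the first zero — so a Gaussian
centroid systematically underestimates the mode, by ~2% for n = 1 close
to the meridian.  With the exact shape the noise-free round trip from
generator to analyzer is accurate to well under 1% for orders 1, 3 and
4 across R~m~ 11–14 nm.  When the Gaussian peak has been absorbed by the
background components (a real degeneracy for first-order lines whose
lobe sits on the meridian-proximal background), a decisively better
Bessel-shaped fit overrides the "no peak" conclusion.

The head radius follows from the first-maximum relation
$R_m = x^*_n / (2\pi r_{max})$, where $x^*_n$ is the first maximum of
$J_n(x)^2$ (located numerically to ~10^−8^; 1.84118, 4.20119, 5.31755
for n = 1, 3, 4).  The order convention is configurable (default
MLL1 → 1, MLL4 → 4).  The same relation with n = 4 converts the
literature's ~0.062 nm^−1^ MLL4 first maximum into 13.65 nm, while
first-order analysis of MLL1 yields ~12.5 nm; the package keeps the
convention explicit rather than hiding the discrepancy, and the
generator default (R~m~ = 12.53 nm) is expressed in the MLL1
convention.

A fitted peak whose amplitude is consistent with zero (below three times
the residual noise, or an area below its standard error) is flagged
`no_ordered_heads`; rigor patterns, which have no ordered myosin heads,
produce this flag and a residual-intensity ratio of zero.

# Image reduction

* **Quadrant folding** averages the four mirror quadrants about the beam
  center (nearest-pixel reflection for fractional centers), excluding
  masked (NA) pixels with a per-pixel divisor.  It is idempotent and
  leaves an already symmetric image unchanged.
* **Circular background**: the 15th percentile of intensities in
  one-pixel annuli, smoothed with a Savitzky–Golay filter (window 11,
  order 2).  The image is box-blurred (half-width 2 pixels) before the
  quantile is taken: the low quantile of raw Poisson counts sits about
  one standard deviation below the local mean — a bias that depends on
  the count level and would make the normalization denominator differ
  systematically between bright and dim exposures; averaging ~25 pixels
  suppresses it to the few-per-mille level.  Empty corner annuli are
  filled flat and flagged.  The sum of the expanded background image is
  the **diffuse normalization** denominator: normalized intensities are
  invariant under common rescaling of exposure, which is what makes
  intensities comparable between specimens and states.
* **Band projection** sums intensity across a reciprocal-space band with
  linear fractional weights for the partially covered edge pixels (bands
  are specified in nm^−1^, not pixels), onto either the meridian (axial
  traces) or the equatorial direction (radial traces).  Projections are
  linear and masked pixels contribute zero.

# The synthetic pattern generator

The generator is a forward model of the same physics the analysis
assumes, with a few deliberate extensions so that reduction steps face
realistic structure:

* **Equator**: two-filament hexagonal unit cell — thick filament at the
  origin carrying the backbone mass plus the unrecruited fraction
  (1 − p) of head mass, thin filaments at the trigonal points each
  carrying the thin mass plus p/2 of head mass — with cylindrical
  Gaussian form factors $\phi(R) = e^{-2\pi^2\rho^2R^2}$ (thick radius
  defaulting to R~m~, thin 4.5 nm), the simplest monotone decay giving
  resting ratios below 1.  The phase sums make I~1,1~/I~1,0~ strictly
  increasing in p, so `solveHeadPartition` can calibrate p to any
  achievable target ratio by bisection (to 10^−9^); the default model is
  calibrated to the resting ratio 0.421.
* **Myosin layer lines** at l/(43(1+ε)) nm^−1^ with radial profile
  $f_{ord}^2\,A_l\,J_n(2\pi R_m R)^2$ — intensity proportional to the
  square of the ordered head fraction, the mass-squared law that the
  analysis inverts.
* **State presets**: contracting multiplies the ordered fraction by
  √0.28 (the square root of the published residual-intensity ratio),
  sets ε = 1%, doubles σ~s~ and raises the head partition to the
  contracting ratio 1.175; rigor has no ordered heads, strong actin and
  actomyosin lines and maximal head partition; blebbistatin increases
  ordering (×1.36, i.e. the square root of the observed ~1.85-fold
  MLL4 intensification), reduces R~m~ (×12.31/12.53) and lowers the head
  partition; BTS is structurally resting (force-only inhibition).  All
  presets are overridable.
* **Other features**: actin layer lines on the 35.9 nm (13/6-helix)
  repeat, with the outer part of ALL2 (the tropomyosin-sensitive
  Tm/ALL2 band) scaling as 0.4 + 0.6 × activation, so full activation
  raises it 2.5-fold over rest; meridional reflections (M3, M6 on
  43 nm; troponin orders on 38.7 nm; MyBP-C orders on ~44 nm, as simple
  Gaussians, with only the myosin family following ε); a broad circular
  diffuse background plus a meridian-proximal stripe; Poisson counting
  noise from an isolated RNG stream, so the same seed always gives the
  bit-identical image.
* **Actomyosin lines in rigor** sit at ~1/24 and ~1/10.3 nm^−1^
  axially.  AM~+1~'s center lies essentially on the upper edge of the
  MLL4 integration band; on a real detector it is azimuthally offset
  from the band, which an azimuthally uniform render cannot represent,
  so its amplitude is attenuated (2% of the AM scale) and its axial
  profile kept narrow.  This keeps the rigor MLL4 band at the
  background level, as observed.

Default geometry: 0.1 mm pixels, 2 m camera, 0.1033 nm wavelength
(4.84×10^−4^ nm^−1^ per pixel — at this scale one pixel matches the
0.84×10^−3^ nm^−1^ beam width within a factor ~2), 441×441 pixels with
the beam centered, 10^6^ expected counts per pattern.  These sizes keep
a full render-and-analyze cycle under a second, so ensemble tests over
tens of seeds run in seconds; they cover the first five equatorial
orders and the first four myosin layer lines of a 36 nm lattice.

## What the generator does and does not emulate

It emulates the feature set the analysis consumes: peak positions,
widths, intensity scalings, state contrasts, counting noise, and the
background structure the reduction must remove.  It does **not** model
lattice sampling of low-order layer lines, interference fine structure
of the meridionals (M3 doublets), detector distortion, polarization or
absorption, azimuthal (arcing) intensity spread, Debye–Waller
attenuation, or shortening-induced mass changes during fixed-end
contraction.  Passing parameter-recovery tests therefore demonstrates
the internal consistency and numerical correctness of the pipeline
under the stated model, not its accuracy on features the model omits.

# Derived physiology

* `orderedHeadFraction(r)` = √r: helical diffraction intensity scales
  with the square of the coherently ordered mass, so a residual
  intensity ratio of 0.28 implies ~53% of heads remaining ordered.
  Ratios above 1 (inhibitor-enhanced ordering) return a value above 1
  with a flag rather than an error.
* `recruitedFraction(Δstate, Δrigor)` divides the equatorial ratio
  change by the rigor change under the linearity assumption; the
  remaining fraction is its complement, returned at full precision (the
  published rounded figure differs only by rounding).
* `crossSectionalArea` = mass/(density × length) with the ml→mm³
  conversion (density default 1.06 g/ml); `specificTension` divides
  force by it.
* Regressions are ordinary least squares (`lm`), with optional
  inverse-variance weights; the quadratic fit is descriptive only.
* `hillVsLinear` fits $y = y_{max}x^h/(x_{50}^h + x^h)$ and a line, and
  compares them by an extra-sum-of-squares F-test with one extra
  parameter.  The Hill curve does not nest the line exactly, so AICc
  for both models is also reported; simulations in the test suite show
  the F-test holds its nominal type-I error on linear truths and
  rejects decisively on sigmoidal truths at the ~50-point sampling of a
  time-resolved tension rise.  The slope of the low-tension regime
  (x ≤ 0.6 by default) is reported separately.

# Known limitations

* The equatorial ratio is reported uncorrected for disorder or for
  thin-filament localization, by design; σ~d~ and σ~s~ are reported so
  such corrections can be applied downstream.  The optional conversions
  of σ~d~ and σ~s~ to Δd~10~/d~10~ and ΔX/d~10~ are not built in, since
  no explicit formula is adopted here.
* The Gaussian intensity of a layer line is an approximation to an
  asymmetric lobe; between-state intensity *ratios* are accurate
  because the shape cancels, but absolute areas carry a shape-dependent
  few-percent offset from the true lobe integral.
* Fractional beam centers are folded by nearest-pixel reflection;
  sub-pixel interpolation is not implemented.
* The circular-background quantile (15%) and its smoothing are
  conventional but not canonical; both are exposed as parameters.
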