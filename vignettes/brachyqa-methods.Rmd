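---
title: "Methods: dose calculation, medium conversion, film dosimetry and gamma analysis in brachyqa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose calculation, medium conversion, film dosimetry and gamma analysis in brachyqa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brachyqa)
```

## The problem

Patient-specific quality assurance of high-dose-rate (HDR) Ir-192
brachytherapy asks one question: does the dose distribution the afterloader
actually delivers agree with the one the treatment planning system (TPS)
computed? A practical answer is to deliver the plan into a solid plastic
phantom holding a radiochromic film, convert the film to a planar dose map,
recalculate the same plane independently, and compare the two with a
gamma-index analysis. Two physics complications make this non-trivial:

1. TPS dose engines follow the AAPM TG-43 formalism, which assumes all dose
   is deposited in *water*. A plastic (ABS) phantom scatters and attenuates
   differently, so a calculated water dose is not directly comparable with a
   dose measured inside plastic.
2. Radiochromic film is not a direct dosimeter; it needs a per-batch
   calibration from net optical density (netOD) to dose, with a colour
   channel chosen for the dose range at hand.

`brachyqa` implements the full chain: a TG-43 line-source dose engine, a
radial water-to-ABS conversion factor, film netOD calibration and
conversion, gamma analysis with an exhaustive-search oracle, and a workflow
layer with standard test cases and a synthetic-measurement generator.

## Dose model

The dose rate around a single source position is the TG-43U1 line-source
equation

$$\dot D(r, \theta) = S_K \,\Lambda\,
\frac{G_L(r,\theta)}{G_L(r_0,\theta_0)}\, g_L(r)\, F(r,\theta)\, CF(r),$$

with $r$ the distance from the source centre (cm), $\theta$ the polar angle
from the source long axis, and the reference point
$(r_0, \theta_0) = (1\ \mathrm{cm}, 90^\circ)$. The factors are:

* $S_K$ — air-kerma strength, in U = cGy·cm²·h⁻¹ (package default
  40 700 U, a nominal 10 Ci Ir-192 source);
* $\Lambda$ — dose-rate constant, cGy·h⁻¹·U⁻¹, from the source
  characterization;
* $G_L(r,\theta) = \beta / (L\, r \sin\theta)$ — the line-source geometry
  factor, where $\beta$ is the angle subtended by the active length $L$ at
  the calculation point; on the long axis the closed form
  $(r^2 - L^2/4)^{-1}$ applies. This closed form *is* the exact value of the
  inverse-square integral over the source segment, which is why the test
  suite can demand agreement with numerical quadrature to $10^{-6}$
  relative;
* $g_L(r)$ — radial dose function, interpolated linearly in $r$ and clamped
  to the end values outside the table (no extrapolated physics is
  invented);
* $F(r,\theta)$ — 2D anisotropy function, interpolated bilinearly and
  edge-clamped;
* $CF(r)$ — the medium conversion factor (next section); $CF \equiv 1$
  in water.

A plan is a set of dwell positions and times along one straight catheter.
`dose_plane()` superposes dwells onto a planar grid parallel to the catheter
at a configurable perpendicular offset (default 1 cm — the "1 cm below the
source" measurement geometry, with the film sandwiched in the phantom).
Dwell times are in seconds and converted to hours inside the superposition,
because $S_K \Lambda$ is per hour. The default grid spacing is 0.1 cm,
matching the 1 mm scoring voxel of the Monte Carlo work the conversion
curve derives from; the default extent is 8 × 8 cm, a film-sized window
that comfortably contains the 10%-of-maximum analysis region of all
packaged cases. CF is applied inside the per-dwell sum, at each
contribution's own radius, because the conversion is defined per source
position, not for a composite distribution.

## The medium conversion factor CF(r)

$CF(r)$ is the ratio of dose in the ABS phantom to dose in water at radial
distance $r$ from the source, as determined by Monte Carlo transport (the
transport itself is outside this package's scope; the curve ships as data).
The packaged anchors are 0.88 at 0.5 cm, 0.932 at 1.0 cm, 1.00 at 2.1 cm,
1.08 at 6.0 cm and 1.04 at 8.0 cm: the plastic under-responds close to the
source, crosses unity at 2.1 cm and over-responds at mid range. Evaluation
is piecewise linear — transparent, and it reproduces every anchor exactly.
Below 0.5 cm the first value is held rather than extrapolating into
near-source conditions the data do not cover. Above 8 cm the ABS/water
difference is small enough to be treated as negligible, so `cf_at()`
returns exactly 1 there; the step from 1.04 to 1 at the 8 cm boundary is a
deliberate, documented discontinuity outside the curve's stated validity
range.

The 1.0 cm anchor (0.932) is the ABS percentage dose at the water
normalization point. It fixes the headline single-dwell result: a plan
normalized to 400 cGy water dose at (1 cm, 90°) yields
400 × 0.932 = 372.80 cGy in the phantom.

## Film dosimetry

netOD is the standard $\log_{10}(PV_\mathrm{unexposed}/PV_\mathrm{exposed})$
of scanner pixel values. Calibration fits

$$D(\mathrm{netOD}) = b\,\mathrm{netOD} + c\,\mathrm{netOD}^{\,n}$$

with $n$ fixed per channel by a grid search over $\{1.5, 2, 2.5, 3\}$ and
$(b, c)$ by least squares. Residuals are *relative* (weighted by 1/dose):
the calibration spans 0–19 Gy, two decades, and the quantity that matters
clinically is percent error, not cGy. With absolute residuals the 19 Gy end
dominates the fit and low-dose nodes can err by several percent under 1%
netOD measurement noise; with relative residuals the same noise propagates
to about 1–2% at every node. The fitted curve must be strictly increasing
over the calibrated range (enforced, not assumed), which also makes it
invertible; inversion uses bisection plus Newton polishing so the noiseless
dose → synthetic scan → dose round trip closes to numerical precision.

Channel selection follows film practice: red below 10 Gy, green at and
above it (the boundary itself goes to green — the wording "below 10 Gy /
above 10 Gy" leaves the boundary open, so it is fixed here by convention).
Scans are accepted as delimited-text channel grids; synthetic scans keep
continuous (unquantized) pixel values so round-trip tests are exact. No
scanner corrections (lateral response, orientation, quantization) are
modelled — a documented limitation, and one reason synthetic measurements
are gentler than real film.

## Gamma analysis

`gamma_map()` implements the Low et al. gamma index: for each reference
point above the low-dose threshold,

$$\gamma = \min_{x'} \sqrt{\left(\frac{D_e(x') - D_r(x)}{\Delta D}\right)^2 +
\left(\frac{|x' - x|}{\mathrm{DTA}}\right)^2},$$

with $\Delta D$ = 3% of the normalization dose under global normalization
(default: the maximum of the reference distribution, since the source named
only "global normalization") or 3% of the local reference dose under local
normalization. Defaults are 3%/3 mm, a 10% low-dose threshold (exposed as
an option because passing rates depend on it), and a search radius of
3 × DTA — beyond that radius the distance term alone already exceeds
$\gamma = 3$, so truncation cannot change pass/fail decisions.

Numerically, the evaluated grid is bilinearly upsampled to at most DTA/10
sampling; candidate offsets are visited in order of increasing spatial
distance, and the search stops once the distance term alone exceeds every
point's current minimum. `gamma_oracle()` is an independent implementation
— brute-force enumeration of all fine-grid positions per reference point,
with its own upsampling code — used purely for validation; the two agree to
better than 0.01 per point across a 50-pair seeded suite of random and
structured fields.

### An asymmetry worth knowing about

Gamma is not symmetric in its arguments, and the asymmetry matters exactly
where this package operates. Near an HDR source the dose gradient is
enormous (about 20%/mm at 1 cm), so a systematic few-percent *scaling*
error can be absorbed by a sub-millimetre shift: the water-formalism plane
differs from the phantom plane by ~7% at 1 cm, yet against a noiseless
phantom-derived reference every water point finds a matching isodose well
inside 3 mm and gamma stays around 0.9 or below. The configuration that
*does* discriminate is the one where the evaluated distribution cannot
reach the reference's maximum at all: with the water plane as reference,
the phantom-derived measurement is ~7% lower everywhere near the source, no
shift helps, and the near-source region fails. The acceptance suite
therefore checks the water-vs-corrected ranking in that configuration
(reference = calculated plane, evaluated = synthetic measurement), which is
deterministic and reproduces the qualitative clinical finding — the
water-only calculation always ranks below the medium-corrected one. With
real film, noise and registration error break the perfect DTA rescue and
the measurement-as-reference direction becomes discriminating too; with a
noiseless synthetic measurement it is provably not.

## The synthetic-measurement generator

`simulate_measurement()` stands in for the film: a rigid (u, v) shift in mm
(bilinear resampling, edge-clamped) models registration error, followed by
multiplicative Gaussian noise modelling scanner and film-response noise.
Realistic settings used in the tests are 1% noise and ~1 mm shift; film
dosimetry under a careful protocol achieves per-pixel noise at about this
level. The generator is deterministic under a fixed seed and leaves the
session RNG untouched. It does **not** emulate scanner lateral-response
artifacts, film curling or orientation effects, energy-response drift, or
non-rigid registration error — so a green verification here establishes the
correctness of the calculation chain, not the performance of a physical
scanner workflow.

## Packaged fixtures and standard cases

* The source file `source_mHDRv2_synthetic.txt` has the mHDR-v2 active
  length (0.35 cm) and a dose-rate constant of 1.109 cGy·h⁻¹·U⁻¹, but its
  $g_L$/$F$ tables are a synthetic stand-in shaped like published Ir-192
  consensus data (the consensus tables are not redistributed). All headline
  results depend on these tables only through the normalization points
  $g_L(1) = 1$ and $F(r, 90^\circ) = 1$.
* `make_case()` builds the three standard plans: a single dwell; an
  elliptical distribution from 7 equal-time dwells at 5 mm pitch; and a
  concave-elliptical distribution from the same positions with a monotone
  1..7 time ramp. The dwell count and the ramp shape are package choices
  (documented, illustrative); dwell times are normalized so the *water*
  dose 1 cm below the dwell-pattern centroid equals the prescription, which
  for the single dwell is the TG-43 reference point exactly.
* High-dose verification uses the concave case at 9.5, 10.75, 13.5 and
  15 Gy, which exercises the green film channel.

## Numerical choices, degenerate inputs, limitations

* Interpolation nodes are reproduced exactly (linear/bilinear with
  edge-clamping); continuity at nodes is tested to $10^{-6}$.
* On-axis geometry-factor evaluation switches to the closed form when
  $\sin\theta < 10^{-12}$; points inside the source segment are a domain
  error, not a number.
* Points below the gamma low-dose threshold are NaN in the gamma map and
  excluded from the passing-rate denominator; a reference point with no
  evaluated candidate in range (possible when grids barely overlap) gets
  $\gamma = \infty$ and counts as failing.
* Negative netOD (noise around zero dose) is flagged, clamped to zero dose,
  and never an error; an all-saturated scan is an error.
* One straight catheter only; no applicator or shielding heterogeneity; CF
  is radial only (no angular or depth dependence); no DICOM import/export;
  no TIFF reader in this environment, so film scans travel as delimited
  text.
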