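---
title: "Task-based CT image quality: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-based CT image quality: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctiq)
```

# What the package measures

Task-based image quality assessment characterises a CT imaging chain by
three quantities measured on phantom images:

* the **noise power spectrum** (NPS), the spectral density of image noise
  in HU² mm² against spatial frequency in mm⁻¹, whose integral is the
  noise variance and whose shape encodes noise *texture*;
* the **task-based transfer function** (TTF), the effective modulation
  transfer measured on a contrast insert with the circular-edge technique,
  summarised by `f50`, the frequency at which it falls to 50%;
* the **detectability index** `d'` of a non-prewhitening model observer
  with an eye filter (NPWE), which condenses task, resolution, noise and
  viewing conditions into a single scalar that tracks human lesion
  detection.

The motivating application is virtual monoenergetic imaging (VMI) on
dual-energy CT of abdomens of different sizes: low energy levels (40--70
keV) raise iodine contrast and noise together, and the three quantities
above quantify the net effect per phantom diameter. Because raw scanner
acquisitions of this kind are proprietary and not deposited, the package
ships a synthetic phantom generator with *known* ground truth; every
estimator is validated by parameter recovery, and a study pipeline
reproduces the qualitative orderings such data exhibit.

# The synthetic phantom generator

`generatePhantomStack()` renders a uniform section disk (default 35 HU,
configurable, since phantom background at each energy level is not a
published constant) in air at −1000 HU, with an optional circular insert
at `background + contrast`, and adds an independent stationary noise
field per slice.

**Edge blur.** The scene is convolved with an isotropic Gaussian of
width `edgeBlurSigma` representing the system PSF. The convolution is
computed *exactly* for circular structures — the blurred disk profile is
the offset-Gaussian disk-coverage probability, evaluated by radial
quadrature with scaled Bessel functions — and then sampled at pixel
centers. A rendered-then-filtered pipeline was rejected because pixel-area
rendering multiplies the spectrum by a box MTF (a 12% droop at the
frequencies where `f50` lives) and a sampled discrete kernel adds aliased
tails; with the analytic profile, the generator's transfer function *is*
`exp(-2π²σ²f²)`, which is what makes closed-form recovery tests possible.

**Noise.** `noiseModel()` describes the radial NPS as a mixture of
components `S(f) = A (f/f_c)^p exp{-(p/q)[(f/f_c)^q - 1]}`: each
component is non-negative, peaks with value `A` exactly at `f_c` (for
`p > 0`), and `p = 0` gives a flat, white component. One mid-frequency
component emulates the usual reconstruction-kernel band-pass; adding a
low-frequency component (defaults `f_c` = 0.03 and 0.16 mm⁻¹) emulates
the two-peak spectra observed on split-filter systems, whose generative
origin is not modelled — the mixture is phenomenological, which is all
that peak detection needs. `generateNoiseField()` shapes white Gaussian
noise in the frequency domain with the square root of the target
spectrum, so the expected periodogram equals the target exactly and, by
Parseval, the field variance equals the spectral integral; `targetSd`
rescales the spectrum so that variance is a chosen noise SD in HU.

What the generator does **not** emulate: spatial non-stationarity of real
CT noise (the estimators assume local stationarity inside ROIs anyway),
slice-to-slice noise correlation (all estimators here pool slices and
average), beam hardening, iterative-reconstruction non-linearity, and
projection physics. Passing tests therefore demonstrate estimator
correctness under the stationary-Gaussian model, not robustness to those
effects.

# NPS estimation

`estimateNps()` follows standard CT practice: square ROIs in the
homogeneous region (defaults: four ROIs at 90° around the section center
at half the section radius — published figures show four off-center ROIs
but not their coordinates — with sizes 80/104/120 pixels for the
26/31/36 cm sections and a 180-slice budget), each detrended by a
least-squares polynomial of total degree 2 (the de-facto standard
pre-processing; the alternative of subtracting a paired ROI is not
implemented), then the averaged periodogram

```
NPS(u, v) = (Δx Δy) / (Nx Ny) · ⟨ |DFT(residual)|² ⟩.
```

Frequency bins are `1/(roiSize · spacing)` wide with no zero padding
(unbiased periodogram resolution).

Two 1-D curves are kept, because the field's scalar metrics mix two
conventions. The **radial average** (HU² mm²) is what is plotted and what
peaks are read from; `f_av` is its power-weighted mean frequency,
computed *without* the `2πf` Jacobian — whether published `f_av` values
weight by `2πf` cannot be determined from the text, and the unweighted
reading matches "average frequency of the displayed curve". The
**angular-integrated** curve is the exact per-ring integral divided by
the bin width, taken over the whole grid including the corner region
beyond the Nyquist disk; its integral over `f` therefore equals the 2-D
spectral integral *exactly*, and the noise magnitude
`sqrt(∫ curve df)` equals the stationary noise SD by Parseval. (For white
noise the corners carry 21% of the power; a curve truncated at Nyquist
could never satisfy the Parseval check.)

Peaks are local maxima of the radial average, prominence-ranked; at most
two are reported, matching how such tables list "NPS peak(s)", and a
secondary peak requires prominence above a configurable 5% of the global
maximum. With averaged periodograms the argmax still jitters by about one
bin when a lobe is broad; recovery tests therefore use ensembles of a few
hundred ROI blocks, the same regime the study pipeline operates in.

# TTF estimation

The circular-edge chain is `estimateCenter()` →`radialEsf()` →
`ttfFromEsf()` → `ttfF50()`:

1. the insert center is the intensity-weighted centroid of the
   thresholded insert (threshold = midpoint of the inside/outside
   plateaus), averaged over slices, with sub-pixel precision; a slice
   whose plateau difference is below the window SD contributes nothing,
   and if no slice detects the insert the stack is rejected;
2. every pixel of every pooled slice is binned by radial distance from
   that center (default bin width 0.1 pixel); the per-bin mean is the
   ESF, and the contrast is the difference of plateau means read from
   configurable inner/outer margins. Pooling all slices *before*
   differentiation is variance-optimal and is asserted against the
   per-slice alternative in the test suite. One numerical subtlety: for
   an insert centered exactly on the pixel lattice, attainable radii are
   quantized (`sqrt(m)·spacing/2` for certain integers `m`) with gaps
   that exceed 0.1 pixel at small radii, so some bins are legitimately
   empty; `radialEsf()` rejects empty bins by default (naming the first
   offender), and the `estimateTtf()` pipeline instead interpolates them
   from neighbouring bins, which is exact for any smooth profile;
3. the LSF is the centered finite difference of the ESF. A window is
   applied before the Fourier transform to suppress far-tail noise: flat
   across the contiguous region where `|LSF|` exceeds 1% of its peak,
   with a cosine-squared (Hann) taper of the same width beyond. Tapering
   only where the LSF is already negligible leaves the transfer estimate
   unbiased; a taper reaching into the LSF core would broaden the
   apparent transfer by several tens of percent. The TTF is the modulus
   of the (explicitly evaluated) Fourier transform of the windowed LSF,
   normalized to 1 at zero frequency; `f50` is found by linear
   interpolation at the first downward 0.5 crossing.

No monotonicity constraint or smoothing is applied to the ESF and no
noise-power correction to the TTF (both are configurable absences by
design): the noise-dependence of the measured TTF is part of the
measurand in this field's practice. At realistic contrast-to-noise
ratios and a 160-slice budget the pooled estimator is essentially
unbiased (the suite asserts 5% recovery under noise and 2% noiseless);
when CNR is pushed very low the modulus spectrum acquires a noise
pedestal and the curve distorts — the suite asserts that this distortion
grows as CNR falls, rather than a sign, because a pooled-ESF estimator
does not reproduce the *downward* f50 shifts that real systems show at
low energy levels. Those shifts are system properties, and the study
generator encodes them as generator conditions (below).

# The NPWE observer

The detection task is a 10 mm circular lesion with Gaussian contrast
profile. "Diameter" of a profile without a hard edge is read as the FWHM
(`sigma = d/2.3548`), the only scale-free interpretation; a `"2sigma"`
reading is available. Its task function is
`W(f) = C·2πσ²·exp(-2π²σ²f²)`. The per-energy contrasts default to the
iodine ladder 1260/820/550/390 HU at 40/50/60/70 keV.

The eye filter is `E(ρ) = ρ^{n1} exp(-c ρ^{n2})` with `c` fixed so the
maximum value 1 sits at `peakFreq` cycles/degree; defaults
`(n1, n2, peakFreq) = (1.5, 2, 4)` are documented assumptions, not
published constants, and are configurable. Spatial frequency converts to
angular frequency via `ρ = f · zoom · distance · π/180` (zoom 1.5,
500 mm viewing distance by default); zoom conventions differ between
implementations, so the factor is exposed.

The index is

```
d'² = [ ∬ W² TTF² E² df ]² / ∬ W² TTF² E⁴ NPS df
```

with both 2-D integrals computed as radial quadratures `∫ 2πf (·) df` on
[0, Nyquist], the measured TTF and the *un-normalized* measured NPS
linearly interpolated and clamped beyond support. Omitting the display
gives the plain NPW observer, for which the white-noise, ideal-TTF closed
form `d' = Cσ√π/√N₀` anchors the quadrature to 1%; radial and full 2-D
Cartesian quadrature agree to 0.5% for isotropic spectra. Degeneracies
are explicit: a zero NPS is an error (ideal-observer limit), a
zero-contrast task returns `d' = 0`.

# The study pipeline and its reference conditions

`syntheticStudyConfig()` + `runStudy()` enumerate dataset × diameter ×
keV combinations, generate `nAcq` independent acquisitions each
(emulating repeated scans; 18 slices per acquisition feed the NPS and 16
the TTF, so the full budgets of 180 and 160 slices correspond to 10
acquisitions), pool the slices, and run NPS → TTF → d′ per combination,
recording failures per row without aborting. `percentDiffSummary()`
reports `100·(A−B)/B` per level, then mean ± *sample* SD (n−1) over
levels — the conventional reading of "mean ± SD" across four energy
levels, stated here because it changes the printed SD.

The default generator conditions are the package's reference study and
encode the orderings such acquisitions exhibit:

* noise SD: per-dataset base (14 and 13 HU at 26 cm / 70 keV) times
  diameter factors (1, 1.35, 1.75) times keV factors
  (2.5, 1.8, 1.35, 1) — noise grows with patient size and falls with
  energy level, roughly −60% from 40 to 70 keV;
* NPS shape: two lobes at 0.03 and 0.16 mm⁻¹; the low-frequency lobe is
  the larger (ratios 1.1/1.3/1.5 across diameters × 1.5/1.3/1.15/1.0
  across keV), so noise texture coarsens with diameter (f_av falls) and
  the low/high peak gap narrows with rising keV;
* effective PSF: per-dataset base sigma (0.45, 0.42 mm) times diameter
  factors (1, 1.12, 1.25) times keV factors (1.06, 1.04, 1.02, 1.00).
  The diameter and keV widening encode the *measured* behaviour of f50 on
  such systems (resolution falls with patient size and toward low keV);
  they are generator conditions, not estimator artifacts — see the TTF
  section;
* one 25 mm iodine-like insert at the section center; acquisition
  geometry 380 mm field of view, 512² matrix (0.742 mm/pixel), 1 mm
  slices.

With these conditions a 2-dataset × 3-diameter × 4-keV study at
`nAcq = 2` (the problem size used by the test suite and the acceptance
script; about 1.5 thousand slice syntheses) reproduces, as strict
monotonicities in the output table: noise magnitude increasing with
diameter and decreasing with keV; d′ maximal at 40 keV, decreasing with
keV and with diameter; f50 and f_av decreasing with diameter.

# Numerical choices and degenerate inputs

* Frequency grids: periodogram bins `1/(N·Δx)`; radial bins of one
  frequency step centered on multiples of the step; no zero padding.
* The TTF is evaluated as an explicit discrete-time Fourier transform on
  a fine frequency grid (step ~0.005 mm⁻¹), so `f50` interpolation error
  is negligible against its 2% tolerance.
* `d'` quadrature uses 4096 trapezoid points to Nyquist; doubling changes
  results at the 1e-6 level.
* Exactly noiseless stacks produce periodograms at the double-precision
  floor (~1e-26); spectra below 1e-18 HU² mm² are treated as identically
  zero so the degenerate paths error cleanly instead of returning
  astronomically large d′.
* Determinism: every stochastic step derives its seed from the spec/config
  seed (kept below 2³¹); identical configuration gives bit-identical
  stacks, tables and CSV files, and generators restore the caller's RNG
  state.
* DICOM round trips quantize to the rescale slope (default 0.1 HU);
  the portable array sidecar round trip is exact.

# Known limitations

* Stationary Gaussian noise only; no non-stationary or 3-D NPS.
* One insert, one task profile (Gaussian); no slanted-edge MTF, no
  channelized-Hotelling or internal-noise observers.
* The DICOM reader handles explicit-VR little-endian single-frame CT
  series (what the writer emits and what the round-trip tests need), not
  the full standard.
* Peak localization is quantized to the radial bin width; broad spectral
  lobes localize to ±1 bin only with ensembles of a few hundred ROIs.
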