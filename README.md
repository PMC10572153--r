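# ctiq — task-based image quality assessment for CT

`ctiq` measures how well a CT imaging chain supports a clinical detection
task, the way medical physicists assess scanners on multi-diameter
image-quality phantoms. It is aimed at anyone who needs the three
standard task-based metrics from stacks of axial CT slices in Hounsfield
units — and at method developers who need a ground-truth image generator
to validate such estimators.

The three metrics, computed per phantom section diameter and (for
dual-energy virtual monoenergetic images) per energy level:

* **Noise power spectrum (NPS).** From four square ROIs per slice in the
  homogeneous region, detrended with a degree-2 polynomial and averaged
  as periodograms: `NPS(u,v) = (ΔxΔy)/(NxNy) ⟨|DFT(residual)|²⟩`.
  Scalar summaries: noise magnitude `sqrt(∫NPS₁D df)` (HU, the noise SD
  by Parseval), average spatial frequency `f_av`, and up to two
  prominence-ranked peak frequencies `f_peak` with their magnitudes.
* **Task-based transfer function (TTF).** The circular-edge technique on
  a contrast insert: pixels binned by radial distance from the sub-pixel
  insert center give the edge spread function, its derivative the line
  spread function, and the modulus of its windowed Fourier transform the
  TTF, summarised by `f50` (mm⁻¹), where transfer falls to 50%.
* **NPWE detectability index.** For a circular lesion with Gaussian
  contrast profile (task function `W(f) = C·2πσ²·e^{-2π²σ²f²}`) viewed
  at zoom 1.5 from 500 mm through a band-pass eye filter:

  `d'² = [∬W²·TTF²·E² df]² / ∬W²·TTF²·E⁴·NPS df`

Because the scanner acquisitions behind such studies are not publicly
deposited, the package includes a synthetic phantom generator —
uniform sections of 26/31/36 cm diameter, stationary correlated noise
with a prescribed (optionally two-peak) radial spectrum, an iodine-like
insert whose contrast follows the 40–70 keV ladder (1260/820/550/390 HU),
and exact Gaussian edge blur — so every estimator is validated by
recovering known parameters. A study pipeline runs all combinations and
summarises differences as mean ± SD percentages. Minimal DICOM-series
and compressed-array I/O round-trip stacks to disk.

## Worked example

A 26 cm section at 40 keV: two-lobe noise at 35 HU, a 25 mm insert at
1260 HU contrast, 0.45 mm PSF, 36 slices.

```r
library(ctiq)

spec  <- phantomSpec(260, backgroundHU = 35,
                     insert = centeredInsert(1260, 25),
                     edgeBlurSigma = 0.45, nSlices = 36, seed = 42)
model <- noiseModel(c(130, 100), c(0.03, 0.16), targetSd = 35)
stack <- generatePhantomStack(spec, model, label = list(kev = 40, diameter_cm = 26))

nps <- estimateNps(stack, defaultRoiLayout(26, nSlicesUsed = 36))
nps
#> NPSResult from 144 ROI blocks (80 x 80, 0.7422 mm/pixel)
#>   noise magnitude 34.9 HU, f_av 0.1568 mm^-1
#>   peaks:
#>       fpeak magnitude prominence
#>  0.03368421  5788.380   5782.754
#>  0.15157895  5152.898   2164.164

ttf <- estimateTtf(stack)
ttf
#> TTFResult: 401 frequencies up to 2 mm^-1, f50 = 0.4153 mm^-1, contrast 1260 HU

dprimeNpwe(taskSpec(10, contrast = 1260), nps, ttf, displaySpec())$dprime
#> [1] 88.10
```

Reading the numbers: the estimated noise magnitude (34.9 HU) recovers the
prescribed 35 HU; the two NPS peaks sit on the generator's 0.03 and
0.16 mm⁻¹ lobes (within one 0.0168 mm⁻¹ frequency bin) with the
low-frequency lobe dominant; the measured edge contrast recovers the
1260 HU insert; `f50` ≈ 0.415 mm⁻¹ reflects the 0.45 mm PSF
(analytically `sqrt(ln 2/2)/(π·0.45) = 0.4164`); and `d'` ≈ 88 condenses
task, resolution and noise into the observer's detectability.

A whole study — datasets × diameters × energy levels, with noise rising
with diameter and falling with keV — is one call:

```r
cfg <- syntheticStudyConfig(nAcq = 2, seed = 11)
res <- runStudy(cfg)                       # 24-row tidy table
percentDiffSummary(res[res$dataset == "A", ], "noise_magnitude",
                   axis = "kev", ref = 40, cmp = 70, over = "diameter_cm")
#>   mean_pct ≈ -60, sd_pct ≈ 0.5, n = 3   (noise drops ~60% from 40 to 70 keV)
```

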