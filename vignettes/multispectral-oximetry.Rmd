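---
title: "Methods: multispectral tissue oximetry with oximsi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multispectral tissue oximetry with oximsi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oximsi)
```

## The measurement problem

Visible-range tissue reflectance is dominated by haemoglobin absorption,
with oxy- and deoxyhaemoglobin differing most strongly between roughly
500 and 600 nm. A filter-wheel multispectral camera samples this range
through eight narrow Gaussian passbands, giving a per-pixel eight-point
absorbance spectrum from which relative chromophore concentrations — and
from them oxygen saturation — can be estimated. The intended application
is intraoperative perfusion assessment of exposed bowel: the clinically
relevant output is the longitudinal SO₂ profile of a segment, summarised
per region of interest from the proximal to the distal end.

## Model and assumptions

Per pixel, base-10 absorbance in band $b$ is modelled as

$$A_b = [\mathrm{HbO_2}]\,\bar\varepsilon_{\mathrm{HbO_2},b}
      + [\mathrm{Hb}]\,\bar\varepsilon_{\mathrm{Hb},b}
      + [\mathrm{Fat}]\,\bar\varepsilon_{\mathrm{Fat},b} + G,$$

where $\bar\varepsilon_{c,b}$ is the extinction spectrum of chromophore
$c$ convolved with the transmission profile of filter $b$, and $G$ is an
offset. The model assumes (i) these three are the only absorbers in the
field of view, (ii) scattering is wavelength-independent, so it folds
into $G$ together with any illumination scale, and (iii) photon
pathlength is common across chromophores, so concentrations are
*relative* and only ratios such as SO₂ are comparable across scenes.

Assumption (ii) is what makes the estimate illumination-invariant:
multiplying reflectance by any $k>0$ shifts every band's absorbance by
$-\log_{10}k$, which the fit absorbs entirely into $G$. The test suite
checks this to $10^{-8}$ for $k \in \{0.5, 2, 10\}$.

The fit is *unconstrained* ordinary least squares. Negative
concentration estimates are possible and are handled downstream by the
validity filter, which excludes any pixel with CoD $< 0.9$ or a negative
concentration — mirroring a filter that presupposes an unconstrained
estimator. Excluded pixels carry a sentinel value of 0 in every exported
map plus an explicit boolean mask; all statistics in the package consume
the mask, never the sentinel.

## Spectral data and band convolution

Band coefficients are transmission-weighted means
$\sum_\lambda \varepsilon(\lambda)T(\lambda) / \sum_\lambda T(\lambda)$
with $T$ the Gaussian passband
$T(\lambda)=T_0\exp(-4\ln 2\,(\lambda-\lambda_0)^2/w^2)$ ($w$ = FWHM).
A weighted *mean* rather than a raw integral is used because
white-reference normalisation cancels the illuminant spectrum and system
throughput, leaving only the passband shape relevant; the coefficient is
accordingly independent of peak transmission.

Numerical choices:

- Tabulated spectra (1 nm grid) are internally refined to 0.1 nm by
  linear interpolation before the weighted sum, so the quadrature error
  of the tabulation step is negligible (verified against a brute-force
  0.1 nm oracle to $10^{-3}$ relative in the tests).
- Passband coverage is defined as capturing at least 50% of the
  analytic Gaussian transmission integral on the grid. The default
  450–650 nm grid truncates one tail of the edge filters (470, 645 nm);
  the truncated shape is used identically by the forward model and the
  fit, so this is a definition, not an error source. A grid that misses
  a passband raises a domain-coverage error.
- The default bank — 470, 500, 520, 546, 560, 577, 600, 645 nm, FWHM
  20 nm, peak 0.9 — straddles the HbO₂/Hb difference features; it is a
  stand-in for real hardware and fully overridable via a YAML config
  (`read_filter_bank()`). Its design matrix has condition number ≈ 21,
  comfortably full rank.

The packaged extinction tables are **synthetic**: smooth closed-form
curves reproducing the qualitative structure of the standard
compilations (HbO₂ β/α peaks at 542/577 nm, the broad Hb peak at
555 nm, Hb ≫ HbO₂ beyond 600 nm, lipid/carotenoid absorption confined
to the blue end), normalised to a common relative scale. Measured tables
were not redistributable here; because every quantitative guarantee in
the package is a forward-model round trip through the *same* spectra,
all tests and acceptance quantities are unaffected by this substitution.
Users with a real instrument should load measured tables via
`read_extinction()`.

## Calibration

$R = (I_{raw}-I_{dark})/(I_{white}-I_{dark})$ per pixel and band, then
$A = -\log_{10}\max(R, r_{floor})$. Defaults: $r_{floor} = 10^{-4}$
(capping absorbance at 4, beyond the useful dynamic range of a 12-bit
sensor) and a minimum usable white-minus-dark signal of 1 count, below
which the pixel is flagged invalid rather than divided. Saturated pixels
are flagged when the sensor maximum is recorded in the metadata. White
correction is applied per pixel (strictly more general than per-band
means); no additional flat-field model is imposed beyond the white stack
itself.

## Fitting and fit quality

All pixels are fitted in one vectorised QR pass; a per-pixel reference
path (`fit_pixel`) exists for scrutiny and testing, and both are checked
against an independent normal-equations solver to $10^{-8}$ on $10^4$
random vectors. CoD is $1 - SS_{res}/SS_{tot}$ with $SS_{tot}$ about the
band mean of the pixel's own absorbance vector. A zero-variance
(constant) absorbance vector is given CoD 1 if its residual is also zero
(the offset alone explains it exactly) and 0 otherwise; "zero" is
$10^{-15}$ relative to the vector's energy, since exact float zeros
arise only for bitwise-constant input. Because the model contains an
intercept, CoD is clamped to $[0,1]$.

SO₂/THb derivation runs after the validity filter (filter-then-derive);
the order cannot change any valid pixel's value, only which pixels are
reported, and doing it in this order keeps zero-THb pixels (where SO₂ is
undefined) out of the valid set.

## Registration and temporal averaging

Acquisition bursts of ~3–5 s raise SNR by averaging but suffer
respiratory motion. Motion is modelled as a per-stack 2-D translation:
one shift is estimated on a single alignment band (by default the band
with the highest mean intensity) and applied to all bands of the stack,
since a full stack is acquired in ~0.3 s — fast relative to breathing.
Shifts are estimated by phase correlation with a matrix-multiply DFT
refinement on a 0.02 px grid around the integer peak; the contract
(integer shifts exact, subpixel within 0.1 px on band-limited content)
is what the tests pin down, not the algorithm. Warping uses bilinear
interpolation with `NA` outside coverage; the temporal average reports a
coverage mask and zeroes uncovered border pixels. Averaging $N$
independent-noise stacks reduces residual noise by $\approx\sqrt N$
(checked at $N = 6$ within ±15%), and registration restores step-edge
gradients that unregistered averaging blurs.

## Profiling

The segment axis is a user-defined line, subdivided into $n$ equal
**half-open** bins $[kL/n, (k+1)L/n)$; ROIs are rectangles centred on
bin midpoints, `roi_length` (default: the full bin) along the axis and
`roi_width` across it, clipped to the image. Half-open binning gives
deterministic boundary handling; the clinical decision position (cm) is
binned with the same rule, so e.g. 3.5 cm with 1 cm divisions lands in
ROI 4 and 0 cm in ROI 1. Quartiles use linear interpolation between
order statistics (R's default convention). The decision report compares
the decision ROI's median SO₂ against the median of the per-ROI medians
— a summary-level convention chosen so the report is computable from the
profile table alone. The physical scale `mm_per_pixel` is supplied by
configuration, not estimated from imagery.

Tissue masking is a configurable stage: a provided mask, global
thresholding (Otsu by default) with largest-connected-component
selection, or seeded watershed on the distance map of the thresholded
foreground (via EBImage).

## The phantom generator

`bowel_phantom()` builds a horizontal serosal tube whose axial SO₂
follows a per-division profile with uniform THb (default 1.0, since
relative units are only meaningful within a scene), a small positive
serosal fat fraction (0.1) and scattering offset (0.1), optionally
flanked by fat-rich strips (fat 0.8, THb 0.3 at 90% SO₂) emulating
mesenteric adipose tissue, over a zero-THb background. The axis length
is forced to a multiple of the division count so that division
boundaries fall exactly between pixel columns and phantom binning agrees
bit-for-bit with ROI binning. `forward_cube()` renders absorbance
through a fine-grid (0.1 nm) per-band convolution of the
wavelength-resolved spectra — a code path deliberately separate from
`build_design_matrix()` — then reflectance and detector counts.

The acquisition model adds multiplicative Gaussian noise
(σ = 1% of signal by default, a high-count shot-noise approximation; the
true counts-level noise of the clinical system is not derivable from
published information) and i.i.d. per-stack Gaussian translations
(σ = 2 px default, applied by exact Fourier resampling so registration
tests have a band-limited oracle; i.i.d. jitter was chosen over a slow
drift for a cleaner oracle). The first stack is the unshifted reference.
All stochastic outputs are seed-deterministic.

What the phantoms do *not* emulate: wavelength-dependent scattering,
specular highlights, vignetting, deformable motion, bile or brown fat,
depth-resolved light transport. Passing round trips therefore
demonstrate the correctness of the inverse pipeline under the model's
own assumptions, not robustness to every violation of them in vivo.

## Problem sizes and tolerances in the shipped tests

Round-trip profile checks run at 256×512 px with 10 divisions (each
pipeline completes in a few seconds); noise/stability checks at
128×256 and 64×64 with 10 acquisitions; registration checks on 48–64 px
squares. Noise-free recovery is asserted to $10^{-6}$ (observed at
machine precision), profile-table recovery to 0.05 percentage points,
subpixel registration to 0.1 px, and the acquisition-stability standard
deviation against a first-order delta-method prediction
$\mathrm{sd}(\overline{SO_2}) =
\sqrt{g^\top \Sigma g / n_{ROI}}$ with
$\Sigma = (\sigma/\ln 10)^2 (X^\top X)^{-1}$, within the sampling band
of a 9-d.f. standard-deviation estimate. That closed form is exact only
with zero dark level and strictly interior (all-positive) concentrations,
so the stability fixture uses `dark_level = 0` and fat 0.3.

## Known limitations

- Concentrations are relative; no absolute (mol/L) calibration is
  attempted or possible without pathlength and illumination control.
- Translation-only motion correction; rotation/deformation are out of
  scope (a rigid extension would slot into `register_sequence()`).
- The synthetic extinction tables preclude quantitative comparison of
  absolute concentration ratios against instruments using measured
  compilations; SO₂, being a ratio within the haemoglobin pair fitted
  with consistent spectra, is the robust output.
- The validity filter's negative-concentration rule biases noisy scenes
  with near-zero true fat (half of such pixels are excluded); phantoms
  for quantitative noise checks keep concentrations away from zero.
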