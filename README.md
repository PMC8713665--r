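# oximsi

Multispectral imaging (MSI) tissue oximetry for laparoscopic perfusion
assessment. During colorectal surgery the choice of where to transect the
bowel hinges on which segment is still well perfused; `oximsi` turns
eight-band visible-range image stacks from a filter-wheel MSI camera into
per-pixel maps of tissue oxygen saturation (SO₂) and total haemoglobin
(THb), and summarises the longitudinal SO₂ profile of a bowel segment so
it can be compared with the surgeon's decision.

## The model

Each pixel's base-10 absorbance spectrum, sampled through B = 8 Gaussian
passbands, is modelled with the modified Beer-Lambert law:

    A(λ) = [HbO₂]·ε_HbO₂(λ) + [Hb]·ε_Hb(λ) + [Fat]·ε_Fat(λ) + G

where the ε are chromophore extinction coefficients band-convolved with
each filter's transmission profile, the bracketed terms are relative
concentrations, and G is a wavelength-independent scattering offset.
Absorbance comes from dark-frame-subtracted, white-reference-normalised
reflectance, `A = −log₁₀ R` with
`R = (I_raw − I_dark)/(I_white − I_dark)`. The four coefficients are
estimated by unconstrained ordinary least squares at every pixel; pixels
with a coefficient of determination (CoD, r²) below 0.9 or any negative
concentration are excluded from quantitative analysis. Derived maps are
`THb = HbO₂ + Hb` and `SO₂ = 100·HbO₂/THb` (percent).

Around that core the package provides:

- **Calibration** — dark subtraction, white normalisation, absorbance
  conversion, with invalid-pixel (degenerate white, saturation) masks.
- **Registration** — subpixel phase-correlation translation estimation
  and motion-corrected temporal averaging of acquisition bursts.
- **Profiling** — perpendicular ROIs along a user-defined segment axis,
  tissue masking (threshold / watershed / provided), per-ROI SO₂
  statistics, acquisition-to-acquisition stability, and mapping of a
  clinical decision position onto the profile.
- **Validation** — colour-checker reflectance comparison against
  spectrometer-style ground-truth curves with a Bland-Altman summary.
- **Synthetic data** — a forward-model phantom generator (bowel segments
  with an axial SO₂ gradient, colour cards, noise and respiratory-like
  jitter) that makes every stage testable without clinical data.

The packaged extinction tables are smooth *synthetic* stand-ins with the
qualitative features of the standard haemoglobin/lipid compilations (see
`?packaged_spectra`); swap in measured tables with `read_extinction()`
for use with a real instrument.

## Worked example

A synthetic bowel segment whose axial SO₂ follows the first patient
column of the packaged profile table, acquired as a noisy jittered
six-stack burst, registered, averaged and unmixed:

```r
library(oximsi)

spectra <- packaged_spectra()
bank    <- default_filter_bank()
design  <- build_design_matrix(bank, list(spectra$hbo2, spectra$hb,
                                          spectra$fat))

tab   <- so2_profile_table()
scene <- bowel_phantom(tab$profiles[, "P1"])
acq   <- noisy_sequence(scene, acquisition_model(bank = bank,
                                                 n_stacks = 6, seed = 7))
reg   <- register_sequence(acq$sequence)
avg   <- temporal_average(reg$sequence)$cube
maps  <- unmix_stack(avg, acq$white, acq$dark, design)

spec <- profile_spec(scene$axis$start, scene$axis$end, n_divisions = 10,
                     roi_width = 80,
                     mm_per_pixel = 100 / scene$truth$axis_length_px)
prof <- profile_statistics(maps, build_rois(spec, scene$shape),
                           scene$tissue_mask)
head(round(prof, 2), 4)
#>   roi mean_so2 median_so2   q25   q75    n
#> 1   1    82.10      82.15 81.81 82.49 3483
#> 2   2    81.53      81.53 81.21 81.85 3483
#> 3   3    79.39      79.38 79.07 79.71 3483
#> 4   4    79.81      79.82 79.48 80.14 3483

decision_alignment(prof, tab$decisions_cm[["P1"]], spec)
#> decision at 3.5 cm -> ROI 4, above segment median: TRUE (margin 1.31 pp)
```

ROI 1 recovers the proximal ground-truth mean of 82.14% SO₂ to within
0.05 points despite 1% multiplicative noise and ~2 px inter-stack jitter;
the per-ROI interquartile ranges reflect the injected noise. On a
noise-free burst the recovery is exact to machine precision.

A shell front end with `simulate`, `unmix`, `average`, `profile` and
`validate` subcommands lives at `inst/cli/oximsi.R`
(`Rscript $(Rscript -e 'cat(system.file("cli","oximsi.R",package="oximsi"))') unmix --help-style usage in the file header`).

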