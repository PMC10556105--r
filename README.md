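# rcfdose

Two-dimensional radiochromic-film dosimetry in R: a forward simulator of
film irradiation and of two readout devices, plus the inverse pipeline that
turns raw readings into absolute dose.

Radiochromic films (EBT3-type) are a gold-standard passive detector for
quality assurance in radiotherapy: their active layer polymerizes and
darkens in proportion to absorbed dose over roughly 0.2–10 Gy. The film's
signal is the net optical density,

    netOD = OD_after − OD_before = −log10(I / I0),

where `I0` and `I` are the intensities transmitted through the unexposed and
irradiated film. Absolute dose comes from a fifth-order polynomial
calibration `netOD(D)` fitted on films at known doses and inverted
numerically (the fit is rejected unless strictly monotone, so the inversion
is unique). Two readouts are modelled end to end:

* **scanner branch** — flatbed transmission scans (red channel), per-pixel
  netOD maps, ROI statistics;
* **LDR-array branch** — a 5×10 matrix of 5 mm photoresistors read through
  green LEDs and a multiplexed 12-bit ADC; each of the 20 participating
  LDRs gets its own quintic count(dose) calibration, collapsed onto a
  reference LDR by a matrix of scalar conversion factors, so unknown doses
  are recovered in situ from ADC counts.

The irradiation side models a 60 kVp X-ray tube — inverse-square-like output
`Dose(mGy) = 138251·(SSD − D′)^−2.003`, a filtered Kramers bremsstrahlung
spectrum, a field with up to 20% OD dispersion — and a homogeneous 137Cs
source (4.05 Gy/min, <4% dispersion), plus PMMA and aluminium staircase
phantoms whose spectrum-weighted Beer–Lambert transmission ratios imprint
dose steps on the film. See the methods vignette
(`vignettes/film-dosimetry.Rmd`) for every model, default and limitation.

## Worked example

```r
library(rcfdose)

# scanner branch: calibrate on 9 synthetic films (0.2-8 Gy, X-ray field),
# then recover a 0.60 Gy validation film
cal <- makeScannerCalibration(seed = 1)
cal$curve
#> CalibrationCurve (degree 5, increasing): dose range [0.2, 8] Gy,
#>   9 points, residual RMS 1.46e-05
v <- runScannerValidation(0.60, cal, seed = 2)
sprintf("%.3f +/- %.3f Gy", v$mean, v$sd)
#> "0.600 +/- 0.028 Gy"

# aluminium staircase at 3 Gy nominal: three dose plateaus and their ratios
fx <- makeFixtures("al_stairs", seed = 1)
tb <- stepAnalysis(fx$film$od, fx$phantom, fx$background$od,
                   curve = fx$scanner$curve, zones = 3)
mid <- tb[tb$zone == "middle", ]
doseRatioTable(mid, referenceDose = mid$mean_dose_gy[mid$step_id == 1])
#>   step_id step_height_mm mean_dose_gy   sd_gy ratio
#>         1              0         3.00 0.05800  1.00
#>         2              3         1.05 0.01715  2.85
#>         3              6         0.52 0.00786  5.78

# the LDR array detects the film orientation from the step pattern
detectOrientation(fx$frames$`R+90`, fx$moem$cal, fx$phantom,
                  beam = fx$beam)$orientation
#> "R+90"
```

The three staircase plateaus (3.00, 1.05, 0.52 Gy) are what makes the
aluminium wedge readable as exactly three zones; the ratio column is the
attenuation figure the staircase experiments report. The 60 kV preset beam
has a first half-value layer of 1.80 mm Al and transmission ratios 1.55
(10 mm PMMA), 2.85 (3 mm Al) and 5.81 (6 mm Al) under dose-response
weighting:

```r
sp <- beamSpectrum(beamPreset("xray_60kv"))
halfValueLayer(sp)                              # 1.80
transmissionRatio(sp, "Al", c(3, 6), "dose")    # 2.85  5.81
```

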