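---
title: "Radiochromic-film dosimetry: models, simulators and the inverse pipeline"
author: "rcfdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiochromic-film dosimetry: models, simulators and the inverse pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcfdose)
```

## The measurement problem

Radiochromic films (EBT3-type) darken in proportion to absorbed dose: the
active layer polymerizes under ionizing radiation and the film's optical
density rises. They are a routine quality-assurance detector in
radiotherapy, with an optimal range of roughly 0.2–10 Gy. The film's signal
is the *net optical density*,

$$\mathrm{netOD} = OD_{after} - OD_{before} = -\log_{10}\!\left(\frac{I}{I_0}\right),$$

the base-10 log ratio of the light transmitted through the unexposed control
($I_0$) and the irradiated film ($I$). Two readout devices are modelled end
to end:

* a flatbed transmission **scanner** (red channel, the standard protocol up
  to 8 Gy), which produces a full-resolution netOD map; and
* a **photodetector array**: 5×10 light-dependent resistors (LDRs, 5 mm
  diameter) read through green LEDs and a multiplexed 12-bit ADC, which
  trades spatial resolution for an immediate, in-situ dose value per LDR.

`rcfdose` contains both a *forward* simulator (irradiation and both
readouts) and the *inverse* pipeline (calibration, dose reconstruction,
staircase-phantom analysis, orientation detection). The forward model's
parameters are never visible to the inverse side: calibration is always
learned from generated exposures.

## Film response and calibration

The generator's dose→netOD law is a saturating rational plus a linear term,

$$\mathrm{netOD}(D) = \frac{aD}{1 + bD} + cD,$$

strictly increasing with netOD(0) = 0. The published literature fits
calibration *points* with polynomials and never states a functional form, so
this choice is deliberately different from the calibration family. Defaults:
`scanner_red` (a = 0.14 /Gy, b = 0.12 /Gy, c = 0.005 /Gy, netOD(8 Gy) ≈
0.61, mimicking typical EBT3 red-channel behaviour) and `led_green`
(a = 0.10, b = 0.10, c = 0.004, slightly less sensitive).

Calibration follows the field's standard: a least-squares **fifth-order
polynomial of signal versus dose**, fitted with `fitCalibration()` on at
least 7 distinct dose points. Two design choices matter:

* **Direction.** The fit is signal(dose), as calibration data are plotted,
  and dose is recovered by numerical inversion (`invertCalibration()`,
  bracketed root finding to 1e-9 Gy; map-sized inputs use a 4096-point
  monotone interpolation grid whose error is far below 1e-4 Gy). Fitting
  dose(signal) instead would discard the guarantee of a single monotone
  branch.
* **Monotonicity guard.** A quintic can oscillate. Fits that are not
  strictly monotone over the fitted range are rejected outright with advice
  to sample more densely — silently inverting the wrong branch would be
  worse than failing.

Signals within 3× the fit's residual RMS of a boundary are clamped to the
boundary rather than masked: a zero-dose film must not be censored just
because the fitted intercept is off by its own residual. Everything further
out is masked (NA) and counted, never clamped.

## The X-ray source

The tube's output follows the machine-calibration power law
$\mathrm{Dose(mGy)} = A\,(SSD - D')^{-p}$ per unit calibration time, with
defaults $A = 138251$, $p = 2.003$ and distances in mm (all the modelled
set-up's distances are quoted in mm; the calibration time base is taken as
the unit exposure since the source law is linear in time).
`estimateOffset()` recovers the offset $D'$ in closed form from dose rates
at two distinct SSDs.

The energy spectrum is **filtered Kramers bremsstrahlung**: fluence weights
$\propto (kVp - E)/E$ on a 1 keV grid from 5 keV, multiplied by
$e^{-\mu_{Al}(E)\,t}$ for the aluminium filtration, with no characteristic
lines (tungsten K lines sit above 59 keV and are negligible at 60 kVp).
Mass attenuation coefficients for Al and PMMA (and the mass energy-absorption
coefficient of water) are bundled as a small table of standard published
values on a 5–100 keV grid, interpolated log-log.

Bare Kramers is too soft to represent a real thick-target tube: its
dose-weighted first half-value layer at 60 kVp with 1.3 mm added Al comes
out at 1.44 mm Al, whereas measured 60 kVp beams at comparable filtration
show roughly 1.7–2.0 mm. The 60 kV preset therefore carries an **effective
anode self-filtration** parameter (default 1.25 mm Al-equivalent), chosen so
that the preset beam's first HVL is 1.8 mm Al — a representative measured
value, checkable with `halfValueLayer(beamSpectrum(...))`. This is a
documented approximation, not a claim of spectral fidelity.

`transmissionRatio()` computes the staircase attenuation figure: the ratio
of detector-weighted fluence without and with a slab,
$\sum w\,r / \sum w\,r\,e^{-\mu t}$. The default weight is flat ($r = 1$, a
pure fluence ratio); `responseWeighting = "dose"` uses
$r(E) = E\,\mu_{en}/\rho(E)$ of water, the fluence-to-dose conversion of a
water-equivalent detector, and is what the simulator uses wherever an
absorbed-dose ratio is formed. **Limitation:** this is a narrow-beam model.
It carries no scattered photons, so it stands in for full photon transport
only within a stated tolerance (±10% covers the bundled reference ratios);
scatter buildup behind thick absorbers is exactly the effect it omits.

## Field inhomogeneity

The tube cannot irradiate a large area uniformly: the modelled field shows
up to 20% maximum OD dispersion (the statistic
$100\,|netOD - netOD_\mu|/netOD_\mu$ about the film mean), with the
intensity maximum displaced off-centre; the 137Cs irradiator is nearly flat
(preset target 3.5%, below the 4% the homogeneous source exhibits).
`inhomogeneityField()` builds a multiplicative surface — a quadratic
fall-off around a configurable off-centre peak plus smooth seeded noise —
centred to mean exactly 1 and rescaled so the maximum dispersion *equals*
the target. The whole pattern (including its rough component) is a fixed
property of the `BeamModel` (`fieldSeed`), because the field belongs to the
machine; per-exposure variability enters through readout noise
(multiplicative per-pixel netOD noise, default sd 1%). Consequently two
seeds give identical dose maps and different noise realizations.

## The LDR array

Each analog stage is an explicit, monotone map:

1. **LED drive**: 256 digital steps spanning 0–3 V (`ledVoltage()`);
   uniform illumination when all nine LEDs share one drive level.
2. **Photoresistance**: $R = R_0\,\mathrm{light}^{-\gamma}$ with
   $\gamma = 0.8$ and $R_0 = 10\,k\Omega$ — inversely proportional to light
   for $\gamma = 1$; the exact transfer is irrelevant downstream because
   calibration absorbs it.
3. **Divider and amplifier**: a fixed divider
   $V = V_{cc} R_{fix}/(R_{fix} + R)$ followed by an affine amplifier
   $V = g\,(V_{div} - V_{off})$. `tuneGain()` performs the two-point gain
   setting used in practice: noiseless 0 and 10 Gy films map to 85% and 5%
   of full scale, so the digitized values of films from 0 to 10 Gy cover
   the ADC range without clipping even at the extremes of the manufacturing
   spread.
4. **ADC**: $\lfloor 4096\,V/V_{ref}\rfloor$ clamped to 0–4095 (a 12-bit
   converter has 4096 codes). Each LDR is read `nReads` times with
   multiplicative glitch noise (default sd 1% per read; LDRs #19 and #20
   get 5× that, emulating their anomalously noisy channels) and the average
   is stored.

Manufacturing differences are a per-LDR multiplicative **gain spread**
(seeded, ±10%). A spread on $\gamma$ is available but defaults to zero: it
changes curve *shapes*, and then scalar conversion factors can only collapse
the calibration curves approximately.

**Geometry.** The film sees the array as its specular image: columns are
left-right mirrored (`mirrorIndex()`, an involution). Twenty LDRs
participate in film experiments; since twenty 5 mm detectors cannot tile a
3×3 cm film as 2×10, the participating block is rows 1–4 × columns 1–5
(bounding box ≈ 30×24 mm at 6 mm pitch), numbered row-major in multiplexer
scan order, with the noisy pair #19/#20 at the block's end. Each LDR
integrates the mean transmission $10^{-netOD}$ over its circular 5 mm
footprint; footprints clipped by the film edge are flagged `boundary`.

**Quantization bound.** With all noise off, calibrating and re-reading a
film at a calibration dose is the identity only up to the ADC code width
divided by the local slope of the count–dose curve — about 5e-3 Gy at the
shallow high-dose end, which is what the identity tests assert (~0.015 Gy
bound), not machine precision.

## Per-LDR calibration and the conversion-factor matrix

`calibrateLDRs()` fits one decreasing quintic count(dose) per LDR, then
computes one **scalar conversion factor** per LDR: the least-squares
multiplier that collapses its fitted curve onto the reference LDR's curve
over a dense common dose grid (reference factor exactly 1). Fitting happens
first, normalization second. A scalar per LDR is the simplest reading of a
conversion-factor matrix and is exact for gain-like manufacturing spread;
shape differences would need per-dose factors, which nothing here motivates.
`adcToDose()` then normalizes counts and inverts the *reference* curve,
flagging out-of-range counts per LDR instead of failing. Calibration frames
average 32 reads (routine frames 8): deeper averaging where it matters,
since a non-monotone fit on a noisy channel would abort the calibration.

## Staircase analysis, ratios, orientation

PMMA (six 5 mm steps, 1–5 then 10 mm high) and aluminium (12 mm zones of
0/3/6 mm) staircases imprint dose steps on a 3 Gy film. Analysis divides the
measurement by the *relative* field of a background exposure at the same
nominal dose without the phantom — in OD space for the scanner branch,
which removes the field inhomogeneity before the nonlinear dose conversion
can bias the steps (the LDR branch, which never observes OD, applies the
relative correction to converted doses; at 20 samples the difference is
second-order). Step averages use the central 60% of each step's width to
avoid penumbra, optionally split into three horizontal zones (top, middle,
bottom). `doseRatioTable()` reports reference/step ratios rounded to 2
decimals while keeping full precision.

`detectOrientation()` exploits the staircase asymmetry: each candidate
orientation (steps along x for `R`, along y for `R+90`) predicts a per-LDR
relative dose pattern from the phantom geometry and spectrum; the scale is
estimated robustly (median of observed/relative) unless a nominal dose is
given, and the orientation with the smaller summed absolute mismatch wins.
No phantom, a single-height phantom, or scores within 10% of each other
return `"undetermined"` with a diagnostic rather than a guess.

## Study conditions and problem sizes

The synthetic experiments default to the modelled protocols: X-ray
calibrations span 0.2–8 Gy (9 films), 137Cs 0.2–4 Gy (9 frames), staircase
films at a nominal 3 Gy, validation films at 0.6 and 1.5 Gy. Films are
simulated at 0.5 mm pitch for 40×40 mm scanner films (80×80 pixels) and for
the array-sized films (the participating block plus margin) — enough pixels
that footprint averaging and ROI statistics are smooth, while a full
calibration-plus-validation run stays around a second. All randomness flows
from one integer seed per generated artifact through derived sub-seeds.

## What the synthetic data do and do not show

The generator reproduces the measured orders of magnitude: field dispersion
(20% / <4%), netOD scale, staircase attenuation, LDR spread, ADC range and
glitch noise. It does **not** model photon scatter or buildup, film
post-irradiation darkening kinetics (all readings are implicitly at the
same post-exposure time), multi-channel (RGB) dosimetry, film-to-film
sensitivity drift, positioning error, or temperature effects. Passing tests
therefore demonstrate the *pipeline's* correctness and internal consistency
under realistic noise — not that the simulator would predict a particular
real film's reading.

## Numerical choices, collected

* Root finding: `uniroot` at 1e-9 Gy; map inversion on a 4096-point
  monotone grid; boundary clamp at 3× residual RMS.
* Monotonicity checks on 513-point grids; strictly monotone required.
* Conversion factors: closed-form least squares
  $f_i = \sum c_{ref} c_i / \sum c_i^2$ on a 200-point dose grid.
* Orientation tie threshold: 10% relative score difference.
* Degenerate inputs: zero dispersion target returns the exactly flat field;
  zero thickness returns ratio exactly 1; netOD maps tolerate noise down to
  −0.05 and are clamped only at reporting time (TIFF export).
* Float TIFF maps are stored normalized with the scale factor recorded in
  the summary, because 32-bit TIFF storage is only defined on [0, 1].
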