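#' @include filmModel.R
NULL

## ---------------------------------------------------------------------------
## Map constructors
## ---------------------------------------------------------------------------

#' Construct film-coordinate maps
#'
#' @param values numeric matrix (rows = y, columns = x).
#' @param pixelPitch mm/pixel.
#' @param origin film-frame (x, y) of element (1,1), mm.
#' @return an [ODMap-class] / [DoseMap-class].
#' @name map-constructors
#' @export
odMap <- function(values, pixelPitch, origin = c(0, 0)) {
  new("ODMap", values = as.matrix(values), pixelPitch = pixelPitch,
      origin = origin)
}

#' @rdname map-constructors
#' @export
doseMap <- function(values, pixelPitch, origin = c(0, 0)) {
  new("DoseMap", values = as.matrix(values), pixelPitch = pixelPitch,
      origin = origin)
}

## ---------------------------------------------------------------------------
## Source model
## ---------------------------------------------------------------------------

#' Beam model presets and constructor
#'
#' `"xray_60kv"` is the kilovoltage tube: output
#' `Dose(mGy) = 138251 (SSD - D')^-2.003` per unit calibration time at
#' 60 kVp with 1.3 mm added Al filtration, plus an effective anode
#' self-filtration (default 1.25 mm Al-equivalent, set so the simulated
#' beam's first half-value layer is ~1.8 mm Al, representative of measured
#' 60 kVp beams at this filtration); its field carries up to 20% OD
#' dispersion with an off-centre intensity maximum. `"cs137"` is the
#' homogeneous 137Cs irradiator at 4.05 Gy/min with <4% field dispersion.
#'
#' @param preset "xray_60kv" or "cs137".
#' @param ... named overrides for any slot of [BeamModel-class].
#' @return a [BeamModel-class].
#' @examples beamPreset("xray_60kv")
#' @export
beamPreset <- function(preset = c("xray_60kv", "cs137"), ...) {
  preset <- match.arg(preset)
  def <- switch(preset,
    xray_60kv = list(amplitudeA = 138251, exponentP = 2.003,
                     offsetDprime = 0, kvp = 60, filtrationMmAl = 1.3,
                     selfFiltrationMmAl = 1.25, fieldDispersionTarget = 20,
                     sourceType = "xray_tube", csDoseRate = 4.05,
                     fieldPeakOffset = c(0.2, 0.1), fieldSeed = 73L),
    cs137 = list(amplitudeA = 138251, exponentP = 2.003, offsetDprime = 0,
                 kvp = 60, filtrationMmAl = 1.3, selfFiltrationMmAl = 1.25,
                 fieldDispersionTarget = 3.5, sourceType = "cs137",
                 csDoseRate = 4.05, fieldPeakOffset = c(0, 0),
                 fieldSeed = 73L))
  args <- modifyList(def, list(...))
  do.call(new, c(list("BeamModel"), args))
}

#' Dose delivered at a source-to-surface distance
#'
#' Inverse-square-like machine calibration `A (SSD - D')^-p`, scaled
#' linearly by exposure time relative to the calibration time base (the
#' tube's dose rate is constant).
#'
#' @param ssd source-to-surface distance, mm; must exceed the offset D'.
#' @param beam a [BeamModel-class].
#' @param time exposure time (same unit as `timeBase`).
#' @param timeBase calibration time base.
#' @return dose in mGy.
#' @examples doseAtSSD(79.5, beamPreset("xray_60kv"))   # 21.59 mGy
#' @export
doseAtSSD <- function(ssd, beam, time = 1, timeBase = 1) {
  stopifnot(is(beam, "BeamModel"))
  if (any(ssd <= beam@offsetDprime))
    stop("SSD must exceed the offset D' = ", beam@offsetDprime, " mm",
         call. = FALSE)
  beam@amplitudeA * (ssd - beam@offsetDprime)^(-beam@exponentP) *
    (time / timeBase)
}

#' Estimate the source-position offset D'
#'
#' Given dose rates measured at two distinct SSDs, solves
#' `(SSD1 - D') / (SSD2 - D') = (rate2 / rate1)^(1/p)` for D'.
#'
#' @param meas1,meas2 numeric c(ssd_mm, dose_rate); rates > 0, SSDs distinct.
#' @param exponentP the power-law exponent p.
#' @return D' in mm (always below both SSDs).
#' @export
estimateOffset <- function(meas1, meas2, exponentP = 2.003) {
  s1 <- meas1[1]; r1 <- meas1[2]; s2 <- meas2[1]; r2 <- meas2[2]
  if (s1 == s2) stop("the two SSDs must be distinct", call. = FALSE)
  if (r1 <= 0 || r2 <= 0) stop("dose rates must be positive", call. = FALSE)
  k <- (r2 / r1)^(1 / exponentP)
  if (abs(k - 1) < 1e-12)
    stop("equal dose rates at distinct SSDs are impossible under a ",
         "decaying power law; no offset exists", call. = FALSE)
  dprime <- (s1 - k * s2) / (1 - k)
  if (dprime >= min(s1, s2))
    stop(sprintf(
      "inconsistent rates: implied D' = %.4g mm is not below both SSDs",
      dprime), call. = FALSE)
  dprime
}

## ---------------------------------------------------------------------------
## Spectrum and attenuation
## ---------------------------------------------------------------------------

#' Filtered bremsstrahlung spectrum
#'
#' Kramers-form fluence weights proportional to `(kvp - E)/E` on a 1 keV
#' grid from 5 keV to kvp, attenuated by `exp(-mu_Al(E) t)` for the given
#' aluminium filtration and normalized to unit sum. Tungsten characteristic
#' lines are omitted (the K lines sit above 59 keV and carry negligible
#' fluence at 60 kVp).
#'
#' @param kvp tube voltage, 20-90 kV (the tube's operating range).
#' @param filtrationMmAl total aluminium filtration, mm.
#' @return a [Spectrum-class].
#' @export
xraySpectrum <- function(kvp, filtrationMmAl = 0) {
  if (kvp < 20 || kvp > 90)
    stop("kvp must be within the tube's 20-90 kV range", call. = FALSE)
  if (filtrationMmAl < 0) stop("filtration must be >= 0", call. = FALSE)
  e <- seq(5, kvp, by = 1)
  if (e[length(e)] < kvp) e <- c(e, kvp)
  w <- (kvp - e) / e
  if (filtrationMmAl > 0)
    w <- w * exp(-linearAttenuation("Al", e) * filtrationMmAl / 10)
  new("Spectrum", energies = e, weights = w / sum(w), kvp = kvp)
}

#' Spectrum of a beam model
#'
#' The beam's filtered bremsstrahlung spectrum: added filtration plus the
#' effective anode self-filtration.
#'
#' @param beam a [BeamModel-class] with `sourceType = "xray_tube"`.
#' @return a [Spectrum-class].
#' @export
beamSpectrum <- function(beam) {
  stopifnot(is(beam, "BeamModel"))
  xraySpectrum(beam@kvp, beam@filtrationMmAl + beam@selfFiltrationMmAl)
}

#' Spectrum-weighted transmission (dose) ratio through an attenuator
#'
#' Ratio of detector-weighted fluence without and with an attenuating slab:
#' `sum(w r) / sum(w r exp(-mu t))`, always >= 1. With
#' `responseWeighting = "flat"` the detector weight r(E) is 1 (a pure
#' fluence ratio); with `"dose"` it is `E * mu_en/rho(E)` of water, the
#' fluence-to-dose conversion of a water-equivalent detector, which is the
#' appropriate weight when the quantity of interest is an absorbed-dose
#' ratio. This narrow-beam model carries no scattered photons, so it stands
#' in for full transport with a stated tolerance rather than exactly.
#'
#' @param spectrum a [Spectrum-class].
#' @param material "Al" or "PMMA".
#' @param thickness slab thickness(es), mm, >= 0.
#' @param responseWeighting "flat" or "dose".
#' @return dimensionless ratio(s) >= 1, one per thickness.
#' @export
transmissionRatio <- function(spectrum, material, thickness,
                              responseWeighting = c("flat", "dose")) {
  stopifnot(is(spectrum, "Spectrum"))
  responseWeighting <- match.arg(responseWeighting)
  if (any(thickness < 0)) stop("thickness must be >= 0", call. = FALSE)
  e <- spectrum@energies
  r <- switch(responseWeighting, flat = rep(1, length(e)),
              dose = e * waterMuEn(e))
  w <- spectrum@weights * r
  mu <- linearAttenuation(material, e)
  vapply(thickness, function(t) sum(w) / sum(w * exp(-mu * t / 10)),
         numeric(1))
}

#' First half-value layer of a spectrum
#'
#' Thickness of material halving the dose-weighted transmitted beam; the
#' quantity the beam preset's effective self-filtration is matched to.
#'
#' @inheritParams transmissionRatio
#' @return thickness in mm.
#' @export
halfValueLayer <- function(spectrum, material = "Al",
                           responseWeighting = "dose") {
  uniroot(function(t)
    transmissionRatio(spectrum, material, t, responseWeighting) - 2,
    interval = c(1e-3, 50), tol = 1e-8)$root
}

## ---------------------------------------------------------------------------
## Staircase phantoms
## ---------------------------------------------------------------------------

#' Staircase phantom presets and constructor
#'
#' `"pmma_stairs"`: six PMMA steps, 5 mm wide at 5 mm pitch, heights 1-5 mm
#' then 10 mm. `"al_stairs"`: three 12 mm aluminium zones of height 0, 3 and
#' 6 mm (the open zone is the in-film reference).
#'
#' @param preset preset name.
#' @param ... overrides for [StaircasePhantom-class] slots.
#' @return a [StaircasePhantom-class].
#' @export
phantomPreset <- function(preset = c("pmma_stairs", "al_stairs"), ...) {
  preset <- match.arg(preset)
  def <- switch(preset,
    pmma_stairs = list(material = "PMMA", widths = rep(5, 6),
                       heights = c(1, 2, 3, 4, 5, 10), pitch = 5,
                       orientation = "x"),
    al_stairs = list(material = "Al", widths = rep(12, 3),
                     heights = c(0, 3, 6), pitch = 12, orientation = "x"))
  args <- modifyList(def, list(...))
  do.call(new, c(list("StaircasePhantom"), args))
}

# staircase extent along its axis, mm
phantomExtent <- function(phantom) {
  (length(phantom@widths) - 1) * phantom@pitch +
    phantom@widths[length(phantom@widths)]
}

#' Step index at a film coordinate
#'
#' Which step covers position `pos` (mm along the staircase axis, measured
#' from the staircase origin); NA outside all steps (including gaps when the
#' pitch exceeds the width).
#'
#' @param phantom a [StaircasePhantom-class].
#' @param pos positions, mm.
#' @return integer step indices (NA where uncovered).
#' @export
stepIndexAt <- function(phantom, pos) {
  starts <- (seq_along(phantom@widths) - 1) * phantom@pitch
  idx <- rep(NA_integer_, length(pos))
  for (k in seq_along(starts)) {
    inside <- pos >= starts[k] & pos < starts[k] + phantom@widths[k]
    idx[inside] <- k
  }
  idx
}

# per-step dose ratios for a phantom under a beam (ratio 1 for open steps
# and for positions not covered by the staircase)
phantomStepRatios <- function(phantom, beam,
                              responseWeighting = "dose") {
  if (beam@sourceType != "xray_tube")
    stop("staircase attenuation is modelled for the X-ray tube only",
         call. = FALSE)
  sp <- beamSpectrum(beam)
  vapply(phantom@heights, function(h)
    if (h == 0) 1 else transmissionRatio(sp, phantom@material, h,
                                         responseWeighting), numeric(1))
}

## ---------------------------------------------------------------------------
## Field inhomogeneity
## ---------------------------------------------------------------------------

# bilinear upsample of a coarse matrix onto nr x nc
bilinearUpsample <- function(m, nr, nc) {
  ri <- seq(1, nrow(m), length.out = nr)
  ci <- seq(1, ncol(m), length.out = nc)
  rows <- t(vapply(seq_len(nrow(m)), function(i)
    approx(seq_len(ncol(m)), m[i, ], xout = ci)$y, numeric(nc)))
  vapply(seq_len(nc), function(j)
    approx(seq_len(nrow(m)), rows[, j], xout = ri)$y, numeric(nr))
}

#' Relative field-inhomogeneity surface
#'
#' A smooth low-order 2-D surface (quadratic fall-off around an off-centre
#' maximum, emulating the displaced beam-intensity maximum of the tube) plus
#' seeded smooth noise, centred to mean exactly 1 and rescaled so that the
#' maximum percent dispersion about the mean equals `dispersionTarget`
#' exactly. A target of 0 returns the flat field.
#'
#' @param shape c(nrow, ncol) of the grid.
#' @param pixelPitch mm/pixel (geometry metadata only).
#' @param dispersionTarget maximum percent dispersion about the mean, >= 0.
#' @param seed integer seed for the noise component.
#' @param peakOffset (x, y) offset of the surface maximum from the grid
#'   centre, as a fraction of the grid size.
#' @return numeric matrix with mean 1.
#' @export
inhomogeneityField <- function(shape, pixelPitch = 1, dispersionTarget = 0,
                               seed = 1L, peakOffset = c(0, 0)) {
  if (dispersionTarget < 0) stop("dispersionTarget must be >= 0", call. = FALSE)
  nr <- shape[1]; nc <- shape[2]
  if (dispersionTarget == 0) return(matrix(1, nr, nc))
  x <- if (nc > 1) seq(-0.5, 0.5, length.out = nc) else 0
  y <- if (nr > 1) seq(-0.5, 0.5, length.out = nr) else 0
  surf <- -outer((y - peakOffset[2])^2, (x - peakOffset[1])^2, `+`)
  noise <- withSeed(seed, bilinearUpsample(matrix(rnorm(36), 6, 6), nr, nc))
  g <- surf + 0.15 * (max(surf) - min(surf)) * noise
  g <- g - mean(g)
  field <- 1 + (dispersionTarget / 100) * g / max(abs(g))
  field
}

## ---------------------------------------------------------------------------
## Synthetic irradiation
## ---------------------------------------------------------------------------

#' Simulate irradiation of a film
#'
#' Builds the absorbed-dose map of a film irradiated at a nominal dose --
#' nominal dose times the beam's inhomogeneity field, divided per pixel by
#' the staircase step's transmission ratio where a phantom covers the film --
#' and the film's netOD map through the forward response, with seeded
#' multiplicative readout noise on the netOD. The whole inhomogeneity
#' pattern (smooth surface plus its rough component) is a fixed property of
#' the beam; only the per-pixel readout noise varies between seeds, so two
#' seeds give identical mean doses but different noise realizations.
#'
#' @param nominalDose nominal delivered dose, Gy (>= 0).
#' @param beam a [BeamModel-class].
#' @param phantom optional [StaircasePhantom-class] placed with its first
#'   step at the film origin, steps advancing along the phantom's axis.
#' @param filmSize c(width, height) of the film, mm.
#' @param response a [FilmResponse-class].
#' @param seed integer seed.
#' @param pixelPitch simulated grid pitch, mm/pixel.
#' @param odNoiseSd relative sd of multiplicative per-pixel netOD noise.
#' @return list with `dose` (a [DoseField-class]) and `od` (an [ODMap-class]).
#' @export
irradiateFilm <- function(nominalDose, beam, phantom = NULL,
                          filmSize = c(40, 40), response = filmResponse(),
                          seed = 1L, pixelPitch = 0.25, odNoiseSd = 0.01) {
  stopifnot(is(beam, "BeamModel"), is(response, "FilmResponse"))
  if (nominalDose < 0) stop("nominalDose must be >= 0", call. = FALSE)
  nc <- max(1L, round(filmSize[1] / pixelPitch))
  nr <- max(1L, round(filmSize[2] / pixelPitch))
  field <- inhomogeneityField(c(nr, nc), pixelPitch,
                              beam@fieldDispersionTarget,
                              seed = beam@fieldSeed,
                              peakOffset = beam@fieldPeakOffset)
  dose <- nominalDose * field
  if (!is.null(phantom)) {
    stopifnot(is(phantom, "StaircasePhantom"))
    ext <- phantomExtent(phantom)
    along <- if (phantom@orientation == "x") filmSize[1] else filmSize[2]
    if (ext > along + 1e-9)
      stop(sprintf(
        "staircase extent (%g mm) exceeds the film %s-size (%g mm)",
        ext, phantom@orientation, along), call. = FALSE)
    ratios <- phantomStepRatios(phantom, beam)
    pos <- if (phantom@orientation == "x")
      (seq_len(nc) - 0.5) * pixelPitch else (seq_len(nr) - 0.5) * pixelPitch
    step <- stepIndexAt(phantom, pos)
    r <- ifelse(is.na(step), 1, ratios[step])
    dose <- if (phantom@orientation == "x")
      sweep(dose, 2, r, `/`) else sweep(dose, 1, r, `/`)
  }
  od <- doseToNetOD(dose, response)
  if (odNoiseSd > 0)
    od <- od * withSeed(subSeed(seed, 2),
                        matrix(1 + rnorm(nr * nc, 0, odNoiseSd), nr, nc))
  list(dose = new("DoseField", values = dose, pixelPitch = pixelPitch,
                  origin = c(0, 0), nominalDose = nominalDose,
                  seed = as.integer(seed)),
       od = odMap(pmax(od, -0.049), pixelPitch))
}
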