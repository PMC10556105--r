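#' @include utils.R
NULL

## ---------------------------------------------------------------------------
## 2-D maps on film coordinates
## ---------------------------------------------------------------------------

#' Virtual parent for 2-D maps on film coordinates
#'
#' A `FilmGrid` holds a numeric matrix on a regular grid in the film frame
#' (row-major, origin top-left) together with the pixel pitch in mm and the
#' film-frame coordinates of element (1,1).
#'
#' @slot values numeric matrix.
#' @slot pixelPitch pixel pitch, mm/pixel (> 0).
#' @slot origin film-frame (x, y) of the first grid element, mm.
#' @name FilmGrid-class
#' @aliases FilmGrid
#' @exportClass FilmGrid
setClass("FilmGrid", representation("VIRTUAL",
  values = "matrix", pixelPitch = "numeric", origin = "numeric"))

validFilmGrid <- function(object) {
  msg <- NULL
  v <- object@values
  if (!is.numeric(v) || length(dim(v)) != 2L || any(dim(v) < 1L))
    msg <- c(msg, "values must be a numeric matrix with dimensions >= 1x1")
  else if (!all(is.finite(v)))
    msg <- c(msg, "values must be finite everywhere")
  if (length(object@pixelPitch) != 1L || !is.finite(object@pixelPitch) ||
      object@pixelPitch <= 0)
    msg <- c(msg, "pixelPitch must be a single positive number")
  if (length(object@origin) != 2L || !all(is.finite(object@origin)))
    msg <- c(msg, "origin must be numeric of length 2")
  if (is.null(msg)) TRUE else msg
}

#' Net optical density map
#'
#' 2-D grid of netOD values on film coordinates. Small negative values are
#' allowed (down to -0.05) so readout noise is never silently clamped inside
#' arithmetic; clamping happens only at reporting time.
#'
#' @name ODMap-class
#' @aliases ODMap
#' @exportClass ODMap
setClass("ODMap", contains = "FilmGrid", validity = function(object) {
  v <- validFilmGrid(object)
  if (!isTRUE(v)) return(v)
  if (any(object@values < -0.05))
    return("netOD values below -0.05 are not plausible readout noise")
  TRUE
})

#' Absolute dose map (Gy)
#'
#' Masked pixels (saturated or outside the calibrated range) are NA.
#'
#' @name DoseMap-class
#' @aliases DoseMap
#' @exportClass DoseMap
setClass("DoseMap", contains = "FilmGrid", validity = function(object) {
  v <- object@values
  if (!is.numeric(v) || length(dim(v)) != 2L || any(dim(v) < 1L))
    return("values must be a numeric matrix with dimensions >= 1x1")
  if (any(is.infinite(v)))
    return("dose values must be finite or NA")
  if (any(v < 0, na.rm = TRUE)) return("dose values must be >= 0")
  if (length(object@pixelPitch) != 1L || object@pixelPitch <= 0)
    return("pixelPitch must be a single positive number")
  TRUE
})

#' Simulated dose field
#'
#' A [DoseMap-class] carrying the nominal dose and the seed it was generated
#' from, so any synthetic field is reproducible from `(model, seed)`.
#'
#' @slot nominalDose nominal delivered dose, Gy.
#' @slot seed integer seed of the generating draw.
#' @name DoseField-class
#' @aliases DoseField
#' @exportClass DoseField
setClass("DoseField", contains = "DoseMap",
  representation(nominalDose = "numeric", seed = "integer"),
  validity = function(object) {
    if (length(object@nominalDose) != 1L || object@nominalDose < 0)
      return("nominalDose must be a single non-negative number")
    TRUE
  })

#' Raw transmission scan of a film
#'
#' Pixel intensities (transmission counts) from a flatbed scanner, one
#' channel, with the pixel pitch recovered from the file's dpi metadata.
#'
#' @slot values numeric matrix of pixel intensities (counts).
#' @slot pixelPitch mm/pixel.
#' @slot origin film-frame (x, y) of pixel (1,1), mm.
#' @slot channel channel the scan was taken from ("red", "green", "blue",
#'   or "gray").
#' @slot bitDepth bits per sample of the source image.
#' @name FilmScan-class
#' @aliases FilmScan
#' @exportClass FilmScan
setClass("FilmScan", contains = "FilmGrid",
  representation(channel = "character", bitDepth = "integer"),
  validity = function(object) {
    v <- validFilmGrid(object)
    if (!isTRUE(v)) return(v)
    if (!object@channel %in% c("red", "green", "blue", "gray"))
      return("channel must be one of red/green/blue/gray")
    TRUE
  })

## ---------------------------------------------------------------------------
## Film response and calibration
## ---------------------------------------------------------------------------

#' Forward film response model
#'
#' Saturating rational plus linear model of the film's netOD response,
#' `netOD(D) = a D / (1 + b D) + c D`. This is the generator's ground truth;
#' the calibration side never sees these parameters and must learn the
#' response from synthetic exposures.
#'
#' @slot scaleA initial slope, netOD/Gy (> 0).
#' @slot saturationB saturation rate, 1/Gy (>= 0).
#' @slot linearC residual linear term, netOD/Gy.
#' @slot readoutTag which readout the response refers to: `"scanner_red"`
#'   (red channel of the flatbed scanner) or `"led_green"` (green-LED/LDR
#'   transmission).
#' @name FilmResponse-class
#' @aliases FilmResponse
#' @exportClass FilmResponse
setClass("FilmResponse",
  representation(scaleA = "numeric", saturationB = "numeric",
                 linearC = "numeric", readoutTag = "character"),
  validity = function(object) {
    msg <- NULL
    if (object@scaleA <= 0) msg <- c(msg, "scaleA must be > 0")
    if (object@saturationB < 0) msg <- c(msg, "saturationB must be >= 0")
    if (!object@readoutTag %in% c("scanner_red", "led_green"))
      msg <- c(msg, "readoutTag must be 'scanner_red' or 'led_green'")
    # strictly increasing on the film's usable range
    d <- seq(0, 10, length.out = 201)
    y <- object@scaleA * d / (1 + object@saturationB * d) + object@linearC * d
    if (any(diff(y) <= 0))
      msg <- c(msg, "response must be strictly increasing on [0, 10] Gy")
    if (is.null(msg)) TRUE else msg
  })

#' Fifth-order calibration curve
#'
#' Polynomial calibration `signal(D)` fitted by least squares, with its
#' validity range, residual RMS and the number of points it was fitted on.
#' The fit is rejected at construction unless it is strictly monotone over
#' `doseRange` (a degree-5 polynomial can oscillate; inverting a
#' non-monotone branch would be meaningless).
#'
#' @slot coefficients length-6 numeric, low order first.
#' @slot doseRange c(min, max) dose in Gy over which the curve is valid.
#' @slot residualRms root-mean-square fit residual (signal units).
#' @slot nPoints number of calibration points.
#' @slot direction "increasing" (netOD vs dose) or "decreasing" (ADC counts
#'   vs dose).
#' @name CalibrationCurve-class
#' @aliases CalibrationCurve
#' @exportClass CalibrationCurve
setClass("CalibrationCurve",
  representation(coefficients = "numeric", doseRange = "numeric",
                 residualRms = "numeric", nPoints = "integer",
                 direction = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@coefficients) != 6L)
      msg <- c(msg, "coefficients must have length 6 (degree-5 polynomial)")
    if (length(object@doseRange) != 2L || diff(object@doseRange) <= 0)
      msg <- c(msg, "doseRange must be c(min, max) with min < max")
    if (object@nPoints < 7L)
      msg <- c(msg, "nPoints must be >= 7 (degree + 2)")
    if (!object@direction %in% c("increasing", "decreasing"))
      msg <- c(msg, "direction must be 'increasing' or 'decreasing'")
    if (is.null(msg) && length(object@coefficients) == 6L) {
      g <- seq(object@doseRange[1], object@doseRange[2], length.out = 513)
      y <- polyEval(object@coefficients, g)
      mono <- if (object@direction == "increasing") all(diff(y) > 0)
              else all(diff(y) < 0)
      if (!mono)
        msg <- c(msg, "polynomial is not strictly monotone over doseRange")
    }
    if (is.null(msg)) TRUE else msg
  })

polyEval <- function(coefs, x) {
  y <- 0
  for (k in rev(seq_along(coefs))) y <- y * x + coefs[k]
  y
}

## ---------------------------------------------------------------------------
## Beam, spectrum and phantom
## ---------------------------------------------------------------------------

#' X-ray fluence spectrum
#'
#' Relative photon-fluence weights on a keV grid (normalized to unit sum).
#'
#' @slot energies strictly increasing keV grid, max <= kvp.
#' @slot weights non-negative relative fluence, at least one positive.
#' @slot kvp tube voltage, kV.
#' @name Spectrum-class
#' @aliases Spectrum
#' @exportClass Spectrum
setClass("Spectrum",
  representation(energies = "numeric", weights = "numeric", kvp = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@energies) != length(object@weights))
      msg <- c(msg, "energies and weights must have equal length")
    if (any(diff(object@energies) <= 0))
      msg <- c(msg, "energies must be strictly increasing")
    if (max(object@energies) > object@kvp + 1e-9)
      msg <- c(msg, "energies must not exceed kvp")
    if (any(object@weights < 0) || !any(object@weights > 0))
      msg <- c(msg, "weights must be >= 0 with at least one positive")
    if (is.null(msg)) TRUE else msg
  })

#' Radiation source model
#'
#' The source side of the simulator: either a kilovoltage X-ray tube whose
#' output follows the inverse-square-like law
#' `Dose(mGy) = A (SSD - D')^-p` per unit calibration time, or a 137Cs
#' irradiator with a constant dose rate and a nearly homogeneous field.
#'
#' @slot amplitudeA output amplitude A, mGy mm^p.
#' @slot exponentP distance exponent p (close to 2).
#' @slot offsetDprime source-position offset D', mm.
#' @slot kvp tube voltage, kV.
#' @slot filtrationMmAl added aluminium filtration, mm.
#' @slot selfFiltrationMmAl effective inherent (anode self-)filtration,
#'   mm Al-equivalent; see the methods vignette for how its default is set.
#' @slot fieldDispersionTarget maximum percent OD dispersion of the field.
#' @slot sourceType "xray_tube" or "cs137".
#' @slot csDoseRate 137Cs dose rate, Gy/min.
#' @slot fieldPeakOffset (x, y) offset of the field maximum from the film
#'   centre, as a fraction of the film size (emulates the off-axis beam
#'   intensity displacement seen with the tube).
#' @slot fieldSeed seed of the field pattern's rough component. The
#'   inhomogeneity pattern is a property of the source, so it is fixed per
#'   beam; per-exposure variability enters through readout noise.
#' @name BeamModel-class
#' @aliases BeamModel
#' @exportClass BeamModel
setClass("BeamModel",
  representation(amplitudeA = "numeric", exponentP = "numeric",
                 offsetDprime = "numeric", kvp = "numeric",
                 filtrationMmAl = "numeric", selfFiltrationMmAl = "numeric",
                 fieldDispersionTarget = "numeric", sourceType = "character",
                 csDoseRate = "numeric", fieldPeakOffset = "numeric",
                 fieldSeed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@amplitudeA <= 0) msg <- c(msg, "amplitudeA must be > 0")
    if (object@exponentP < 1.5 || object@exponentP > 2.5)
      msg <- c(msg, "exponentP must be in [1.5, 2.5]")
    if (object@fieldDispersionTarget < 0)
      msg <- c(msg, "fieldDispersionTarget must be >= 0")
    if (!object@sourceType %in% c("xray_tube", "cs137"))
      msg <- c(msg, "sourceType must be 'xray_tube' or 'cs137'")
    if (object@csDoseRate <= 0) msg <- c(msg, "csDoseRate must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' Staircase attenuation phantom
#'
#' Steps of increasing height placed over the film, advancing along one axis.
#'
#' @slot material "PMMA" or "Al".
#' @slot widths step widths along the staircase axis, mm.
#' @slot heights step heights (attenuator thickness), mm; 0 means an open
#'   (unattenuated) step.
#' @slot pitch step pitch, mm (defaults to the widths).
#' @slot orientation axis along which steps advance, "x" or "y".
#' @name StaircasePhantom-class
#' @aliases StaircasePhantom
#' @exportClass StaircasePhantom
setClass("StaircasePhantom",
  representation(material = "character", widths = "numeric",
                 heights = "numeric", pitch = "numeric",
                 orientation = "character"),
  validity = function(object) {
    msg <- NULL
    if (!object@material %in% c("PMMA", "Al"))
      msg <- c(msg, "material must be 'PMMA' or 'Al'")
    if (length(object@widths) != length(object@heights))
      msg <- c(msg, "widths and heights must have equal length")
    if (any(object@widths <= 0)) msg <- c(msg, "step widths must be > 0")
    if (any(object@heights < 0)) msg <- c(msg, "step heights must be >= 0")
    if (!object@orientation %in% c("x", "y"))
      msg <- c(msg, "orientation must be 'x' or 'y'")
    if (is.null(msg)) TRUE else msg
  })

## ---------------------------------------------------------------------------
## Sensor array and readout
## ---------------------------------------------------------------------------

#' LDR sensor array ("dosiMOEMs"-type device)
#'
#' Geometry and response parameters of the 5x10 light-dependent-resistor
#' array: LED drive grid, per-LDR resistance parameters and manufacturing
#' spread, voltage-divider and amplifier transfer, and the multiplexed
#' 12-bit ADC. Only a subset of LDRs (`participating`, default the 4x5
#' top-left block of 20) takes part in film experiments; the full matrix
#' stays addressable.
#'
#' @slot nRows,nCols array dimensions (default 5 x 10).
#' @slot ldrDiameter sensitive diameter of one LDR, mm.
#' @slot pitch centre-to-centre spacing, mm.
#' @slot r0 per-LDR reference resistance at unit light, ohm (length nRows*nCols).
#' @slot gamma per-LDR response exponent: R = R0 * light^-gamma.
#' @slot gainSpread per-LDR multiplicative channel-gain factor
#'   (manufacturing spread; the motivation for the conversion-factor matrix).
#' @slot participating full-array indices (row-major) of the LDRs used in
#'   film experiments; experiment numbering 1..20 follows this vector.
#' @slot referenceLdr index into `participating` of the reference LDR (#1).
#' @slot badLdrs experiment numbers of LDRs with inflated noise (default 19, 20).
#' @slot ledGrid 3x3 integer LED drive levels, 0-255.
#' @slot amplifierGain,amplifierOffset affine amplifier transfer
#'   `V = gain * (Vdivider - offset)`, set so films from 0 to 10 Gy span the
#'   ADC range.
#' @slot dividerRFix fixed resistor of the read-out voltage divider, ohm.
#' @slot adcBits ADC resolution (12).
#' @slot vref ADC reference voltage, V.
#' @slot readsPerLdr multiplexed repeated reads averaged per LDR.
#' @slot glitchSd relative sd of per-read multiplicative glitch noise.
#' @slot badNoiseFactor noise inflation factor for `badLdrs`.
#' @name SensorArray-class
#' @aliases SensorArray
#' @exportClass SensorArray
setClass("SensorArray",
  representation(nRows = "integer", nCols = "integer", ldrDiameter = "numeric",
                 pitch = "numeric", r0 = "numeric", gamma = "numeric",
                 gainSpread = "numeric", participating = "integer",
                 referenceLdr = "integer", badLdrs = "integer",
                 ledGrid = "matrix", amplifierGain = "numeric",
                 amplifierOffset = "numeric", dividerRFix = "numeric",
                 adcBits = "integer", vref = "numeric", readsPerLdr = "integer",
                 glitchSd = "numeric", badNoiseFactor = "numeric"),
  validity = function(object) {
    msg <- NULL
    n <- object@nRows * object@nCols
    if (object@ldrDiameter <= 0 || object@pitch <= 0)
      msg <- c(msg, "ldrDiameter and pitch must be > 0")
    if (length(object@r0) != n || length(object@gamma) != n ||
        length(object@gainSpread) != n)
      msg <- c(msg, "r0, gamma, gainSpread must have length nRows*nCols")
    if (any(object@gamma <= 0) || any(object@gamma > 2))
      msg <- c(msg, "gamma must be in (0, 2]")
    if (any(object@participating < 1L) || any(object@participating > n))
      msg <- c(msg, "participating indices out of array range")
    if (!all(object@ledGrid == round(object@ledGrid)) ||
        any(object@ledGrid < 0) || any(object@ledGrid > 255))
      msg <- c(msg, "ledGrid drive levels must be integers in 0..255")
    if (object@adcBits < 1L || object@adcBits > 16L)
      msg <- c(msg, "adcBits must be in 1..16")
    if (object@readsPerLdr < 1L) msg <- c(msg, "readsPerLdr must be >= 1")
    if (is.null(msg)) TRUE else msg
  })

#' One multiplexed averaged readout of the array
#'
#' Per-LDR averaged ADC values plus the film-frame position each LDR saw
#' (after the specular device-to-film mapping) and per-LDR flags.
#'
#' @slot readings data.frame with columns `ldr` (experiment number), `row`,
#'   `col` (full-array position), `x_mm`, `y_mm` (film-frame footprint
#'   centre), `count` (averaged ADC value), `n_reads`, `boundary` (footprint
#'   clipped at the film edge).
#' @slot nReads reads averaged per LDR.
#' @slot seed integer seed of the generating draw.
#' @slot tag free-text tag.
#' @name ADCFrame-class
#' @aliases ADCFrame
#' @exportClass ADCFrame
setClass("ADCFrame",
  representation(readings = "data.frame", nReads = "integer",
                 seed = "integer", tag = "character"),
  validity = function(object) {
    need <- c("ldr", "row", "col", "x_mm", "y_mm", "count", "n_reads",
              "boundary")
    if (!all(need %in% names(object@readings)))
      return(paste("readings must have columns:", paste(need, collapse = ", ")))
    if (any(object@readings$count < 0) || any(object@readings$count > 4095))
      return("averaged counts must lie within the 12-bit ADC range [0, 4095]")
    if (object@nReads < 1L) return("nReads must be >= 1")
    TRUE
  })

#' Per-LDR calibration with conversion factors
#'
#' Degree-5 `count(dose)` curve per LDR plus the scalar conversion factor
#' that collapses each LDR's curve onto the reference LDR's curve.
#'
#' @slot curves named list of [CalibrationCurve-class] (decreasing), one per
#'   participating LDR.
#' @slot conversionFactors named numeric; factor of the reference LDR is
#'   exactly 1.
#' @slot referenceLdr experiment number of the reference LDR.
#' @name LDRCalibration-class
#' @aliases LDRCalibration
#' @exportClass LDRCalibration
setClass("LDRCalibration",
  representation(curves = "list", conversionFactors = "numeric",
                 referenceLdr = "integer"),
  validity = function(object) {
    msg <- NULL
    ref <- as.character(object@referenceLdr)
    if (!ref %in% names(object@conversionFactors))
      msg <- c(msg, "reference LDR missing from conversionFactors")
    else if (object@conversionFactors[[ref]] != 1)
      msg <- c(msg, "conversion factor of the reference LDR must be exactly 1")
    if (any(object@conversionFactors <= 0))
      msg <- c(msg, "conversion factors must be > 0")
    if (!all(vapply(object@curves, is, TRUE, "CalibrationCurve")))
      msg <- c(msg, "curves must be CalibrationCurve objects")
    if (is.null(msg)) TRUE else msg
  })
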