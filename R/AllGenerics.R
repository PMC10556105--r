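#' @include AllClasses.R
NULL

#' Accessors for film-grid objects
#'
#' `mapValues` returns the numeric matrix of a map, `pixelPitch` its pixel
#' pitch in mm/pixel, `mapOrigin` the film-frame coordinates of element (1,1).
#'
#' @param x a [FilmGrid-class] derivative.
#' @return `mapValues`: numeric matrix; `pixelPitch`, `mapOrigin`: numeric.
#' @name filmgrid-accessors
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname filmgrid-accessors
#' @export
setGeneric("pixelPitch", function(x) standardGeneric("pixelPitch"))

#' @rdname filmgrid-accessors
#' @export
setGeneric("mapOrigin", function(x) standardGeneric("mapOrigin"))

#' @rdname filmgrid-accessors
setMethod("mapValues", "FilmGrid", function(x) x@values)

#' @rdname filmgrid-accessors
setMethod("pixelPitch", "FilmGrid", function(x) x@pixelPitch)

#' @rdname filmgrid-accessors
setMethod("mapOrigin", "FilmGrid", function(x) x@origin)

#' @rdname filmgrid-accessors
setMethod("dim", "FilmGrid", function(x) dim(x@values))

setMethod("show", "ODMap", function(object) {
  v <- object@values
  cat(sprintf("ODMap: %d x %d px, %.4g mm/px, netOD range [%.4g, %.4g]\n",
              nrow(v), ncol(v), object@pixelPitch, min(v), max(v)))
})

setMethod("show", "DoseMap", function(object) {
  v <- object@values
  cat(sprintf("%s: %d x %d px, %.4g mm/px, dose range [%.4g, %.4g] Gy\n",
              class(object), nrow(v), ncol(v), object@pixelPitch,
              min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  if (is(object, "DoseField"))
    cat(sprintf("  nominal %.4g Gy, seed %d\n", object@nominalDose,
                object@seed))
})

setMethod("show", "FilmScan", function(object) {
  v <- object@values
  cat(sprintf(
    "FilmScan (%s channel, %d-bit): %d x %d px, %.4g mm/px (%.0f dpi)\n",
    object@channel, object@bitDepth, nrow(v), ncol(v), object@pixelPitch,
    25.4 / object@pixelPitch))
})

setMethod("show", "FilmResponse", function(object) {
  cat(sprintf("FilmResponse [%s]: netOD(D) = %.4g D/(1 + %.4g D) + %.4g D\n",
              object@readoutTag, object@scaleA, object@saturationB,
              object@linearC))
})

#' Accessors for calibration curves
#'
#' @param object,x a [CalibrationCurve-class].
#' @param ... unused.
#' @return `coef`: the six polynomial coefficients (low order first);
#'   `doseRange`: c(min, max) in Gy; `residualRMS`: the fit's residual RMS.
#' @name calibration-accessors
#' @export
setGeneric("doseRange", function(x) standardGeneric("doseRange"))

#' @rdname calibration-accessors
#' @export
setGeneric("residualRMS", function(x) standardGeneric("residualRMS"))

#' @rdname calibration-accessors
setMethod("doseRange", "CalibrationCurve", function(x) x@doseRange)

#' @rdname calibration-accessors
setMethod("residualRMS", "CalibrationCurve", function(x) x@residualRms)

#' @rdname calibration-accessors
#' @export
setMethod("coef", "CalibrationCurve", function(object, ...) {
  setNames(object@coefficients, paste0("c", 0:5))
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf(
    "CalibrationCurve (degree 5, %s): dose range [%.3g, %.3g] Gy, %d points, residual RMS %.3g\n",
    object@direction, object@doseRange[1], object@doseRange[2],
    object@nPoints, object@residualRms))
})

setMethod("show", "Spectrum", function(object) {
  meanE <- sum(object@energies * object@weights) / sum(object@weights)
  cat(sprintf("Spectrum: %g kVp, %d energy bins (%g-%g keV), mean %.2f keV\n",
              object@kvp, length(object@energies), min(object@energies),
              max(object@energies), meanE))
})

setMethod("show", "BeamModel", function(object) {
  if (object@sourceType == "xray_tube")
    cat(sprintf(
      "BeamModel [x-ray tube]: %g kVp, %g + %g mm Al filtration,\n  Dose(mGy) = %g (SSD - %g)^-%g, field dispersion target %g%%\n",
      object@kvp, object@filtrationMmAl, object@selfFiltrationMmAl,
      object@amplitudeA, object@offsetDprime, object@exponentP,
      object@fieldDispersionTarget))
  else
    cat(sprintf(
      "BeamModel [137Cs]: %g Gy/min, field dispersion target %g%%\n",
      object@csDoseRate, object@fieldDispersionTarget))
})

setMethod("show", "StaircasePhantom", function(object) {
  cat(sprintf("StaircasePhantom [%s], steps along %s:\n", object@material,
              object@orientation))
  cat(sprintf("  widths (mm): %s\n", paste(object@widths, collapse = ", ")))
  cat(sprintf("  heights (mm): %s\n", paste(object@heights, collapse = ", ")))
})

setMethod("show", "SensorArray", function(object) {
  cat(sprintf(
    "SensorArray: %d x %d LDRs (d = %g mm, pitch %g mm), %d participating,\n  %d-bit ADC, %d reads/LDR, glitch sd %.2g%% (bad LDRs %s: x%g)\n",
    object@nRows, object@nCols, object@ldrDiameter, object@pitch,
    length(object@participating), object@adcBits, object@readsPerLdr,
    100 * object@glitchSd, paste(object@badLdrs, collapse = ","),
    object@badNoiseFactor))
})

setMethod("show", "ADCFrame", function(object) {
  cat(sprintf("ADCFrame '%s': %d LDRs, %d reads each, seed %d\n",
              object@tag, nrow(object@readings), object@nReads, object@seed))
  cat(sprintf("  counts: %.0f - %.0f (mean %.0f)\n",
              min(object@readings$count), max(object@readings$count),
              mean(object@readings$count)))
})

#' Accessors for ADC frames and LDR calibrations
#'
#' @param x an [ADCFrame-class] or [LDRCalibration-class].
#' @return `frameReadings`: the per-LDR data.frame of an ADCFrame;
#'   `conversionFactors`: named numeric factors; `referenceLdr`: the
#'   reference LDR's experiment number; `ldrCurves`: named list of
#'   per-LDR calibration curves.
#' @name sensor-accessors
#' @export
setGeneric("frameReadings", function(x) standardGeneric("frameReadings"))

#' @rdname sensor-accessors
setMethod("frameReadings", "ADCFrame", function(x) x@readings)

#' @rdname sensor-accessors
#' @export
setGeneric("conversionFactors", function(x) standardGeneric("conversionFactors"))

#' @rdname sensor-accessors
setMethod("conversionFactors", "LDRCalibration", function(x) x@conversionFactors)

#' @rdname sensor-accessors
#' @export
setGeneric("referenceLdr", function(x) standardGeneric("referenceLdr"))

#' @rdname sensor-accessors
setMethod("referenceLdr", "LDRCalibration", function(x) x@referenceLdr)

#' @rdname sensor-accessors
#' @export
setGeneric("ldrCurves", function(x) standardGeneric("ldrCurves"))

#' @rdname sensor-accessors
setMethod("ldrCurves", "LDRCalibration", function(x) x@curves)

setMethod("show", "LDRCalibration", function(object) {
  f <- object@conversionFactors
  cat(sprintf(
    "LDRCalibration: %d LDR curves, reference LDR#%d, conversion factors %.3f - %.3f\n",
    length(object@curves), object@referenceLdr, min(f), max(f)))
})
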