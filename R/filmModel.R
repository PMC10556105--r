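#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## netOD arithmetic
## ---------------------------------------------------------------------------

#' Net optical density from transmission intensities
#'
#' netOD = -log10(I / I0), the film's dose-dependent signal: the change in
#' optical density between the irradiated film (transmitted intensity `I`)
#' and the unexposed control (`I0`). Works elementwise on equal-shaped
#' vectors or matrices; either argument may also be a scalar.
#'
#' @param exposed transmitted intensity (counts) through the irradiated film.
#' @param unexposed transmitted intensity (counts) through the control film.
#' @return netOD, same shape as the (broadcast) inputs.
#' @examples
#' netOD(100, 1000)          # 1: one decade of attenuation
#' netOD(21500, 40000)       # 0.2696...
#' @export
netOD <- function(exposed, unexposed) {
  if (is(exposed, "FilmGrid")) exposed <- mapValues(exposed)
  if (is(unexposed, "FilmGrid")) unexposed <- mapValues(unexposed)
  if (length(exposed) > 1 && length(unexposed) > 1 &&
      !identical(dim(exposed), dim(unexposed)) &&
      length(exposed) != length(unexposed))
    stop("exposed and unexposed maps must have equal shape", call. = FALSE)
  checkPositive <- function(x, what) {
    bad <- which(!(x > 0))
    if (length(bad))
      stop(sprintf("non-positive %s intensity at index %d (value %g)",
                   what, bad[1], x[bad[1]]), call. = FALSE)
  }
  checkPositive(exposed, "exposed")
  checkPositive(unexposed, "unexposed")
  -log10(exposed / unexposed)
}

#' Percent OD dispersion about a reference
#'
#' The field-inhomogeneity statistic: each element is
#' `100 * |netOD - reference| / reference`. By default the reference is the
#' film-mean netOD, so the map measures dispersion about the mean.
#'
#' @param od an [ODMap-class] or a numeric matrix/vector of netOD.
#' @param reference reference netOD (> 0); defaults to `mean(od)`.
#' @return list with `percent` (the dispersion map, %) and `max` (its
#'   maximum, %).
#' @examples
#' odDispersion(c(0.9, 1.0, 1.1))$max   # 10
#' @export
odDispersion <- function(od, reference = NULL) {
  v <- if (is(od, "FilmGrid")) mapValues(od) else od
  if (is.null(reference)) reference <- mean(v)
  if (!is.finite(reference) || reference <= 0)
    stop("reference netOD must be positive, got ", reference, call. = FALSE)
  p <- 100 * abs(v - reference) / reference
  list(percent = p, max = max(p))
}

## ---------------------------------------------------------------------------
## Forward response
## ---------------------------------------------------------------------------

#' Film response presets and constructor
#'
#' Construct a [FilmResponse-class], either from a named preset or from
#' explicit parameters. The two presets are the generator's ground truth for
#' the red-channel scanner readout (`"scanner_red"`, netOD(8 Gy) ~ 0.6,
#' mimicking typical EBT3 behaviour) and for the green-LED/LDR readout
#' (`"led_green"`, slightly less sensitive). Calibration code never reads
#' these parameters.
#'
#' @param tag preset name, also stored as the readout tag.
#' @param scaleA,saturationB,linearC model parameters; defaults come from
#'   the preset.
#' @return a [FilmResponse-class].
#' @examples filmResponse("scanner_red")
#' @export
filmResponse <- function(tag = c("scanner_red", "led_green"),
                         scaleA = NULL, saturationB = NULL, linearC = NULL) {
  tag <- match.arg(tag)
  def <- switch(tag,
    scanner_red = c(a = 0.14, b = 0.12, c = 0.005),
    led_green   = c(a = 0.10, b = 0.10, c = 0.004))
  new("FilmResponse",
      scaleA = scaleA %||% def[["a"]],
      saturationB = saturationB %||% def[["b"]],
      linearC = linearC %||% def[["c"]],
      readoutTag = tag)
}

#' Forward dose-to-netOD response
#'
#' `netOD(D) = a D / (1 + b D) + c D`: a saturating rational term plus a
#' small linear term, strictly increasing with netOD(0) = 0.
#'
#' @param dose dose(s) in Gy, >= 0.
#' @param response a [FilmResponse-class].
#' @return netOD, same shape as `dose`.
#' @export
doseToNetOD <- function(dose, response) {
  stopifnot(is(response, "FilmResponse"))
  if (any(dose < 0))
    stop("dose must be >= 0 (got ", min(dose), ")", call. = FALSE)
  response@scaleA * dose / (1 + response@saturationB * dose) +
    response@linearC * dose
}

## ---------------------------------------------------------------------------
## Fifth-order calibration
## ---------------------------------------------------------------------------

#' Fit a fifth-order calibration curve
#'
#' Least-squares degree-5 polynomial of `signal` as a function of dose, the
#' standard form for radiochromic-film calibration. The fit is rejected if it
#' is not strictly monotone over the fitted dose range, because a
#' non-monotone branch cannot be inverted to a unique dose.
#'
#' @param dose calibration doses, Gy; at least 7 distinct values.
#' @param signal measured signal at each dose (netOD for the scanner branch,
#'   averaged ADC counts for an LDR).
#' @param direction expected monotonicity; netOD increases with dose, ADC
#'   counts decrease.
#' @return a [CalibrationCurve-class].
#' @seealso [invertCalibration()], [predictSignal()]
#' @export
fitCalibration <- function(dose, signal,
                           direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  keep <- is.finite(dose) & is.finite(signal)
  dose <- dose[keep]; signal <- signal[keep]
  if (length(unique(dose)) < 7L)
    stop("calibration needs >= 7 distinct dose points (degree + 2); got ",
         length(unique(dose)), call. = FALSE)
  fit <- lm(signal ~ stats::poly(dose, 5, raw = TRUE))
  coefs <- unname(coef(fit))
  coefs[is.na(coefs)] <- 0
  rng <- range(dose)
  curve <- try(new("CalibrationCurve", coefficients = coefs, doseRange = rng,
                   residualRms = sqrt(mean(fit$residuals^2)),
                   nPoints = length(dose), direction = direction),
               silent = TRUE)
  if (inherits(curve, "try-error"))
    stop("fifth-order fit is not monotone over [", rng[1], ", ", rng[2],
         "] Gy; sample the dose range more densely or reduce noise",
         call. = FALSE)
  curve
}

#' Evaluate a calibration curve
#'
#' @param curve a [CalibrationCurve-class].
#' @param dose dose(s) in Gy.
#' @return predicted signal.
#' @export
predictSignal <- function(curve, dose) {
  stopifnot(is(curve, "CalibrationCurve"))
  polyEval(curve@coefficients, dose)
}

#' Invert a calibration curve
#'
#' Unique dose with `curve(dose) = signal`, found by bracketed root finding
#' (monotonicity over the dose range is guaranteed at fit time).
#'
#' @param curve a [CalibrationCurve-class].
#' @param signal signal value(s) within the curve's range.
#' @param tol root-finding tolerance, Gy.
#' @return dose(s) in Gy.
#' @export
invertCalibration <- function(curve, signal, tol = 1e-9) {
  stopifnot(is(curve, "CalibrationCurve"))
  rng <- curve@doseRange
  ends <- predictSignal(curve, rng)
  lo <- min(ends); hi <- max(ends)
  eps <- 1e-9 * max(1, abs(hi))
  vapply(signal, function(s) {
    if (s < lo - eps || s > hi + eps)
      stop(sprintf(
        "signal %.6g outside the calibrated interval [%.6g, %.6g]",
        s, lo, hi), call. = FALSE)
    s <- min(max(s, lo), hi)
    if (s == ends[1]) return(rng[1])
    if (s == ends[2]) return(rng[2])
    uniroot(function(d) predictSignal(curve, d) - s, interval = rng,
            tol = tol)$root
  }, numeric(1))
}

# Fast vectorized inversion for whole maps: the curve is sampled on a dense
# dose grid and inverted by monotone linear interpolation (absolute accuracy
# ~ (range/n)^2 * curvature, well below 1e-4 Gy at n = 4096). Out-of-range
# signals return NA.
invertCalibrationGrid <- function(curve, signal, n = 4096L) {
  rng <- curve@doseRange
  g <- seq(rng[1], rng[2], length.out = n)
  y <- predictSignal(curve, g)
  if (curve@direction == "decreasing") { y <- rev(y); g <- rev(g) }
  # signals are only defined up to the calibration's residual scatter, so
  # values within that tolerance of a boundary clamp to it instead of being
  # masked (a zero-dose film must not be censored because the fitted curve's
  # intercept is off by its residual RMS)
  eps <- max(1e-8 * (y[n] - y[1]), 3 * curve@residualRms)
  signal[signal > y[1] - eps & signal < y[1]] <- y[1]
  signal[signal < y[n] + eps & signal > y[n]] <- y[n]
  approx(y, g, xout = signal, rule = 1)$y
}

## ---------------------------------------------------------------------------
## Calibration serialization
## ---------------------------------------------------------------------------

#' Read and write calibration data
#'
#' Calibration tables travel as CSV with header `dose_gy,netod`; fitted
#' curves travel as JSON holding the six coefficients (low order first), the
#' dose range, residual RMS, number of points and direction.
#'
#' @param path file path.
#' @param dose,netod calibration table columns.
#' @param curve a [CalibrationCurve-class].
#' @return `readCalibrationTable`: data.frame with `dose_gy`, `netod`;
#'   `readCalibrationJSON`: a [CalibrationCurve-class]; the writers return
#'   the path invisibly.
#' @name calibration-io
#' @export
writeCalibrationTable <- function(dose, netod, path) {
  write.csv(data.frame(dose_gy = dose, netod = netod), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname calibration-io
#' @export
readCalibrationTable <- function(path) {
  df <- read.csv(path)
  if (!all(c("dose_gy", "netod") %in% names(df)))
    stop("calibration CSV must have header 'dose_gy,netod'", call. = FALSE)
  df
}

#' @rdname calibration-io
#' @export
writeCalibrationJSON <- function(curve, path) {
  stopifnot(is(curve, "CalibrationCurve"))
  jsonlite::write_json(list(
    coefficients = curve@coefficients, dose_range = curve@doseRange,
    residual_rms = curve@residualRms, n_points = curve@nPoints,
    direction = curve@direction), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname calibration-io
#' @export
readCalibrationJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("CalibrationCurve", coefficients = as.numeric(x$coefficients),
      doseRange = as.numeric(x$dose_range),
      residualRms = as.numeric(x$residual_rms),
      nPoints = as.integer(x$n_points),
      direction = as.character(x$direction))
}
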