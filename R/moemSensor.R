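#' @include beamPhantom.R
NULL

## ---------------------------------------------------------------------------
## Array construction
## ---------------------------------------------------------------------------

#' Construct an LDR sensor array
#'
#' The `"dosimoems_v1"` preset is a 5x10 matrix of 5 mm photoresistors at
#' 6 mm pitch read through a multiplexed 12-bit ADC. Twenty LDRs (the 4x5
#' top-left block) participate in film experiments; per-LDR channel gains
#' carry a seeded +/-10% manufacturing spread (the reason a conversion-factor
#' matrix is needed), and LDRs #19 and #20 get inflated glitch noise. The
#' amplifier transfer is tuned at construction so that noiseless films from
#' 0 to 10 Gy (green-LED response) span the ADC range without clipping.
#'
#' @param preset preset name ("dosimoems_v1").
#' @param seed seed for the per-LDR manufacturing spread.
#' @param gainSpreadSd half-width of the uniform relative gain spread.
#' @param gammaSpreadSd half-width of a uniform relative spread on the
#'   response exponent (default 0: a gamma spread changes curve shapes, not
#'   just scales, and then scalar conversion factors collapse curves only
#'   approximately).
#' @param response film response used to tune the amplifier.
#' @param ... overrides for [SensorArray-class] slots (applied before tuning).
#' @return a [SensorArray-class].
#' @export
sensorArray <- function(preset = "dosimoems_v1", seed = 42L,
                        gainSpreadSd = 0.10, gammaSpreadSd = 0,
                        response = filmResponse("led_green"), ...) {
  preset <- match.arg(preset)
  nRows <- 5L; nCols <- 10L; n <- nRows * nCols
  spread <- withSeed(subSeed(seed, 7), list(
    gain = runif(n, 1 - gainSpreadSd, 1 + gainSpreadSd),
    gamma = runif(n, 1 - gammaSpreadSd, 1 + gammaSpreadSd)))
  # rows 1-4, cols 1-5, numbered row-major (the multiplexer's scan order)
  block <- as.integer(t(outer(0:3 * nCols, 1:5, `+`)))
  def <- list(nRows = nRows, nCols = nCols, ldrDiameter = 5, pitch = 6,
              r0 = rep(10e3, n), gamma = 0.8 * spread$gamma,
              gainSpread = spread$gain, participating = block,
              referenceLdr = 1L, badLdrs = c(19L, 20L),
              ledGrid = matrix(255L, 3, 3), amplifierGain = 1,
              amplifierOffset = 0, dividerRFix = 10e3, adcBits = 12L,
              vref = 3.3, readsPerLdr = 8L, glitchSd = 0.01,
              badNoiseFactor = 5)
  args <- modifyList(def, list(...))
  arr <- do.call(new, c(list("SensorArray"), args))
  if (!"amplifierGain" %in% names(list(...))) arr <- tuneGain(arr, response)
  arr
}

#' Tune the amplifier to span the ADC range
#'
#' Two-point calibration of the affine amplifier transfer: with the given
#' film response, a 0 Gy film maps to `fsFrac[1]` and a 10 Gy film to
#' `fsFrac[2]` of full scale (nominal channel gain), so the digitized values
#' of films from 0 to 10 Gy cover the ADC range without clipping even at the
#' extremes of the manufacturing gain spread.
#'
#' @param array a [SensorArray-class].
#' @param response a [FilmResponse-class].
#' @param doseSpan doses anchoring the two calibration points, Gy.
#' @param fsFrac full-scale fractions the two anchors map to.
#' @return the array with `amplifierGain`/`amplifierOffset` set.
#' @export
tuneGain <- function(array, response = filmResponse("led_green"),
                     doseSpan = c(0, 10), fsFrac = c(0.85, 0.05)) {
  led <- ledScale(array)
  r0 <- median(array@r0); gam <- median(array@gamma)
  vdiv <- vapply(doseSpan, function(d) {
    light <- led * 10^(-doseToNetOD(d, response))
    dividerVoltage(light, r0, gam, array@dividerRFix, array@vref)
  }, numeric(1))
  vtarget <- fsFrac * array@vref
  gain <- diff(vtarget) / diff(vdiv)
  offset <- vdiv[1] - vtarget[1] / gain
  array@amplifierGain <- gain
  array@amplifierOffset <- offset
  array
}

## ---------------------------------------------------------------------------
## Elementary transfer stages
## ---------------------------------------------------------------------------

#' LED drive voltage
#'
#' The LED drive is digital with 256 steps spanning 0 to 3 V.
#'
#' @param level integer drive level(s), 0-255.
#' @return volts.
#' @examples ledVoltage(85)   # 1 V
#' @export
ledVoltage <- function(level) {
  if (any(level != round(level)) || any(level < 0) || any(level > 255))
    stop("LED drive level must be an integer in 0..255", call. = FALSE)
  level * 3 / 255
}

# relative LED illumination of the array (uniform when all drives are equal)
ledScale <- function(array) mean(ledVoltage(array@ledGrid)) / 3

#' LDR resistance at a light level
#'
#' The photoresistor's resistance decays with light, inversely proportional
#' for `gamma = 1`: `R = R0 * max(light, eps)^-gamma`.
#'
#' @param light relative light intensity, >= 0.
#' @param r0 reference resistance at unit light, ohm.
#' @param gamma response exponent in (0, 2].
#' @param eps darkness floor for the light level.
#' @return resistance in ohm.
#' @export
ldrResistance <- function(light, r0 = 10e3, gamma = 0.8, eps = 1e-6) {
  if (any(light < 0)) stop("light must be >= 0", call. = FALSE)
  r0 * pmax(light, eps)^(-gamma)
}

# fixed monotone divider: V = vcc * Rfix / (Rfix + R_ldr); more light ->
# lower R -> higher voltage
dividerVoltage <- function(light, r0, gamma, rFix, vcc) {
  r <- ldrResistance(light, r0, gamma)
  vcc * rFix / (rFix + r)
}

#' LDR channel output voltage
#'
#' Full analog chain of one channel: resistance decay, fixed voltage
#' divider, affine amplifier `V = gain * (Vdivider - offset)`. Strictly
#' increasing in light; the value may be negative in darkness (the ADC
#' clamps at zero).
#'
#' @param light relative light intensity, >= 0.
#' @param array a [SensorArray-class].
#' @param ldr full-array LDR index (for its channel parameters); NULL for
#'   nominal (median) parameters.
#' @return volts (unclamped).
#' @export
ldrVoltage <- function(light, array, ldr = NULL) {
  r0 <- if (is.null(ldr)) median(array@r0) else array@r0[ldr]
  gam <- if (is.null(ldr)) median(array@gamma) else array@gamma[ldr]
  s <- if (is.null(ldr)) 1 else array@gainSpread[ldr]
  vdiv <- dividerVoltage(light, r0, gam, array@dividerRFix, array@vref)
  s * array@amplifierGain * (vdiv - array@amplifierOffset)
}

#' Quantize a voltage on the ADC
#'
#' `floor(2^bits * v / vref)` clamped to the code range; clamping at both
#' ends is the contract (a 12-bit converter has 4096 codes, 0..4095).
#'
#' @param voltage volts.
#' @param vref reference voltage, > 0.
#' @param bits ADC resolution.
#' @return integer count(s).
#' @examples adcQuantize(1.65, 3.3)   # 2048
#' @export
adcQuantize <- function(voltage, vref = 3.3, bits = 12L) {
  if (vref <= 0) stop("vref must be > 0", call. = FALSE)
  pmin(pmax(floor(2^bits * voltage / vref), 0), 2^bits - 1)
}

## ---------------------------------------------------------------------------
## Film sampling geometry
## ---------------------------------------------------------------------------

#' Mirror a device index onto the film frame
#'
#' The film sees the array as its specular image: the column order is
#' left-right mirrored while rows are unchanged. The mapping is an
#' involution (applying it twice is the identity).
#'
#' @param array a [SensorArray-class].
#' @param index full-array LDR index(es), row-major.
#' @return mirrored full-array index(es).
#' @export
mirrorIndex <- function(array, index) {
  n <- array@nRows * array@nCols
  if (any(index < 1) || any(index > n) || any(index != round(index)))
    stop("LDR index out of range 1..", n, call. = FALSE)
  r <- (index - 1) %/% array@nCols
  c0 <- (index - 1) %% array@nCols
  as.integer(r * array@nCols + (array@nCols - 1 - c0) + 1)
}

#' Film-frame positions of the participating LDRs
#'
#' Positions of the participating LDR footprints on a film of the given
#' size, with the participating block centred on the film and the specular
#' (left-right) device-to-film mapping applied within the block.
#'
#' @param array a [SensorArray-class].
#' @param filmSize c(width, height) of the film, mm.
#' @return data.frame with `ldr` (experiment number), `row`, `col`
#'   (full-array position) and `x_mm`, `y_mm` (footprint centre, film frame).
#' @export
ldrFilmPositions <- function(array, filmSize) {
  p <- array@participating
  r <- (p - 1) %/% array@nCols + 1
  c0 <- (p - 1) %% array@nCols + 1
  jr <- r - min(r) + 1          # block-relative row/col
  jc <- c0 - min(c0) + 1
  bw <- max(jc) * array@pitch
  bh <- max(jr) * array@pitch
  ox <- (filmSize[1] - bw) / 2
  oy <- (filmSize[2] - bh) / 2
  data.frame(ldr = seq_along(p), row = r, col = c0,
             x_mm = ox + bw - (jc - 0.5) * array@pitch,  # specular image
             y_mm = oy + (jr - 0.5) * array@pitch)
}

#' Mean film transmission over an LDR footprint
#'
#' Mean of `10^-netOD` over the pixels inside the circular footprint. A
#' footprint partly outside the film is clipped at the edge and flagged
#' (such an LDR integrates a lower-dose boundary region); a footprint
#' wholly outside the film is a geometry error.
#'
#' @param od an [ODMap-class].
#' @param center footprint centre c(x, y) in film-frame mm.
#' @param diameter footprint diameter, mm.
#' @return list with `transmission` (mean fraction) and `clipped` (logical).
#' @export
ldrTransmission <- function(od, center, diameter) {
  stopifnot(is(od, "ODMap"))
  v <- mapValues(od); pp <- pixelPitch(od)
  xc <- mapOrigin(od)[1] + (seq_len(ncol(v)) - 0.5) * pp
  yc <- mapOrigin(od)[2] + (seq_len(nrow(v)) - 0.5) * pp
  dx2 <- (xc - center[1])^2
  dy2 <- (yc - center[2])^2
  inside <- outer(dy2, dx2, `+`) <= (diameter / 2)^2
  if (!any(inside))
    stop(sprintf(
      "LDR footprint at (%.1f, %.1f) mm lies wholly outside the film",
      center[1], center[2]), call. = FALSE)
  filmW <- ncol(v) * pp; filmH <- nrow(v) * pp
  clipped <- center[1] - diameter / 2 < mapOrigin(od)[1] ||
    center[2] - diameter / 2 < mapOrigin(od)[2] ||
    center[1] + diameter / 2 > mapOrigin(od)[1] + filmW ||
    center[2] + diameter / 2 > mapOrigin(od)[2] + filmH
  list(transmission = mean(10^(-v[inside])), clipped = clipped)
}

## ---------------------------------------------------------------------------
## Full readout
## ---------------------------------------------------------------------------

#' Simulate one multiplexed scan of a film
#'
#' For each participating LDR: the mean transmission over its (mirrored)
#' footprint, the channel voltage, and `nReads` repeated ADC reads with
#' multiplicative glitch noise, averaged into one stored count. Bad LDRs
#' get `badNoiseFactor` times the glitch noise. Reproducible from `seed`.
#'
#' @param od an [ODMap-class] of the film under readout.
#' @param array a [SensorArray-class].
#' @param seed integer seed.
#' @param nReads reads per LDR (default the array's `readsPerLdr`).
#' @param tag free-text tag stored in the frame.
#' @return an [ADCFrame-class].
#' @export
scanFilm <- function(od, array, seed = 1L, nReads = NULL, tag = "") {
  stopifnot(is(od, "ODMap"), is(array, "SensorArray"))
  nReads <- as.integer(nReads %||% array@readsPerLdr)
  if (nReads < 1L) stop("nReads must be >= 1", call. = FALSE)
  v <- mapValues(od); pp <- pixelPitch(od)
  filmSize <- c(ncol(v), nrow(v)) * pp
  pos <- ldrFilmPositions(array, filmSize)
  if (any(pos$x_mm < 0) || any(pos$x_mm > filmSize[1]) ||
      any(pos$y_mm < 0) || any(pos$y_mm > filmSize[2]))
    stop(sprintf(
      "film (%g x %g mm) does not cover the participating LDR block",
      filmSize[1], filmSize[2]), call. = FALSE)
  led <- ledScale(array)
  withSeed(seed, {
    out <- lapply(seq_len(nrow(pos)), function(i) {
      tr <- ldrTransmission(od, c(pos$x_mm[i], pos$y_mm[i]),
                            array@ldrDiameter)
      full <- array@participating[pos$ldr[i]]
      volt <- ldrVoltage(led * tr$transmission, array, full)
      sdRel <- array@glitchSd *
        if (pos$ldr[i] %in% array@badLdrs) array@badNoiseFactor else 1
      reads <- adcQuantize(volt * (1 + rnorm(nReads, 0, sdRel)),
                           array@vref, array@adcBits)
      c(count = mean(reads), boundary = tr$clipped)
    })
    out <- do.call(rbind, out)
    new("ADCFrame",
        readings = data.frame(ldr = pos$ldr, row = pos$row, col = pos$col,
                              x_mm = pos$x_mm, y_mm = pos$y_mm,
                              count = out[, "count"], n_reads = nReads,
                              boundary = as.logical(out[, "boundary"])),
        nReads = nReads, seed = as.integer(seed), tag = tag)
  })
}

#' Serialize an ADC frame
#'
#' CSV with columns `ldr_index,row,col,count,n_reads` (plus film-frame
#' positions and the boundary flag), or JSON carrying the same fields with
#' the seed and tag.
#'
#' @param frame an [ADCFrame-class].
#' @param path output path; format chosen by extension (.csv or .json).
#' @return the path, invisibly.
#' @export
writeADCFrame <- function(frame, path) {
  stopifnot(is(frame, "ADCFrame"))
  df <- frame@readings
  names(df)[names(df) == "ldr"] <- "ldr_index"
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(readings = df, n_reads = frame@nReads,
                              seed = frame@seed, tag = frame@tag),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
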