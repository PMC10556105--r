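#' @include moemSensor.R
NULL

## ---------------------------------------------------------------------------
## Scanner branch
## ---------------------------------------------------------------------------

#' Reconstruct a dose map from a scanned film
#'
#' The scanner branch of the inverse pipeline: per-pixel netOD (from an
#' [ODMap-class], or from an exposed/unexposed [FilmScan-class] pair through
#' [netOD()]), inverted through the fifth-order calibration curve. Pixels
#' that are saturated/zero in the scans or fall outside the calibrated
#' signal interval are masked (NA) and counted, never silently clamped.
#'
#' @param exposed an [ODMap-class], or the exposed [FilmScan-class].
#' @param curve a [CalibrationCurve-class] (netOD vs dose, increasing).
#' @param unexposed the control [FilmScan-class] when `exposed` is a scan.
#' @param roi optional region of interest `c(x, y, width, height)` in mm
#'   (film frame); clipped to the film with a warning flag. Default: the
#'   whole film.
#' @return list with `dose` (a [DoseMap-class], NA at masked pixels),
#'   `roiMean`, `roiSd` (Gy, over unmasked ROI pixels), `nMasked`,
#'   `roiClipped`.
#' @export
scannerDoseMap <- function(exposed, curve, unexposed = NULL, roi = NULL) {
  stopifnot(is(curve, "CalibrationCurve"))
  if (is(exposed, "FilmScan")) {
    if (is.null(unexposed) || !is(unexposed, "FilmScan"))
      stop("an unexposed control scan is required with FilmScan input",
           call. = FALSE)
    ve <- mapValues(exposed); vu <- mapValues(unexposed)
    if (!identical(dim(ve), dim(vu)))
      stop("exposed and unexposed scans are not congruent", call. = FALSE)
    full <- 2^exposed@bitDepth - 1
    usable <- ve > 0 & vu > 0 & ve < full & vu < full
    od <- matrix(NA_real_, nrow(ve), ncol(ve))
    od[usable] <- -log10(ve[usable] / vu[usable])
    pp <- pixelPitch(exposed); orig <- mapOrigin(exposed)
  } else if (is(exposed, "ODMap")) {
    od <- mapValues(exposed)
    pp <- pixelPitch(exposed); orig <- mapOrigin(exposed)
  } else stop("exposed must be an ODMap or a FilmScan", call. = FALSE)

  dose <- matrix(invertCalibrationGrid(curve, od), nrow(od), ncol(od))
  nMasked <- sum(is.na(dose))
  dm <- new("DoseMap", values = dose, pixelPitch = pp, origin = orig)

  filmW <- ncol(dose) * pp; filmH <- nrow(dose) * pp
  roiClipped <- FALSE
  if (is.null(roi)) roi <- c(orig[1], orig[2], filmW, filmH)
  x0 <- roi[1]; y0 <- roi[2]; x1 <- roi[1] + roi[3]; y1 <- roi[2] + roi[4]
  cx0 <- max(x0, orig[1]); cy0 <- max(y0, orig[2])
  cx1 <- min(x1, orig[1] + filmW); cy1 <- min(y1, orig[2] + filmH)
  if (cx0 > x0 || cy0 > y0 || cx1 < x1 || cy1 < y1) {
    roiClipped <- TRUE
    warning("ROI extends beyond the film; clipped", call. = FALSE)
  }
  xc <- orig[1] + (seq_len(ncol(dose)) - 0.5) * pp
  yc <- orig[2] + (seq_len(nrow(dose)) - 0.5) * pp
  sel <- dose[yc >= cy0 & yc <= cy1, xc >= cx0 & xc <= cx1, drop = FALSE]
  list(dose = dm, roiMean = mean(sel, na.rm = TRUE),
       roiSd = sd(as.vector(sel), na.rm = TRUE), nMasked = nMasked,
       roiClipped = roiClipped)
}

## ---------------------------------------------------------------------------
## LDR-array branch
## ---------------------------------------------------------------------------

#' Calibrate the LDR array
#'
#' Fits a degree-5 `count(dose)` curve per participating LDR, then computes
#' the matrix of conversion factors: for each LDR, the least-squares scalar
#' that collapses its fitted curve onto the reference LDR's curve over a
#' dense common dose grid. The reference LDR's factor is exactly 1. Fitting
#' happens first, normalization second.
#'
#' @param doses calibration doses, Gy (>= 7 distinct levels).
#' @param frames list of [ADCFrame-class], one per dose, all covering the
#'   same LDRs.
#' @param referenceLdr experiment number of the reference LDR.
#' @return an [LDRCalibration-class].
#' @export
calibrateLDRs <- function(doses, frames, referenceLdr = 1L) {
  if (length(doses) != length(frames))
    stop("doses and frames must have equal length", call. = FALSE)
  if (length(unique(doses)) < 7L)
    stop("LDR calibration needs >= 7 distinct dose levels", call. = FALSE)
  ldrs <- sort(frames[[1]]@readings$ldr)
  counts <- vapply(frames, function(f) {
    df <- f@readings
    if (!identical(sort(df$ldr), ldrs))
      stop("LDR#", setdiff(ldrs, df$ldr)[1],
           " missing from a calibration frame", call. = FALSE)
    df$count[match(ldrs, df$ldr)]
  }, numeric(length(ldrs)))
  curves <- lapply(seq_along(ldrs), function(i) {
    cv <- try(fitCalibration(doses, counts[i, ], direction = "decreasing"),
              silent = TRUE)
    if (inherits(cv, "try-error"))
      stop("calibration failed for LDR#", ldrs[i], ": ",
           attr(cv, "condition")$message, call. = FALSE)
    cv
  })
  names(curves) <- ldrs
  refIdx <- match(referenceLdr, ldrs)
  if (is.na(refIdx))
    stop("reference LDR#", referenceLdr, " not present in the frames",
         call. = FALSE)
  grid <- seq(min(doses), max(doses), length.out = 200)
  yref <- predictSignal(curves[[refIdx]], grid)
  factors <- vapply(seq_along(ldrs), function(i) {
    yi <- predictSignal(curves[[i]], grid)
    sum(yref * yi) / sum(yi * yi)
  }, numeric(1))
  factors[refIdx] <- 1
  names(factors) <- ldrs
  new("LDRCalibration", curves = curves, conversionFactors = factors,
      referenceLdr = as.integer(referenceLdr))
}

#' Convert an ADC frame to per-LDR doses
#'
#' Counts are multiplied by their conversion factor and inverted through the
#' reference LDR's calibration curve -- the in-situ ADC-to-dose conversion.
#' Counts outside the calibrated interval yield an `out_of_range` flag and
#' NA dose (never an error); clipped-footprint LDRs are flagged `boundary`
#' and the array's noisy LDRs `bad`.
#'
#' @param frame an [ADCFrame-class].
#' @param cal an [LDRCalibration-class].
#' @param badLdrs experiment numbers to flag as noisy (default 19, 20).
#' @return data.frame with `ldr`, `row`, `col`, `x_mm`, `y_mm`, `count`,
#'   `normalized`, `dose_gy`, `flag`.
#' @export
adcToDose <- function(frame, cal, badLdrs = c(19L, 20L)) {
  stopifnot(is(frame, "ADCFrame"), is(cal, "LDRCalibration"))
  df <- frame@readings
  key <- as.character(df$ldr)
  miss <- setdiff(key, names(cal@conversionFactors))
  if (length(miss))
    stop("frame LDR#", miss[1], " is not covered by the calibration",
         call. = FALSE)
  f <- cal@conversionFactors[key]
  normalized <- df$count * f
  ref <- cal@curves[[as.character(cal@referenceLdr)]]
  dose <- invertCalibrationGrid(ref, normalized)
  flag <- rep("ok", nrow(df))
  flag[df$ldr %in% badLdrs] <- "bad"
  flag[df$boundary] <- "boundary"
  flag[is.na(dose)] <- "out_of_range"
  data.frame(ldr = df$ldr, row = df$row, col = df$col, x_mm = df$x_mm,
             y_mm = df$y_mm, count = df$count, normalized = unname(normalized),
             dose_gy = dose, flag = flag)
}

## ---------------------------------------------------------------------------
## Staircase analysis
## ---------------------------------------------------------------------------

#' Staircase step analysis with background subtraction
#'
#' Per-step, per-zone mean dose of a staircase measurement after the
#' background correction the protocol prescribes: the measurement is divided
#' by the *relative* field of a background exposure at the same nominal dose
#' without the phantom, which removes the beam's field inhomogeneity. For
#' the scanner branch the correction happens in OD space (relative netOD
#' field) before dose conversion; for the LDR branch, which never observes
#' OD, the per-LDR relative correction is applied to the converted doses.
#' Step averages use the central band of each step (default 60% of its
#' width) to avoid penumbra, and the film can be split into three horizontal
#' zones (top/middle/bottom) analysed independently.
#'
#' @param measurement an [ODMap-class] (scanner branch, requires `curve`) or
#'   a per-LDR dose data.frame from [adcToDose()].
#' @param phantom the [StaircasePhantom-class] registered to the film frame
#'   (first step at the staircase origin = film origin).
#' @param background same type as `measurement`: the matching exposure
#'   without the phantom.
#' @param curve a [CalibrationCurve-class] (scanner branch only).
#' @param zones 1 or 3 horizontal zones.
#' @param centralFrac central fraction of each step width used for averages.
#' @return a step-dose table: data.frame with `step_id`, `step_height_mm`,
#'   `zone`, `mean_dose_gy`, `sd_gy`, `n`.
#' @export
stepAnalysis <- function(measurement, phantom, background, curve = NULL,
                         zones = 3, centralFrac = 0.6) {
  stopifnot(is(phantom, "StaircasePhantom"), zones %in% c(1, 3))
  if (is(measurement, "ODMap")) {
    if (is.null(curve))
      stop("the scanner branch needs a calibration curve", call. = FALSE)
    if (!is(background, "ODMap") ||
        !identical(dim(mapValues(background)), dim(mapValues(measurement))))
      stop("background must be an ODMap congruent with the measurement",
           call. = FALSE)
    odm <- mapValues(measurement)
    bg <- mapValues(background)
    rel <- bg / mean(bg)                      # relative OD field
    dose <- matrix(invertCalibrationGrid(curve, odm / rel),
                   nrow(odm), ncol(odm))
    pp <- pixelPitch(measurement)
    xs <- (seq_len(ncol(dose)) - 0.5) * pp
    ys <- (seq_len(nrow(dose)) - 0.5) * pp
    values <- dose; posAlong <- xs; posAcross <- ys
    alongIsX <- phantom@orientation == "x"
    getCell <- function(inAlong, inAcross) {
      if (alongIsX) values[inAcross, inAlong, drop = FALSE]
      else values[inAlong, inAcross, drop = FALSE]
    }
    acrossPos <- if (alongIsX) ys else xs
    alongPos <- if (alongIsX) xs else ys
  } else if (is.data.frame(measurement)) {
    if (!is.data.frame(background))
      stop("background must be an adcToDose() table", call. = FALSE)
    m <- merge(measurement, background[, c("ldr", "dose_gy")], by = "ldr",
               suffixes = c("", "_bg"))
    good <- is.finite(m$dose_gy) & is.finite(m$dose_gy_bg)
    rel <- m$dose_gy_bg / mean(m$dose_gy_bg[good])
    m$dose_corr <- m$dose_gy / rel
    alongIsX <- phantom@orientation == "x"
    alongPos <- if (alongIsX) m$x_mm else m$y_mm
    acrossPos <- if (alongIsX) m$y_mm else m$x_mm
    values <- m$dose_corr
    getCell <- function(inAlong, inAcross) values[inAlong & inAcross]
  } else stop("measurement must be an ODMap or an adcToDose() table",
              call. = FALSE)

  starts <- (seq_along(phantom@widths) - 1) * phantom@pitch
  zoneBreaks <- if (zones == 3) {
    rng <- range(acrossPos)
    seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = 4)
  } else range(acrossPos) + c(-1e-9, 1e-9)
  zoneNames <- if (zones == 3) c("top", "middle", "bottom") else "all"

  rows <- list()
  for (k in seq_along(starts)) {
    pad <- phantom@widths[k] * (1 - centralFrac) / 2
    inAlong <- alongPos >= starts[k] + pad &
      alongPos <= starts[k] + phantom@widths[k] - pad
    for (z in seq_len(zones)) {
      inAcross <- acrossPos >= zoneBreaks[z] & acrossPos < zoneBreaks[z + 1]
      cell <- getCell(inAlong, inAcross)
      cell <- cell[is.finite(cell)]
      rows[[length(rows) + 1]] <- data.frame(
        step_id = k, step_height_mm = phantom@heights[k],
        zone = zoneNames[z],
        mean_dose_gy = if (length(cell)) mean(cell) else NA_real_,
        sd_gy = if (length(cell) > 1) sd(cell) else NA_real_,
        n = length(cell))
    }
  }
  do.call(rbind, rows)
}

#' Dose-ratio table
#'
#' Ratios `reference dose / step dose`, the attenuation figure the staircase
#' experiments report (reference: the dose without the staircase). Reported
#' rounded (2 decimals by default); full precision is kept in `ratio_full`.
#'
#' @param doses step doses in Gy, or a step-dose table from [stepAnalysis()]
#'   (rows with NA mean dose are dropped).
#' @param referenceDose the unattenuated reference dose, Gy (> 0).
#' @param digits rounding for the reported ratio.
#' @return data.frame with the input identifiers, `ratio` (rounded) and
#'   `ratio_full`.
#' @examples
#' doseRatioTable(c(0.98, 0.49), 2.9)   # ratios 2.96, 5.92
#' @export
doseRatioTable <- function(doses, referenceDose, digits = 2) {
  if (!is.finite(referenceDose) || referenceDose <= 0)
    stop("referenceDose must be positive", call. = FALSE)
  if (is.data.frame(doses)) {
    tb <- doses[is.finite(doses$mean_dose_gy), , drop = FALSE]
    tb$ratio_full <- referenceDose / tb$mean_dose_gy
    tb$ratio <- round(tb$ratio_full, digits)
    return(tb)
  }
  data.frame(dose_gy = doses, ratio = round(referenceDose / doses, digits),
             ratio_full = referenceDose / doses)
}

## ---------------------------------------------------------------------------
## Orientation detection
## ---------------------------------------------------------------------------

#' Detect the film orientation from an ADC frame
#'
#' For each candidate orientation the staircase geometry predicts a per-LDR
#' relative dose pattern (1 over the step's transmission ratio at the LDR's
#' film position; steps advance along x in "R" and along y in "R+90"). The
#' observed per-LDR doses are compared against each scaled prediction and
#' the orientation with the smaller summed absolute mismatch wins; a
#' symmetric phantom, a uniform film (no phantom) or a near-tie returns
#' `"undetermined"` with a diagnostic.
#'
#' @param frame an [ADCFrame-class].
#' @param cal an [LDRCalibration-class].
#' @param phantom a [StaircasePhantom-class] (or NULL: undetermined).
#' @param beam the [BeamModel-class] providing the spectrum for step ratios.
#' @param nominalDose optional nominal dose, Gy; when NULL the scale of each
#'   prediction is estimated robustly from the observations themselves.
#' @param candidates candidate orientations.
#' @param tieTol relative score difference below which the result is a tie.
#' @return list with `orientation` ("R", "R+90" or "undetermined"),
#'   `scores`, `diagnostic`, and `report` (per-LDR observed and expected
#'   doses under each candidate).
#' @export
detectOrientation <- function(frame, cal, phantom,
                              beam = beamPreset("xray_60kv"),
                              nominalDose = NULL,
                              candidates = c("R", "R+90"), tieTol = 0.1) {
  doses <- adcToDose(frame, cal)
  obs <- doses[is.finite(doses$dose_gy), ]
  undet <- function(why, report = NULL)
    list(orientation = "undetermined", scores = NULL, diagnostic = why,
         report = report)
  if (is.null(phantom)) return(undet("no phantom: uniform films carry no orientation signal"))
  stopifnot(is(phantom, "StaircasePhantom"))
  if (length(unique(phantom@heights)) < 2L)
    return(undet("phantom is symmetric (single step height): orientations are indistinguishable"))
  ratios <- phantomStepRatios(phantom, beam)
  relAt <- function(pos) {
    k <- stepIndexAt(phantom, pos)
    ifelse(is.na(k), 1, 1 / ratios[k])
  }
  pred <- list("R" = relAt(obs$x_mm), "R+90" = relAt(obs$y_mm))
  expected <- scores <- setNames(vector("list", length(candidates)),
                                 candidates)
  for (cand in candidates) {
    rel <- pred[[cand]]
    scale <- nominalDose %||% median(obs$dose_gy / rel)
    expected[[cand]] <- scale * rel
    scores[[cand]] <- sum(abs(obs$dose_gy - expected[[cand]]))
  }
  report <- data.frame(ldr = obs$ldr, observed_gy = obs$dose_gy)
  for (cand in candidates)
    report[[paste0("expected_", gsub("\\+", "plus", cand), "_gy")]] <-
      expected[[cand]]
  s <- unlist(scores)
  best <- names(s)[which.min(s)]
  if (diff(range(s)) <= tieTol * max(s))
    return(undet(sprintf(
      "mismatch scores nearly tie (%s): film likely uniform or phantom symmetric",
      paste(sprintf("%s=%.3g", names(s), s), collapse = ", ")), report))
  list(orientation = best, scores = s, diagnostic = "ok", report = report)
}
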