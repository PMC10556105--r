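#' @include io.R
NULL

## Default study conditions of the synthetic experiments: X-ray calibration
## films span 0.2-8 Gy (red-channel scanner readout, ROI statistics), 137Cs
## films span 0.2-4 Gy, staircase films are irradiated at a nominal 3 Gy.
.xrayCalDoses <- c(0.2, 0.5, 1, 1.5, 2, 3, 4, 6, 8)
.csCalDoses <- c(0.2, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4)

# film large enough to cover the participating LDR block with a margin
moemFilmSize <- function(array, margin = 3) {
  pos <- ldrFilmPositions(array, c(0, 0))
  p <- array@participating
  nc <- length(unique((p - 1) %% array@nCols))
  nr <- length(unique((p - 1) %/% array@nCols))
  c(nc, nr) * array@pitch + 2 * margin
}

#' Build a scanner-branch calibration from synthetic films
#'
#' Irradiates one synthetic film per calibration dose, records the ROI-mean
#' netOD of each (the protocol's "mean pixel value" statistic) and fits the
#' fifth-order calibration curve.
#'
#' @param doses calibration doses, Gy.
#' @param beam a [BeamModel-class].
#' @param response the film's [FilmResponse-class].
#' @param seed integer seed; each film draws from a sub-seed.
#' @param filmSize,pixelPitch film geometry, mm.
#' @return list with `curve`, `doses`, `netods`, and the generated `films`.
#' @export
makeScannerCalibration <- function(doses = .xrayCalDoses,
                                   beam = beamPreset("xray_60kv"),
                                   response = filmResponse("scanner_red"),
                                   seed = 1L, filmSize = c(40, 40),
                                   pixelPitch = 0.5) {
  films <- lapply(seq_along(doses), function(i)
    irradiateFilm(doses[i], beam, response = response,
                  seed = subSeed(seed, 10 + i), filmSize = filmSize,
                  pixelPitch = pixelPitch))
  netods <- vapply(films, function(f) mean(mapValues(f$od)), numeric(1))
  list(curve = fitCalibration(doses, netods), doses = doses,
       netods = netods, films = films)
}

#' Build an LDR-array calibration from synthetic frames
#'
#' Irradiates one synthetic film per dose (green-LED readout response),
#' scans each with the array and calibrates the 20 participating LDRs with
#' their conversion factors.
#'
#' @inheritParams makeScannerCalibration
#' @param array a [SensorArray-class].
#' @param nReads reads averaged per LDR for the calibration frames;
#'   calibration uses deeper averaging than routine frames so glitch noise
#'   (notably on the noisy LDRs) cannot break the monotone quintic fits.
#' @return list with `cal` (an [LDRCalibration-class]), `doses`, `frames`,
#'   and the generated `films`.
#' @export
makeMoemCalibration <- function(doses = .csCalDoses,
                                beam = beamPreset("cs137"),
                                response = filmResponse("led_green"),
                                array = sensorArray(), seed = 1L,
                                pixelPitch = 0.5, nReads = 32L) {
  filmSize <- moemFilmSize(array)
  films <- lapply(seq_along(doses), function(i)
    irradiateFilm(doses[i], beam, response = response,
                  seed = subSeed(seed, 40 + i), filmSize = filmSize,
                  pixelPitch = pixelPitch))
  frames <- lapply(seq_along(films), function(i)
    scanFilm(films[[i]]$od, array, seed = subSeed(seed, 70 + i),
             nReads = nReads, tag = sprintf("cal_%g_gy", doses[i])))
  list(cal = calibrateLDRs(doses, frames), doses = doses, frames = frames,
       films = films)
}

#' Reconstruct the mean dose of one synthetic film, both branches
#'
#' Convenience runners for validation experiments: irradiate a film at a
#' nominal dose and recover it through the scanner branch
#' ([scannerDoseMap()]) or the LDR branch ([scanFilm()] + [adcToDose()]).
#'
#' @param nominalDose nominal dose, Gy.
#' @param calibration output of [makeScannerCalibration()] /
#'   [makeMoemCalibration()].
#' @param beam,response,seed generation parameters.
#' @param array the [SensorArray-class] (LDR branch).
#' @param pixelPitch film grid pitch, mm.
#' @return list with `mean` (Gy), `sd`, and branch detail (`recon` or
#'   `doses` table).
#' @name branch-runners
#' @export
runScannerValidation <- function(nominalDose, calibration,
                                 beam = beamPreset("xray_60kv"),
                                 response = filmResponse("scanner_red"),
                                 seed = 2L, pixelPitch = 0.5) {
  film <- irradiateFilm(nominalDose, beam, response = response, seed = seed,
                        filmSize = c(40, 40), pixelPitch = pixelPitch)
  recon <- scannerDoseMap(film$od, calibration$curve)
  list(mean = recon$roiMean, sd = recon$roiSd, recon = recon, film = film)
}

#' @rdname branch-runners
#' @export
runMoemValidation <- function(nominalDose, calibration,
                              beam = beamPreset("cs137"),
                              response = filmResponse("led_green"),
                              array = sensorArray(), seed = 2L,
                              pixelPitch = 0.5) {
  film <- irradiateFilm(nominalDose, beam, response = response, seed = seed,
                        filmSize = moemFilmSize(array),
                        pixelPitch = pixelPitch)
  frame <- scanFilm(film$od, array, seed = subSeed(seed, 99), tag = "validation")
  doses <- adcToDose(frame, cal = calibration$cal, badLdrs = array@badLdrs)
  good <- doses$flag == "ok" & is.finite(doses$dose_gy)
  list(mean = mean(doses$dose_gy[good]), sd = sd(doses$dose_gy[good]),
       doses = doses, frame = frame, film = film)
}

#' Cross-method comparison on a dose grid
#'
#' Generates, at each nominal dose, one scanner film and one LDR-array film
#' from the same beam, reconstructs each through its own calibration and
#' tabulates the between-method difference (the cross-method agreement
#' figure of merit).
#'
#' @param doses nominal doses, Gy.
#' @param seed integer seed.
#' @param beam a [BeamModel-class].
#' @return data.frame with `dose_gy`, `scanner_gy`, `moem_gy`, `diff_gy`.
#' @export
runCrossMethod <- function(doses = c(0.5, 1, 2, 3, 4, 5, 6, 7, 8),
                           seed = 1L, beam = beamPreset("xray_60kv")) {
  array <- sensorArray(seed = subSeed(seed, 5))
  scal <- makeScannerCalibration(beam = beam, seed = subSeed(seed, 1))
  mcal <- makeMoemCalibration(doses = .xrayCalDoses, beam = beam,
                              array = array, seed = subSeed(seed, 2))
  rows <- lapply(seq_along(doses), function(i) {
    s <- runScannerValidation(doses[i], scal, beam = beam,
                              seed = subSeed(seed, 200 + i))
    m <- runMoemValidation(doses[i], mcal, beam = beam, array = array,
                           seed = subSeed(seed, 300 + i))
    data.frame(dose_gy = doses[i], scanner_gy = s$mean, moem_gy = m$mean,
               diff_gy = abs(s$mean - m$mean))
  })
  do.call(rbind, rows)
}

## ---------------------------------------------------------------------------
## Named fixture suites
## ---------------------------------------------------------------------------

#' Generate a named synthetic fixture suite
#'
#' One-call generators for the synthetic experiments the analyses run on,
#' all reproducible from a single seed:
#' \describe{
#'   \item{`xray`}{scanner-branch calibration (0.2-8 Gy, inhomogeneous tube
#'     field) plus validation films at 0.6 and 1.5 Gy.}
#'   \item{`cs137`}{homogeneous-field calibrations for both branches
#'     (0.2-4 Gy) plus validation exposures at 0.6 Gy.}
#'   \item{`pmma_stairs`}{3 Gy film under the six-step PMMA staircase with
#'     its background film, scanner calibration, and LDR frames.}
#'   \item{`al_stairs`}{3 Gy film under the Al staircase with background,
#'     scanner calibration, and LDR frames in both `R` and `R+90`
#'     orientations.}
#' }
#'
#' @param suite suite name.
#' @param seed integer seed.
#' @param outdir optional directory; when given, the suite's tables and maps
#'   are written there through [writeResults()].
#' @return a named list of fixture objects (invisible when written to disk).
#' @export
makeFixtures <- function(suite = c("xray", "cs137", "pmma_stairs",
                                   "al_stairs"), seed = 1L, outdir = NULL) {
  suite <- match.arg(suite)
  fx <- switch(suite,
    xray = {
      beam <- beamPreset("xray_60kv")
      cal <- makeScannerCalibration(beam = beam, seed = seed)
      list(beam = beam, calibration = cal,
           validation = lapply(c(0.6, 1.5), function(d)
             runScannerValidation(d, cal, beam = beam,
                                  seed = subSeed(seed, round(1000 * d)))))
    },
    cs137 = {
      beam <- beamPreset("cs137")
      array <- sensorArray(seed = subSeed(seed, 5))
      scal <- makeScannerCalibration(doses = .csCalDoses, beam = beam,
                                     seed = subSeed(seed, 1))
      mcal <- makeMoemCalibration(beam = beam, array = array,
                                  seed = subSeed(seed, 2))
      list(beam = beam, array = array, scanner = scal, moem = mcal,
           validationScanner = runScannerValidation(
             0.6, scal, beam = beam, seed = subSeed(seed, 600)),
           validationMoem = runMoemValidation(
             0.6, mcal, beam = beam, array = array,
             seed = subSeed(seed, 601)))
    },
    pmma_stairs = ,
    al_stairs = {
      beam <- beamPreset("xray_60kv")
      phantom <- phantomPreset(
        if (suite == "pmma_stairs") "pmma_stairs" else "al_stairs")
      array <- sensorArray(seed = subSeed(seed, 5))
      scal <- makeScannerCalibration(beam = beam, seed = subSeed(seed, 1))
      mcal <- makeMoemCalibration(doses = .xrayCalDoses, beam = beam,
                                  array = array, seed = subSeed(seed, 2))
      filmSizeM <- pmax(moemFilmSize(array), phantomExtent(phantom))
      stair <- irradiateFilm(3, beam, phantom = phantom,
                             filmSize = c(40, 40), seed = subSeed(seed, 21),
                             response = filmResponse("scanner_red"))
      bg <- irradiateFilm(3, beam, filmSize = c(40, 40),
                          seed = subSeed(seed, 22),
                          response = filmResponse("scanner_red"))
      stairM <- irradiateFilm(3, beam, phantom = phantom,
                              filmSize = filmSizeM, seed = subSeed(seed, 23),
                              response = filmResponse("led_green"))
      bgM <- irradiateFilm(3, beam, filmSize = filmSizeM,
                           seed = subSeed(seed, 24),
                           response = filmResponse("led_green"))
      frames <- list(R = scanFilm(stairM$od, array, seed = subSeed(seed, 25),
                                  tag = "R"),
                     background = scanFilm(bgM$od, array,
                                           seed = subSeed(seed, 26),
                                           tag = "background"))
      if (suite == "al_stairs") {
        phantom90 <- phantomPreset("al_stairs", orientation = "y")
        stair90 <- irradiateFilm(3, beam, phantom = phantom90,
                                 filmSize = filmSizeM,
                                 seed = subSeed(seed, 27),
                                 response = filmResponse("led_green"))
        frames$`R+90` <- scanFilm(stair90$od, array,
                                  seed = subSeed(seed, 28), tag = "R+90")
      }
      list(beam = beam, phantom = phantom, array = array, scanner = scal,
           moem = mcal, film = stair, background = bg, filmMoem = stairM,
           backgroundMoem = bgM, frames = frames)
    })
  if (!is.null(outdir)) {
    tables <- list()
    maps <- list()
    if (!is.null(fx$calibration))
      tables$calibration <- data.frame(dose_gy = fx$calibration$doses,
                                       netod = fx$calibration$netods)
    if (!is.null(fx$film)) {
      maps$staircase_od <- fx$film$od
      maps$background_od <- fx$background$od
    }
    if (!is.null(fx$frames))
      for (nm in names(fx$frames))
        tables[[paste0("frame_", gsub("\\+", "plus", nm))]] <-
          frameReadings(fx$frames[[nm]])
    writeResults(tables = tables, maps = maps, outdir = outdir,
                 config = list(mode = suite, seed = seed), seed = seed,
                 force = TRUE)
    return(invisible(fx))
  }
  fx
}
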