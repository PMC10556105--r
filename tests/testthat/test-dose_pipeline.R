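test_that("scanner branch recovers known doses from noiseless films", {
  cv <- noiselessCurve()
  r <- filmResponse("scanner_red")
  # exposed = unexposed scans -> zero-dose map
  I0 <- matrix(30000, 20, 20)
  sc <- new("FilmScan", values = I0, pixelPitch = 0.5, origin = c(0, 0),
            channel = "red", bitDepth = 16L)
  out <- scannerDoseMap(sc, cv, unexposed = sc)
  expect_equal(out$roiMean, 0, tolerance = 1e-9)
  expect_true(all(mapValues(out$dose) == 0, na.rm = TRUE))
  # forward/inverse round trip on a uniform synthetic film
  for (d in c(0.6, 1.5, 3, 7)) {
    film <- irradiateFilm(d, flatBeam(), filmSize = c(20, 20), seed = 1,
                          pixelPitch = 0.5, odNoiseSd = 0)
    got <- scannerDoseMap(film$od, cv)
    expect_lt(abs(got$roiMean - d), 1e-3)
  }
})

test_that("scanner branch masks saturated pixels and clips the ROI", {
  cv <- noiselessCurve()
  I0 <- matrix(30000, 10, 10)
  I <- I0 * 10^(-doseToNetOD(2, filmResponse("scanner_red")))
  I[1, 1] <- 0                      # dead pixel
  I[2, 2] <- 65535                  # saturated pixel
  sc <- function(v) new("FilmScan", values = v, pixelPitch = 1,
                        origin = c(0, 0), channel = "red", bitDepth = 16L)
  out <- scannerDoseMap(sc(I), cv, unexposed = sc(I0))
  expect_equal(out$nMasked, 2)
  expect_true(is.na(mapValues(out$dose)[1, 1]))
  expect_equal(out$roiMean, 2, tolerance = 1e-3)
  expect_warning(
    clipped <- scannerDoseMap(sc(I), cv, unexposed = sc(I0),
                              roi = c(5, 5, 20, 20)), "clipped")
  expect_true(clipped$roiClipped)
  expect_error(scannerDoseMap(sc(I), cv, unexposed = sc(I[1:5, ])),
               "not congruent")
})

test_that("conversion factors collapse gain-spread channels exactly", {
  doses <- c(0.2, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4)
  beam <- flatBeam("cs137")
  r <- filmResponse("led_green")
  arr <- quietArray()
  # clone of the reference channel with 1.10x gain
  arr@gainSpread[arr@participating[2]] <- 1.10
  films <- lapply(doses, function(d)
    irradiateFilm(d, beam, response = r, filmSize = moemFilmSize(arr),
                  seed = 1, pixelPitch = 0.5, odNoiseSd = 0))
  frames <- lapply(films, function(f) scanFilm(f$od, arr, seed = 1))
  cal <- calibrateLDRs(doses, frames)
  f <- conversionFactors(cal)
  expect_identical(f[["1"]], 1)                       # reference: exactly 1
  expect_equal(f[["2"]], 1 / 1.10, tolerance = 1e-3)  # construction oracle
  expect_equal(unname(f[as.character(3:18)]), rep(1, 16), tolerance = 1e-3)
})

test_that("LDR calibration validates its inputs", {
  doses <- c(0.2, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4)
  arr <- quietArray()
  films <- lapply(doses, function(d)
    irradiateFilm(d, flatBeam("cs137"), response = filmResponse("led_green"),
                  filmSize = moemFilmSize(arr), seed = 1, pixelPitch = 0.5,
                  odNoiseSd = 0))
  frames <- lapply(films, function(f) scanFilm(f$od, arr, seed = 1))
  expect_error(calibrateLDRs(doses[1:6], frames[1:6]), ">= 7 distinct")
  broken <- frames
  broken[[3]]@readings <- broken[[3]]@readings[-4, ]
  expect_error(calibrateLDRs(doses, broken), "missing from a calibration")
  expect_error(calibrateLDRs(doses, frames, referenceLdr = 99L),
               "not present")
})

test_that("ADC-to-dose is the identity up to quantization on noiseless data", {
  # the 12-bit ADC floors counts; the inversion error is bounded by about
  # one code width divided by the local curve slope (worst near the shallow
  # high-dose end), so the identity holds to ~0.01 Gy, not machine precision
  doses <- c(0.2, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4)
  beam <- flatBeam("cs137")
  arr <- quietArray()
  films <- lapply(doses, function(d)
    irradiateFilm(d, beam, response = filmResponse("led_green"),
                  filmSize = moemFilmSize(arr), seed = 1, pixelPitch = 0.5,
                  odNoiseSd = 0))
  frames <- lapply(films, function(f) scanFilm(f$od, arr, seed = 1))
  cal <- calibrateLDRs(doses, frames)
  for (i in seq_along(doses)[-c(1, length(doses))]) {
    dd <- adcToDose(frames[[i]], cal)
    expect_lt(max(abs(dd$dose_gy - doses[i])), 0.015)
  }
})

test_that("ADC-to-dose flags instead of crashing", {
  doses <- c(0.2, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4)
  arr <- quietArray()
  films <- lapply(doses, function(d)
    irradiateFilm(d, flatBeam("cs137"), response = filmResponse("led_green"),
                  filmSize = moemFilmSize(arr), seed = 1, pixelPitch = 0.5,
                  odNoiseSd = 0))
  frames <- lapply(films, function(f) scanFilm(f$od, arr, seed = 1))
  cal <- calibrateLDRs(doses, frames)
  zero <- frames[[1]]
  zero@readings$count <- 0
  dd <- adcToDose(zero, cal)
  expect_true(all(dd$flag == "out_of_range"))         # all-zero counts
  expect_true(all(is.na(dd$dose_gy)))
  dd2 <- adcToDose(frames[[5]], cal)
  expect_true(all(dd2$flag[dd2$ldr %in% c(19, 20)] == "bad"))
})

test_that("step analysis recovers construction ratios after background division", {
  beam <- flatBeam()
  ph <- phantomPreset("al_stairs")
  cv <- noiselessCurve()
  st <- irradiateFilm(3, beam, phantom = ph, filmSize = c(40, 40), seed = 1,
                      pixelPitch = 0.5, odNoiseSd = 0)
  bg <- irradiateFilm(3, beam, filmSize = c(40, 40), seed = 2,
                      pixelPitch = 0.5, odNoiseSd = 0)
  tb <- stepAnalysis(st$od, ph, bg$od, curve = cv, zones = 3)
  ratios <- transmissionRatio(xraySpectrum(60, 2.55), "Al", c(0, 3, 6), "dose")
  # the learned quintic is not the true response family, so the recovery is
  # exact only up to the fit's interpolation error (a few 1e-3 relative)
  for (k in 1:3)
    expect_equal(tb$mean_dose_gy[tb$step_id == k],
                 rep(3 / ratios[k], 3), tolerance = 5e-3)
  # no phantom (all heights 0): every step at the nominal dose
  open <- phantomPreset("al_stairs", heights = c(0, 0, 0))
  tb0 <- stepAnalysis(bg$od, open, bg$od, curve = cv, zones = 1)
  expect_equal(tb0$mean_dose_gy, rep(3, 3), tolerance = 1e-3)
  expect_error(stepAnalysis(st$od, ph, odMap(matrix(0.1, 3, 3), 0.5),
                            curve = cv), "congruent")
  expect_error(stepAnalysis(st$od, ph, bg$od), "calibration curve")
})

test_that("three-zone means agree on homogeneous fields", {
  beam <- flatBeam()
  ph <- phantomPreset("pmma_stairs")
  cv <- noiselessCurve()
  st <- irradiateFilm(3, beam, phantom = ph, filmSize = c(40, 40), seed = 3,
                      pixelPitch = 0.5, odNoiseSd = 0.01)
  bg <- irradiateFilm(3, beam, filmSize = c(40, 40), seed = 4,
                      pixelPitch = 0.5, odNoiseSd = 0.01)
  tb <- stepAnalysis(st$od, ph, bg$od, curve = cv, zones = 3)
  whole <- stepAnalysis(st$od, ph, bg$od, curve = cv, zones = 1)
  for (k in unique(tb$step_id)) {
    z <- tb[tb$step_id == k, ]
    w <- whole[whole$step_id == k, ]
    expect_true(all(abs(z$mean_dose_gy - w$mean_dose_gy) <
                      (z$sd_gy + w$sd_gy)))
  }
})

test_that("dose ratios reproduce reference arithmetic and scale invariance", {
  expect_equal(doseRatioTable(2.9, 2.9)$ratio, 1)
  expect_equal(doseRatioTable(c(0.98, 0.49), 2.9)$ratio, c(2.96, 5.92))
  expect_equal(doseRatioTable(2.1, 3)$ratio, 1.43)
  # invariant under uniform rescaling of all doses
  d <- c(2.8, 1.1, 0.5)
  expect_equal(doseRatioTable(2 * d, 2 * 3)$ratio_full,
               doseRatioTable(d, 3)$ratio_full, tolerance = 1e-12)
  expect_error(doseRatioTable(c(1, 2), 0), "positive")
})

test_that("orientation detection identifies the staircase axis", {
  fx <- makeFixtures("al_stairs", seed = 3)
  detR <- detectOrientation(fx$frames$R, fx$moem$cal, fx$phantom,
                            beam = fx$beam)
  expect_identical(detR$orientation, "R")
  det90 <- detectOrientation(fx$frames$`R+90`, fx$moem$cal, fx$phantom,
                             beam = fx$beam)
  expect_identical(det90$orientation, "R+90")
  # the same LDR reads the once-attenuated zone (~1.05 Gy) in R and the open
  # 3 Gy zone in R+90 (tolerances cover the tube's 20% field inhomogeneity)
  dR <- adcToDose(fx$frames$R, fx$moem$cal)
  d90 <- adcToDose(fx$frames$`R+90`, fx$moem$cal)
  ratios <- transmissionRatio(xraySpectrum(60, 2.55), "Al", c(0, 3, 6), "dose")
  expect_lt(abs(dR$dose_gy[dR$ldr == 3] - 3 / ratios[2]), 0.3)
  expect_lt(abs(d90$dose_gy[d90$ldr == 3] - 3), 0.4)
  # uniform film (no phantom) and symmetric phantom are undetermined
  u <- detectOrientation(fx$frames$background, fx$moem$cal, NULL,
                         beam = fx$beam)
  expect_identical(u$orientation, "undetermined")
  sym <- phantomPreset("al_stairs", heights = c(3, 3, 3))
  s <- detectOrientation(fx$frames$R, fx$moem$cal, sym, beam = fx$beam)
  expect_identical(s$orientation, "undetermined")
})
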