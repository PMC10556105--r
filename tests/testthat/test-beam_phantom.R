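test_that("source power law matches its closed form", {
  beam <- beamPreset("xray_60kv")
  expect_equal(doseAtSSD(1, beam), 138251)           # unit base, D' = 0
  expect_equal(doseAtSSD(79.5, beam), 138251 * 79.5^-2.003, tolerance = 1e-12)
  expect_equal(doseAtSSD(79.5, beam), 21.589, tolerance = 1e-4)
  # doubling the effective distance scales by 2^-p
  expect_equal(doseAtSSD(120, beam) / doseAtSSD(60, beam), 2^-2.003,
               tolerance = 1e-12)
  # time scaling is linear
  expect_equal(doseAtSSD(79.5, beam, time = 30, timeBase = 10),
               3 * doseAtSSD(79.5, beam))
  # strictly decreasing in SSD
  d <- doseAtSSD(seq(20, 200, by = 5), beam)
  expect_true(all(diff(d) < 0))
  expect_error(doseAtSSD(4, beamPreset("xray_60kv", offsetDprime = 5)),
               "must exceed the offset")
})

test_that("offset estimation inverts the power law exactly", {
  beam0 <- beamPreset("xray_60kv")
  rateAt <- function(ssd, dprime)
    doseAtSSD(ssd, beamPreset("xray_60kv", offsetDprime = dprime))
  expect_equal(estimateOffset(c(60, rateAt(60, 5)), c(120, rateAt(120, 5))),
               5, tolerance = 1e-9)
  expect_lt(abs(estimateOffset(c(60, rateAt(60, 0)), c(120, rateAt(120, 0)))),
            1e-6)
  set.seed(31)
  for (i in 1:20) {
    dp <- runif(1, 0, 20)
    s <- sort(runif(2, 30, 200)); s[2] <- s[2] + 5
    est <- estimateOffset(c(s[1], rateAt(s[1], dp)), c(s[2], rateAt(s[2], dp)))
    expect_equal(est, dp, tolerance = 1e-8)
  }
  expect_error(estimateOffset(c(60, 10), c(60, 5)), "distinct")
  expect_error(estimateOffset(c(60, 10), c(120, 10)), "impossible")
  # rates increasing with distance: no offset below both SSDs
  expect_error(estimateOffset(c(60, 5), c(120, 10)), "inconsistent")
})

test_that("bremsstrahlung spectrum follows the filtered Kramers form", {
  sp <- xraySpectrum(60, 0)
  e <- sp@energies; w <- sp@weights
  # unfiltered weights proportional to (kvp - E)/E
  expect_equal(w / sum(w), ((60 - e) / e) / sum((60 - e) / e),
               tolerance = 1e-12)
  expect_equal(w[e == 60], 0)                 # endpoint of bremsstrahlung
  expect_equal(sum(w), 1)
  # filtration hardens the beam: mean energy strictly increases
  meanE <- function(s) sum(s@energies * s@weights)
  expect_gt(meanE(xraySpectrum(60, 1.3)), meanE(sp))
  expect_gt(meanE(xraySpectrum(60, 2.6)), meanE(xraySpectrum(60, 1.3)))
  expect_error(xraySpectrum(15), "20-90")
  expect_error(xraySpectrum(95), "20-90")
})

test_that("transmission ratio matches Beer-Lambert on monoenergetic beams", {
  mono30 <- new("Spectrum", energies = 30, weights = 1, kvp = 60)
  # bundled constants: mu/rho(Al, 30 keV) = 1.128, rho = 2.699
  expect_equal(transmissionRatio(mono30, "Al", 3),
               exp(1.128 * 2.699 * 0.3), tolerance = 1e-9)
  expect_equal(transmissionRatio(mono30, "Al", 3), 2.4926, tolerance = 1e-4)
  expect_equal(transmissionRatio(mono30, "Al", 0), 1)
  # Beer-Lambert composition: doubling thickness squares the mono ratio
  expect_equal(transmissionRatio(mono30, "Al", 6),
               transmissionRatio(mono30, "Al", 3)^2, tolerance = 1e-9)
})

test_that("polychromatic ratios are bounded, ordered and increasing", {
  sp <- xraySpectrum(60, 1.3)
  th <- c(0.5, 1, 2, 4, 8)
  r <- transmissionRatio(sp, "Al", th)
  expect_true(all(r >= 1))
  expect_true(all(diff(r) > 0))                       # increasing in thickness
  expect_true(all(r > transmissionRatio(sp, "PMMA", th)))  # Al absorbs more
  # convex-combination bound: between the extreme monoenergetic ratios
  monoR <- vapply(sp@energies, function(e)
    exp(linearAttenuation("Al", e) * 0.3), numeric(1))
  poly <- transmissionRatio(sp, "Al", 3)
  expect_gte(poly, min(monoR)); expect_lte(poly, max(monoR))
  expect_equal(transmissionRatio(sp, "PMMA", 0), 1)
  expect_error(transmissionRatio(sp, "water", 1), "bundled materials: Al, PMMA")
})

test_that("inhomogeneity field hits its dispersion target with mean one", {
  expect_identical(inhomogeneityField(c(20, 30), dispersionTarget = 0),
                   matrix(1, 20, 30))
  f <- inhomogeneityField(c(60, 60), dispersionTarget = 20, seed = 1,
                          peakOffset = c(0.2, 0.1))
  expect_equal(mean(f), 1, tolerance = 1e-12)
  expect_gt(odDispersion(f, reference = mean(f))$max, 19.5)
  expect_lt(odDispersion(f, reference = mean(f))$max, 20.5)
  f4 <- inhomogeneityField(c(60, 60), dispersionTarget = 3.5, seed = 2)
  expect_lt(odDispersion(f4, reference = mean(f4))$max, 4.5)
})

test_that("film irradiation composes field, staircase and response", {
  flat <- flatBeam()
  u <- irradiateFilm(3, flat, filmSize = c(20, 20), seed = 1,
                     pixelPitch = 0.5, odNoiseSd = 0)
  expect_true(all(mapValues(u$dose) == 3))            # uniform 3 Gy map
  expect_equal(mapValues(u$od)[1, 1],
               doseToNetOD(3, filmResponse("scanner_red")))

  # construction oracle: plateau doses are nominal / per-step ratio
  ph <- phantomPreset("al_stairs")
  st <- irradiateFilm(3, flat, phantom = ph, filmSize = c(40, 20), seed = 1,
                      pixelPitch = 0.5, odNoiseSd = 0)
  ratios <- transmissionRatio(xraySpectrum(60, 1.3 + 1.25),
                              "Al", c(0, 3, 6), "dose")
  v <- mapValues(st$dose)
  xs <- (seq_len(ncol(v)) - 0.5) * 0.5
  for (k in 1:3) {
    sel <- xs >= (k - 1) * 12 & xs < k * 12
    expect_equal(unique(as.vector(v[, sel])), 3 / ratios[k],
                 tolerance = 1e-9)
  }
  # 3 plateaus; the open film beyond the staircase equals the open step
  expect_equal(length(unique(as.vector(v))), 3)

  # seeding contract: identical dose fields, different OD noise
  beam <- beamPreset("xray_60kv")
  a <- irradiateFilm(2, beam, filmSize = c(20, 20), seed = 1, pixelPitch = 0.5)
  b <- irradiateFilm(2, beam, filmSize = c(20, 20), seed = 2, pixelPitch = 0.5)
  expect_identical(mapValues(a$dose), mapValues(b$dose))
  expect_false(identical(mapValues(a$od), mapValues(b$od)))
  expect_equal(mean(mapValues(a$dose)), 2, tolerance = 1e-12)

  expect_error(irradiateFilm(3, flat, phantom = ph, filmSize = c(30, 30)),
               "exceeds the film")
  expect_error(irradiateFilm(-1, flat), ">= 0")
})

test_that("attenuation table interpolates log-log within its range", {
  expect_equal(attenuationCoeff("Al", 30), 1.128)
  expect_equal(attenuationCoeff("PMMA", 10), 3.357)
  expect_equal(materialDensity("Al"), 2.699)
  # log-log interpolation is exact on power laws between nodes
  mu20 <- attenuationCoeff("Al", 20); mu30 <- attenuationCoeff("Al", 30)
  slope <- log(mu30 / mu20) / log(30 / 20)
  expect_equal(attenuationCoeff("Al", 25), mu20 * (25 / 20)^slope,
               tolerance = 1e-12)
  expect_error(attenuationCoeff("Al", 3), "outside")
  expect_error(linearAttenuation("lead", 30), "unknown material")
})
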