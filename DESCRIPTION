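Package: rcfdose
Title: Radiochromic-Film Dosimetry with Flatbed-Scanner and
    Photodetector-Array Readout
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward simulation and inverse analysis for two-dimensional
    radiochromic-film dosimetry. Simulates film irradiation by a
    kilovoltage X-ray tube (inverse-square source law, filtered
    bremsstrahlung spectrum, field inhomogeneity, staircase attenuation
    phantoms) and by a homogeneous 137Cs field, and simulates the two
    readout devices: a flatbed transmission scanner and a 5x10
    light-dependent-resistor (LDR) array with multiplexed 12-bit ADC.
    The inverse pipeline computes net optical density maps, fits and
    inverts fifth-order calibration curves, normalizes per-LDR responses
    through a conversion-factor matrix, reconstructs absolute dose maps,
    and analyses staircase phantoms (background subtraction, three-zone
    statistics, dose-ratio tables, film-orientation detection).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'attenuation.R'
    'filmModel.R'
    'beamPhantom.R'
    'moemSensor.R'
    'dosePipeline.R'
    'io.R'
    'fixtures.R'
    'cli.R'
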