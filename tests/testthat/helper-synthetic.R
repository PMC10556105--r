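# Shared builders for synthetic test inputs.

# a noiseless, homogeneous beam: doses are exactly nominal
flatBeam <- function(preset = "xray_60kv")
  beamPreset(preset, fieldDispersionTarget = 0)

# noiseless sensor array without manufacturing spread
quietArray <- function(seed = 5, ...)
  sensorArray(seed = seed, gainSpreadSd = 0, glitchSd = 0, ...)

# scanner calibration curve learned from noiseless uniform films, 0-8 Gy
noiselessCurve <- function(doses = 0:8,
                           response = filmResponse("scanner_red")) {
  fitCalibration(doses, doseToNetOD(doses, response))
}

# minimal uncompressed 8-bit grayscale TIFF with resolution metadata,
# written tag by tag (the tiff package reads but does not write dpi tags)
writeTiffWithDpi <- function(path, values, dpi = 1200) {
  v <- matrix(as.integer(round(values)), nrow(values))
  stopifnot(all(v >= 0), all(v <= 255))
  h <- nrow(values); w <- ncol(values)
  con <- file(path, "wb")
  on.exit(close(con))
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); u16(42); u32(8)   # header, IFD at byte 8
  nTags <- 10L
  u16(nTags)
  tag <- function(id, type, count, value) { u16(id); u16(type); u32(count); u32(value) }
  ifdEnd <- 8 + 2 + nTags * 12 + 4
  ratX <- ifdEnd; ratY <- ifdEnd + 8; dataOff <- ifdEnd + 16
  tag(256, 3, 1, w)           # ImageWidth
  tag(257, 3, 1, h)           # ImageLength
  tag(258, 3, 1, 8)           # BitsPerSample
  tag(259, 3, 1, 1)           # Compression: none
  tag(262, 3, 1, 1)           # Photometric: BlackIsZero
  tag(273, 4, 1, dataOff)     # StripOffsets
  tag(279, 4, 1, w * h)       # StripByteCounts
  tag(282, 5, 1, ratX)        # XResolution
  tag(283, 5, 1, ratY)        # YResolution
  tag(296, 3, 1, 2)           # ResolutionUnit: inch
  u32(0)                      # next IFD
  u32(dpi); u32(1)            # X rational
  u32(dpi); u32(1)            # Y rational
  writeBin(as.raw(as.vector(t(v))), con)   # row-major strip
  invisible(path)
}
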