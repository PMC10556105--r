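#' @include utils.R
NULL

## Bundled photon interaction data, 5-100 keV.
##
## Mass attenuation coefficients mu/rho (cm^2/g, coherent scattering
## included) for aluminium and PMMA, and the mass energy-absorption
## coefficient mu_en/rho of water used as the dose-response weight of a
## water-equivalent detector. Values follow the standard NIST tabulations
## (PMMA via the H/C/O mixture rule); intermediate energies are obtained by
## log-log interpolation, which is accurate to well under 1% on this grid.
.attenuationTable <- data.frame(
  energy_kev = c(5, 6, 8, 10, 15, 20, 30, 40, 50, 60, 80, 100),
  al = c(193.4, 115.3, 50.33, 26.23, 7.955, 3.441, 1.128, 0.5685,
         0.3681, 0.2778, 0.2018, 0.1704),
  pmma = c(26.81, 15.24, 6.494, 3.357, 1.101, 0.5714, 0.3032, 0.2349,
           0.2073, 0.1924, 0.1752, 0.1641),
  water_muen = c(41.5, 23.3, 9.915, 4.944, 1.374, 0.5503, 0.1557,
                 0.06947, 0.04223, 0.03190, 0.02597, 0.02546)
)

.densities <- c(Al = 2.699, PMMA = 1.190)  # g/cm^3

materialColumn <- function(material) {
  key <- c(al = "al", aluminium = "al", aluminum = "al", pmma = "pmma")
  col <- key[tolower(material)]
  if (is.na(col))
    stop("unknown material '", material, "'; bundled materials: Al, PMMA",
         call. = FALSE)
  unname(col)
}

#' Bundled mass attenuation coefficients
#'
#' Mass attenuation coefficient mu/rho (cm^2/g, coherent included) of the
#' bundled materials, log-log interpolated over 5-100 keV.
#'
#' @param material "Al" or "PMMA" (case-insensitive).
#' @param energy photon energies, keV.
#' @return numeric vector of mu/rho in cm^2/g.
#' @examples attenuationCoeff("Al", 30)   # 1.128
#' @export
attenuationCoeff <- function(material, energy) {
  col <- materialColumn(material)
  logLogInterp(energy, .attenuationTable$energy_kev, .attenuationTable[[col]])
}

#' Density of the bundled materials
#'
#' @param material "Al" or "PMMA".
#' @return density in g/cm^3.
#' @export
materialDensity <- function(material) {
  d <- c(al = .densities[["Al"]], pmma = .densities[["PMMA"]])
  unname(d[materialColumn(material)])
}

#' Linear attenuation coefficient
#'
#' @inheritParams attenuationCoeff
#' @return mu in 1/cm.
#' @export
linearAttenuation <- function(material, energy) {
  attenuationCoeff(material, energy) * materialDensity(material)
}

# mass energy-absorption coefficient of water (cm^2/g); internal, used for
# the fluence-to-dose response weighting of a water-equivalent detector
waterMuEn <- function(energy) {
  logLogInterp(energy, .attenuationTable$energy_kev,
               .attenuationTable$water_muen)
}
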