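## Photon interaction physics for the Monte Carlo transport: mass attenuation
## coefficient tables for air and water and the Compton kinematics used by
## the scatter sampler.

# Photoelectric mass attenuation coefficients (cm^2/g) for water on a coarse
# energy grid, approximating a standard reference compilation; air values are
# close to water per gram in this range (effective-Z ~7.6 vs ~7.4) and are
# taken as 0.92 x water. Coherent scatter is deliberately omitted from the
# totals (small-angle, nearly elastic; not modelled in transport).
.peEnergies <- c(10, 15, 20, 30, 40, 50, 60, 80, 100, 150, 200)
.peWater <- c(4.944, 1.374, 0.5437, 0.1493, 0.05941, 0.02911,
              0.01617, 0.006396, 0.003134, 0.0008534, 0.0003374)

.ELECTRON_REST_KEV <- 511.0
.RE_CM <- 2.8179403e-13          # classical electron radius (cm)
.AVOGADRO <- 6.02214076e23
.ZA_WATER <- 0.5551              # electrons per atomic mass unit
.ZA_AIR <- 0.4992

#' Total Klein-Nishina cross-section per electron
#'
#' Closed-form integral of the Klein-Nishina differential cross-section over
#' all angles, in cm^2 per electron.
#'
#' @param energy photon energy (keV)
#' @return cross-section (cm^2)
#' @export
kleinNishinaTotal <- function(energy) {
  k <- energy / .ELECTRON_REST_KEV
  term1 <- (1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - log(1 + 2 * k) / k)
  term2 <- log(1 + 2 * k) / (2 * k)
  term3 <- (1 + 3 * k) / (1 + 2 * k)^2
  2 * pi * .RE_CM^2 * (term1 + term2 - term3)
}

#' Compton-scattered photon energy
#'
#' E' = E / (1 + (E/511)(1 - cos(theta))) for scattering angle theta.
#'
#' @param energy incident photon energy (keV)
#' @param angle scattering angle (radians)
#' @return scattered energy (keV)
#' @export
comptonEnergy <- function(energy, angle) {
  energy / (1 + (energy / .ELECTRON_REST_KEV) * (1 - cos(angle)))
}

#' Physics tables for photon transport
#'
#' Per-material mass attenuation coefficients (cm^2/g) on a 1-keV energy
#' grid, for the total, photoelectric and incoherent (Compton) channels.
#' The incoherent channel is computed from the Klein-Nishina total
#' cross-section and the material's electrons-per-gram; the photoelectric
#' channel is log-log interpolated from a small built-in reference table.
#' Emission energy is fixed at 140.5 keV (99mTc).
#'
#' @slot energies energy grid (keV)
#' @slot photoelectric,incoherent,total matrices, energies x materials
#'   (columns: air, water)
#' @slot emissionEnergy emission energy (keV)
#' @export
setClass("PhysicsTables",
         representation(energies = "numeric", photoelectric = "matrix",
                        incoherent = "matrix", total = "matrix",
                        emissionEnergy = "numeric"))

setValidity("PhysicsTables", function(object) {
  if (any(object@total < object@photoelectric - 1e-12) ||
      any(object@total < object@incoherent - 1e-12))
    return("total must dominate each partial channel")
  TRUE
})

#' @param eMin,eMax energy grid bounds (keV)
#' @param emissionEnergy photon emission energy (keV)
#' @rdname PhysicsTables-class
#' @export
physicsTables <- function(eMin = 10, eMax = 200, emissionEnergy = 140.5) {
  energies <- seq(eMin, eMax, by = 1)
  peW <- exp(approx(log(.peEnergies), log(.peWater), xout = log(energies),
                    rule = 2)$y)
  peA <- 0.92 * peW
  sigma <- kleinNishinaTotal(energies)
  incW <- sigma * .AVOGADRO * .ZA_WATER
  incA <- sigma * .AVOGADRO * .ZA_AIR
  pe <- cbind(air = peA, water = peW)
  inc <- cbind(air = incA, water = incW)
  new("PhysicsTables", energies = energies, photoelectric = pe,
      incoherent = inc, total = pe + inc,
      emissionEnergy = as.numeric(emissionEnergy))
}

setMethod("show", "PhysicsTables", function(object) {
  cat(sprintf("PhysicsTables: %g-%g keV (%d points), emission %.4g keV\n",
              min(object@energies), max(object@energies),
              length(object@energies), object@emissionEnergy))
})

#' Mass attenuation coefficient lookup
#'
#' @param tables a [PhysicsTables-class]
#' @param energy photon energy (keV)
#' @param material "air" or "water"
#' @param channel "total", "photoelectric" or "incoherent"
#' @return mass attenuation coefficient (cm^2/g)
#' @export
massAttenuation <- function(tables, energy, material = "water",
                            channel = "total") {
  m <- slot(tables, channel)[, material]
  approx(tables@energies, m, xout = energy, rule = 2)$y
}
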