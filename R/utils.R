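#' Molar concentration from a weighed mass
#'
#' Bench-work helper: concentration (M) of `mass_mg` milligrams of a
#' compound of molar mass `mw` dissolved in `volume_mL` millilitres.
#'
#' @param mass_mg mass (mg).
#' @param mw molar mass (g/mol).
#' @param volume_mL solution volume (mL).
#' @return concentration (M).
#' @examples
#' mass_to_molar(17.6, 17600, 20)  # 5e-05 M, i.e. 50 uM metmyoglobin
#' @export
mass_to_molar <- function(mass_mg, mw, volume_mL) {
  if (any(c(mass_mg, mw, volume_mL) <= 0))
    stop("mass, molar mass and volume must be > 0")
  (mass_mg / 1000) / mw / (volume_mL / 1000)
}

#' First-order half-life
#'
#' @param k first-order rate constant (s^-1, > 0).
#' @return half-life `log(2)/k` in seconds.
#' @examples
#' half_life(120e-5) / 60  # ~ 10 minutes
#' @export
half_life <- function(k) {
  if (any(k <= 0)) stop("rate constant must be > 0")
  log(2) / k
}
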