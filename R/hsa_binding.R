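#' Parameters of the fluorescence-quenching binding model
#'
#' 1:1 ligand-protein binding observed through the intrinsic (Trp)
#' fluorescence of the protein. The measured intensity is
#' `I_F = fP [P] exp(-epsL_sum * path_l * Lt)`: free-protein fluorescence
#' attenuated by the inner-filter effect of the total ligand, whose molar
#' absorption at the excitation and emission wavelengths sums to
#' `epsL_sum`, over a mean excitation-light path `path_l` at the point of
#' emission detection.
#'
#' @param Kb ligand-protein binding constant (M^-1, >= 0).
#' @param fP molar fluorescence intensity of the free protein
#'   (M^-1, in instrument units; > 0).
#' @param epsL_ex,epsL_em ligand molar absorption coefficients at the
#'   excitation and emission wavelengths (M^-1 cm^-1, >= 0); their sum
#'   drives the inner-filter correction.
#' @param path_l mean excitation-light path at the detection point (cm,
#'   default 0.65).
#' @return list of class `"quench_params"` (with `epsL_sum` precomputed).
#' @export
quench_params <- function(Kb, fP, epsL_ex = 0, epsL_em = 0, path_l = 0.65) {
  if (!is.finite(Kb) || Kb < 0) stop("Kb must be >= 0")
  if (!is.finite(fP) || fP <= 0) stop("fP must be > 0")
  if (epsL_ex < 0 || epsL_em < 0) stop("molar absorptions must be >= 0")
  if (!is.finite(path_l) || path_l <= 0) stop("path_l must be > 0")
  structure(list(Kb = Kb, fP = fP, epsL_ex = epsL_ex, epsL_em = epsL_em,
                 epsL_sum = epsL_ex + epsL_em, path_l = path_l),
            class = "quench_params")
}

#' Free and bound species of a 1:1 ligand-protein equilibrium
#'
#' Solves the mass-action system `Lt = [L](1 + Kb [P])`,
#' `Pt = [P](1 + Kb [L])`, `[PL] = Kb [P][L]` for the unique nonnegative
#' root, using the numerically stable form of the quadratic in `[P]`.
#'
#' @param Kb binding constant (M^-1, >= 0).
#' @param Lt,Pt total ligand and protein concentrations (M, >= 0);
#'   `Lt` may be a vector.
#' @return data frame with columns `L`, `P`, `PL` (M).
#' @examples
#' free_species(273e3, Lt = 2e-6, Pt = 2e-6)
#' @export
free_species <- function(Kb, Lt, Pt) {
  if (Kb < 0) stop("Kb must be >= 0")
  if (any(Lt < 0) || Pt < 0) stop("concentrations must be >= 0")
  if (Kb == 0) {
    return(data.frame(L = Lt, P = rep(Pt, length(Lt)),
                      PL = rep(0, length(Lt))))
  }
  # each species from its own cancellation-free quadratic root; the shared
  # discriminant 1 + 2Kb(Lt+Pt) + (Kb(Lt-Pt))^2 is a sum of positive terms
  s <- sqrt(1 + 2 * Kb * (Lt + Pt) + (Kb * (Lt - Pt))^2)
  bP <- 1 + Kb * (Lt - Pt)
  P <- ifelse(bP >= 0, 2 * Pt / (bP + s), (s - bP) / (2 * Kb))
  bL <- 1 + Kb * (Pt - Lt)
  L <- ifelse(bL >= 0, 2 * Lt / (bL + s), (s - bL) / (2 * Kb))
  PL <- 2 * Kb * Lt * Pt / (1 + Kb * (Lt + Pt) + s)
  data.frame(L = L, P = P, PL = PL)
}

#' Predicted protein fluorescence in a quenching titration
#'
#' Evaluates `I_F = fP [P] exp(-epsL_sum * path_l * Lt)` with the free
#' protein concentration from [free_species()]. The total ligand
#' concentration (not the free one) drives the inner-filter exponential.
#' Strictly decreasing in `Lt` whenever `Kb > 0` or `epsL_sum > 0`.
#'
#' @param params a [quench_params()] object.
#' @param Lt total ligand concentration(s) (M).
#' @param Pt total protein concentration (M).
#' @return fluorescence intensity (instrument units).
#' @export
predicted_fluorescence <- function(params, Lt, Pt) {
  stopifnot(inherits(params, "quench_params"))
  sp <- free_species(params$Kb, Lt, Pt)
  params$fP * sp$P * exp(-params$epsL_sum * params$path_l * Lt)
}

#' Fit the quenching titration for the binding constant
#'
#' Least-squares fit of [predicted_fluorescence()] to a fluorescence vs
#' total-ligand series, estimating `Kb` and `fP` with the inner-filter
#' parameters (`epsL_ex + epsL_em`, `path_l`) fixed: the ligand absorption
#' is determined independently by UV-visible spectroscopy (Beer's plot)
#' and must be supplied, never fitted.
#'
#' @param titration data frame with columns `ligand_total_M` and
#'   `fluorescence` (>= 5 points).
#' @param Pt total protein concentration (M).
#' @param epsL_ex,epsL_em fixed ligand molar absorptions at excitation /
#'   emission wavelengths (M^-1 cm^-1).
#' @param path_l fixed mean excitation path (cm, default 0.65).
#' @param init optional named starting values for `Kb`, `fP`.
#' @return a `"flavokin_fit"` object.
#' @export
fit_quench <- function(titration, Pt, epsL_ex = 0, epsL_em = 0,
                       path_l = 0.65, init = NULL) {
  stopifnot(is.data.frame(titration),
            all(c("ligand_total_M", "fluorescence") %in% names(titration)))
  if (nrow(titration) < 5L) stop("need at least 5 titration points")
  Lt <- titration$ligand_total_M
  IF <- titration$fluorescence
  if (is.null(init)) {
    init <- c(Kb = 1 / max(Lt[Lt > 0], Pt), fP = max(IF) / Pt)
  }
  least_squares_fit(
    model = function(p)
      list(predicted_fluorescence(
        quench_params(p$Kb, p$fP, epsL_ex, epsL_em, path_l), Lt, Pt)),
    observed = list(IF),
    init = init,
    transform = c(Kb = "log", fP = "log"))
}

#' Deconvolve the intrinsic chalcone binding constant
#'
#' A titration performed on an equilibrated pigment solution measures an
#' apparent binding constant averaged over the chalcone and the residual
#' colored forms. Under linear mole-fraction weighting,
#' `Kb_apparent = f * Kb_chalcone + (1 - f) * Kb_colored`, the intrinsic
#' chalcone constant is recovered as
#' `Kb_chalcone = (Kb_apparent - (1 - f) * Kb_colored) / f`.
#'
#' @param Kb_apparent apparent (mixture) binding constant (M^-1).
#' @param Kb_colored binding constant of the colored forms (M^-1).
#' @param chalcone_fraction mole fraction f of the chalcone in the mixture
#'   (0 < f <= 1; a 3:1 chalcone-to-colored ratio gives f = 0.75).
#' @return intrinsic chalcone binding constant (M^-1).
#' @examples
#' deconvolve_chalcone_Kb(344e3, 273e3, 0.75)  # ~ 368e3
#' @export
deconvolve_chalcone_Kb <- function(Kb_apparent, Kb_colored,
                                   chalcone_fraction) {
  if (!is.finite(chalcone_fraction) || chalcone_fraction <= 0 ||
      chalcone_fraction > 1)
    stop("chalcone_fraction must lie in (0, 1]")
  (Kb_apparent - (1 - chalcone_fraction) * Kb_colored) / chalcone_fraction
}
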