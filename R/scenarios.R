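#' Named ground-truth scenarios for simulation and recovery studies
#'
#' Parameter sets assembled from published fits of the P1/P2 flavylium
#' pigments (iron binding kinetics and equilibria, pKa2 titrations, HSA
#' quenching titrations, peroxidation inhibition), together with the assay
#' designs they were measured under (50 uM pigment and iron/pigment ratios
#' 0.5-5 at pH 4; 2 uM HSA at pH 7.4; 0.7 mM linoleic acid + 0.5 uM
#' metmyoglobin at pH 5.8). Free-pigment molar absorptions, which the
#' published tables do not list, are set to plausible values consistent
#' with the reported t = 0 absorbances; each scenario records its own.
#'
#' @return named list of scenarios. Each scenario is a list with elements
#'   `family`, `params` (a params object for that family), and the
#'   design/conditions fields the generators need (`L0`, `M0`, `times`,
#'   `Lt`, `Mt`, `pH_grid`, `Pt`, `cond` ... as applicable) plus a default
#'   `noise` (see [noise_spec()]).
#' @examples
#' sc <- flavokin_scenarios()
#' names(sc)
#' sc$table1_ratio1$params$kb
#' @export
flavokin_scenarios <- function() {
  uM <- 1e-6
  list(
    # Fe(III)-P1 two-step binding, equimolar iron and pigment
    table1_ratio1 = list(
      family = "two_step",
      params = two_step_params(
        kb = 17890, kr = 4e-3,
        eps_L = c(`470` = 15000, `620` = 500),
        eps_1 = c(`470` = 10340, `620` = 12270),
        eps_2 = c(`470` = 7910, `620` = 10810)),
      L0 = 50 * uM, M0 = 50 * uM,
      times = seq(0, 120, by = 0.5),
      noise = noise_spec("additive", 0.002)),
    # Fe(III)-P1 two-step binding, 4 equiv. iron
    table1_ratio4 = list(
      family = "two_step",
      params = two_step_params(
        kb = 2670, kr = 29e-3,
        eps_L = c(`470` = 15000, `620` = 500),
        eps_1 = c(`470` = 10360, `620` = 9710),
        eps_2 = c(`470` = 8900, `620` = 9930)),
      L0 = 50 * uM, M0 = 200 * uM,
      times = seq(0, 120, by = 0.5),
      noise = noise_spec("additive", 0.002)),
    # Fe(II)-P2: autoxidation then binding, 5 equiv. iron, no chalcone
    table2_ratio5 = list(
      family = "autox",
      params = autox_params(
        kautox = 163e-5, kb = 785, kh_obs = 0,
        eps_L = c(`470` = 12000, `650` = 300),
        eps_ML = c(`470` = 8810, `650` = 7340)),
      L0 = 50 * uM, M0 = 250 * uM,
      times = seq(0, 900, by = 15),
      noise = noise_spec("additive", 0.002)),
    # Fe(II)-P1: autoxidation, binding and chalcone formation, 5 equiv.
    table1_noteA_FeII_P1 = list(
      family = "autox",
      params = autox_params(
        kautox = 58e-5, kb = 250, kh_obs = 95e-5,
        eps_L = c(`470` = 15000, `630` = 400, `375` = 3000),
        eps_ML = c(`470` = 10700, `630` = 11800, `375` = 4200),
        eps_CE = c(`470` = 0, `630` = 0, `375` = 33800)),
      L0 = 50 * uM, M0 = 250 * uM,
      times = seq(0, 900, by = 15),
      noise = noise_spec("additive", 0.002)),
    # Fe(III)-P2 equilibrium isotherm at 650 nm
    feIII_P2_isotherm = list(
      family = "isotherm",
      params = isotherm_params(Kb = 21e3, delta_eps = 6500),
      Lt = 50 * uM, Mt = c(0.5, 1, 2, 3, 4, 5) * 50 * uM,
      noise = noise_spec("additive", 0.005)),
    # P1 quinonoid base titration at 550 nm, no HSA
    table3_P1_noHSA = list(
      family = "pka2",
      truth = c(pKa2 = 7.12, rA = 6.3, A_neutral = 0.3),
      pH_grid = seq(6, 8, by = 0.2),
      noise = noise_spec("additive", 0.005)),
    # P1 titration at 580 nm with 5 equiv. HSA
    table3_P1_HSA = list(
      family = "pka2",
      truth = c(pKa2 = 7.11, rA = 3.1, A_neutral = 0.3),
      pH_grid = seq(6, 8, by = 0.2),
      noise = noise_spec("additive", 0.005)),
    # P2 color loss at 530 nm, pH 7.4 (first-order hydration)
    table3_P2_decay = list(
      family = "first_order",
      params = list(A0 = c(`530` = 0.5), A_inf = c(`530` = 0.02),
                    kh_obs = 88e-5),
      times = seq(0, 7000, by = 30),
      noise = noise_spec("additive", 0.002)),
    # HSA quenching titrations (2 uM HSA, pH 7.4, l = 0.65 cm)
    table4_P1_colored = list(
      family = "quench",
      params = quench_params(Kb = 273e3, fP = 15.5e6,
                             epsL_ex = 8900, epsL_em = 5800),
      Pt = 2 * uM, Lt = seq(0, 20 * uM, length.out = 11),
      noise = noise_spec("multiplicative", 0.01)),
    table4_P1_chalcone = list(
      family = "quench",
      params = quench_params(Kb = 344e3, fP = 14.2e6,
                             epsL_ex = 15800, epsL_em = 16400),
      Pt = 2 * uM, Lt = seq(0, 20 * uM, length.out = 11),
      noise = noise_spec("multiplicative", 0.01)),
    table4_P2_colored = list(
      family = "quench",
      params = quench_params(Kb = 17.5e3, fP = 14.1e6,
                             epsL_ex = 3800, epsL_em = 2800),
      Pt = 2 * uM, Lt = seq(0, 20 * uM, length.out = 11),
      noise = noise_spec("multiplicative", 0.01)),
    table4_P2_chalcone = list(
      family = "quench",
      params = quench_params(Kb = 58.4e3, fP = 13.5e6,
                             epsL_ex = 7200, epsL_em = 7000),
      Pt = 2 * uM, Lt = seq(0, 20 * uM, length.out = 11),
      noise = noise_spec("multiplicative", 0.01)),
    # heme-induced peroxidation inhibited by P1 colored forms, 2.5 uM
    table5_P1_2p5uM = list(
      family = "perox",
      params = perox_params(r2 = 2.1, AE = 11, n = 4.0, ki1 = 3e3),
      cond = perox_conditions(AH0 = 2.5 * uM),
      times = seq(0, 1800, by = 10),
      noise = noise_spec("additive", 0.005)),
    # uninhibited control for the same assay
    perox_uninhibited = list(
      family = "perox",
      params = perox_params(r2 = 2.1, ki1 = 3e3),
      cond = perox_conditions(AH0 = 0),
      times = seq(0, 1800, by = 10),
      noise = noise_spec("additive", 0.005))
  )
}

#' Published kinetic analysis of inhibited lipid peroxidation
#'
#' The full table of fitted `(r2, AE, n)` values for the four antioxidants
#' (the two pigments and their chalcones) across antioxidant
#' concentrations, with `ki1` fixed at 3e3 M^-1 s^-1. Useful as ground
#' truth for recovery studies and as a worked-example input.
#'
#' @return data frame with columns `antioxidant`, `conc_uM`, `r2`, `AE`,
#'   `n`.
#' @export
table5_parameters <- function() {
  data.frame(
    antioxidant = rep(c("P1", "P1-CE", "P2", "P2-CE"), c(5L, 5L, 5L, 4L)),
    conc_uM = c(0.5, 1, 1.5, 2, 2.5,
                0.5, 1, 1.5, 2, 2.5,
                1.5, 2.5, 5, 6.25, 7.5,
                1.25, 2.5, 3.75, 5),
    r2 = c(2.8, 2.6, 2.3, 2.2, 2.1,
           2.7, 2.4, 2.3, 2.1, 1.9,
           2.4, 2.3, 1.9, 1.6, 1.0,
           2.5, 2.1, 1.6, 1.2),
    AE = c(137, 40, 38, 29, 11,
           108, 59, 40, 29, 28,
           95, 76, 15, 17, 24,
           31, 19, 21, 29),
    n = c(3.0, 2.5, 2.5, 3.2, 4.0,
          4.4, 5.6, 4.3, 5.2, 3.9,
          0.9, 0.5, 1.4, 1.2, 0.9,
          3.1, 3.5, 1.9, 1.3))
}
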