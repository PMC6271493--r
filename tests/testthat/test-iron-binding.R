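two_step_p1 <- function() {
  two_step_params(kb = 17890, kr = 4e-3,
                  eps_L = c(`470` = 15000, `620` = 500),
                  eps_1 = c(`470` = 10340, `620` = 12270),
                  eps_2 = c(`470` = 7910, `620` = 10810))
}

test_that("two-step simulation honours initial conditions and conservation", {
  p <- two_step_p1()
  sim <- simulate_two_step(p, 50e-6, 50e-6, seq(0, 120, 0.5))
  st <- sim$states
  expect_equal(st$L[1], 50e-6)
  expect_equal(st$FeL1[1], 0)
  expect_equal(sim$traces$A_470[1], 15000 * 50e-6)
  # pigment and iron balances hold at every time point
  expect_rel_equal(st$L + st$FeL1 + st$FeL2, rep(50e-6, nrow(st)), 1e-9)
  expect_rel_equal(st$Fe + st$FeL1 + st$FeL2, rep(50e-6, nrow(st)), 1e-9)
  expect_true(all(as.matrix(st[-1]) >= -1e-15))
  expect_error(simulate_two_step(p, -1e-6, 5e-5, c(0, 1)), "> 0")
  expect_error(simulate_two_step(p, 5e-5, 5e-5, c(1, 2)), "start at 0")
})

test_that("two-step ODE with kr = 0 matches the equal-concentration closed form", {
  p <- two_step_params(kb = 17890, kr = 0,
                       eps_L = c(`470` = 15000), eps_1 = c(`470` = 10340),
                       eps_2 = c(`470` = 7910))
  L0 <- 50e-6
  tt <- seq(0, 120, 0.5)
  sim <- simulate_two_step(p, L0, L0, tt)
  expect_rel_equal(sim$states$L, L0 / (1 + p$kb * L0 * tt), 1e-8)
})

test_that("excess-iron kinetics converge to the complex-2 plateau absorbance", {
  p <- two_step_params(kb = 2670, kr = 29e-3,
                       eps_L = c(`470` = 15000, `620` = 500),
                       eps_1 = c(`470` = 10360, `620` = 9710),
                       eps_2 = c(`470` = 8900, `620` = 9930))
  sim <- simulate_two_step(p, 50e-6, 200e-6, c(seq(0, 120, 0.5), 2000))
  n <- nrow(sim$traces)
  expect_equal(sim$traces$A_470[n], 8900 * 50e-6, tolerance = 1e-6)
  expect_equal(sim$traces$A_620[n], 9930 * 50e-6, tolerance = 1e-6)
})

test_that("free-metal quadratic matches the bisection oracle", {
  # worked case: Kb = 21e3, delta_eps = 6500, 50 uM ligand, 250 uM metal
  ip <- isotherm_params(21e3, 6500)
  dA <- isotherm_deltaA(ip, 50e-6, 250e-6)
  Fe <- bisect_free_metal(21e3, 50e-6, 250e-6)
  expect_equal(dA, 6500 * (250e-6 - Fe), tolerance = 1e-10)
  expect_equal(dA, 0.265, tolerance = 1e-2)
  # limits
  expect_equal(isotherm_deltaA(ip, 50e-6, 0), 0)
  strong <- isotherm_params(1e12, 6500)
  expect_equal(isotherm_deltaA(strong, 50e-6, 20e-6), 6500 * 20e-6,
               tolerance = 1e-6)
  # property: stable root vs bisection over random draws
  set.seed(31)
  for (i in 1:1000) {
    Kb <- 10^runif(1, 1, 7)
    Lt <- 10^runif(1, -6, -3)
    Mt <- 10^runif(1, -7, -2)
    d1 <- isotherm_deltaA(isotherm_params(Kb, 1000), Lt, Mt)
    # bound amount bisected directly from its own mass law
    d2 <- 1000 * bisect_complex(Kb, Lt, Mt)
    expect_rel_equal(d1, d2, 1e-12)
  }
})

test_that("isotherm response is nondecreasing in total metal and in Kb", {
  Mt <- seq(0, 500e-6, 10e-6)
  dA <- isotherm_deltaA(isotherm_params(21e3, 6500), 50e-6, Mt)
  expect_true(all(diff(dA) >= 0))
  dKb <- vapply(10^seq(2, 7, 0.25), function(K)
    isotherm_deltaA(isotherm_params(K, 6500), 50e-6, 100e-6), numeric(1))
  expect_true(all(diff(dKb) >= 0))
})

test_that("isotherm fit recovers noiseless parameters and flags linear series", {
  ip <- isotherm_params(21e3, 6500)
  d <- make_isotherm(ip, 50e-6, c(0.5, 1, 2, 3, 4, 5) * 50e-6,
                     noise_spec(sigma = 0))
  fit <- fit_isotherm(d, 50e-6)
  expect_rel_equal(fit$estimates[c("Kb", "delta_eps")],
                   c(Kb = 21e3, delta_eps = 6500), 1e-7)
  expect_true(fit$converged)
  # data exactly linear in Mt: Kb and delta_eps only identified as a product
  lin <- data.frame(Mt = c(0.5, 1, 2, 3, 4, 5) * 50e-6,
                    deltaA = 1000 * c(0.5, 1, 2, 3, 4, 5) * 50e-6)
  expect_warning(lfit <- fit_isotherm(lin, 50e-6), "anticorrelated")
  expect_false(lfit$identifiable)
})

test_that("two-step fit recovers generating parameters", {
  p <- two_step_p1()
  tr <- make_kinetic_traces("two_step", p, list(L0 = 50e-6, M0 = 50e-6),
                            seq(0, 120, 0.5), noise_spec(sigma = 0))
  fit <- fit_two_step(tr, 50e-6, 50e-6)
  truth <- c(kb = 17890, kr = 4e-3, eps1_470 = 10340, eps1_620 = 12270,
             eps2_470 = 7910, eps2_620 = 10810)
  expect_rel_equal(fit$estimates[names(truth)], truth, 1e-6)
  expect_true(fit$converged)
})

test_that("barely-progressing rearrangement is reported with undefined or large error", {
  p <- two_step_params(kb = 17890, kr = 1e-6,
                       eps_L = c(`470` = 15000, `620` = 500),
                       eps_1 = c(`470` = 10340, `620` = 12270),
                       eps_2 = c(`470` = 7910, `620` = 10810))
  tr <- make_kinetic_traces("two_step", p, list(L0 = 50e-6, M0 = 50e-6),
                            seq(0, 120, 0.5),
                            noise_spec("additive", 0.002, seed = 3))
  fit <- fit_two_step(tr, 50e-6, 50e-6)
  se_kr <- fit$std_errors[["kr"]]
  expect_true(is.na(se_kr) || se_kr > fit$estimates[["kr"]])
})

test_that("autoxidation simulator reduces to its limiting regimes", {
  eL <- c(`470` = 12000, `650` = 300)
  eML <- c(`470` = 8810, `650` = 7340)
  tt <- seq(0, 900, 15)
  # no autoxidation: pure hydration, no complex ever forms
  p0 <- autox_params(kautox = 0, kb = 785, kh_obs = 95e-5,
                     eps_L = eL, eps_ML = eML)
  st0 <- simulate_autox(p0, 50e-6, 250e-6, tt)$states
  expect_rel_equal(st0$L, 50e-6 * exp(-95e-5 * tt), 1e-8)
  expect_true(all(st0$LFe == 0))
  # no hydration: pigment is conserved between free and bound pools
  p1 <- autox_params(kautox = 163e-5, kb = 785, kh_obs = 0,
                     eps_L = eL, eps_ML = eML)
  st1 <- simulate_autox(p1, 50e-6, 250e-6, tt)$states
  expect_rel_equal(st1$L + st1$LFe, rep(50e-6, nrow(st1)), 1e-9)
  # iron balance across all three pools
  expect_rel_equal(st1$FeII + st1$FeIII + st1$LFe, rep(250e-6, nrow(st1)),
                   1e-9)
  expect_true(all(as.matrix(st1[-1]) >= -1e-15))
})

test_that("complex absorbance shows a lag while Fe(III) accumulates", {
  p <- autox_params(kautox = 163e-5, kb = 785, kh_obs = 0,
                    eps_L = c(`470` = 12000, `650` = 0),
                    eps_ML = c(`470` = 8810, `650` = 7340))
  tr <- simulate_autox(p, 50e-6, 250e-6, seq(0, 900, 5))$traces
  inc <- diff(tr$A_650)
  expect_lt(inc[1], max(inc) / 5)
  expect_gt(which.max(inc), 5)
})

test_that("autoxidation fits recover parameters in full and steady-state modes", {
  sc <- flavokin_scenarios()
  s <- sc$table2_ratio5
  tr <- make_kinetic_traces("autox", s$params, list(L0 = s$L0, M0 = s$M0),
                            s$times, noise_spec(sigma = 0))
  fit <- fit_autox(tr, s$L0, s$M0, mode = "full")
  expect_rel_equal(fit$estimates[c("kautox", "kb")],
                   c(kautox = 163e-5, kb = 785), 1e-5)
  # P1 variant: three wavelengths, chalcone channel, kh fitted
  s2 <- sc$table1_noteA_FeII_P1
  tr2 <- make_kinetic_traces("autox", s2$params,
                             list(L0 = s2$L0, M0 = s2$M0), s2$times,
                             noise_spec(sigma = 0))
  fit2 <- fit_autox(tr2, s2$L0, s2$M0, mode = "full",
                    eps_CE = s2$params$eps_CE, fit_kh = TRUE)
  expect_rel_equal(fit2$estimates[c("kautox", "kb", "kh_obs")],
                   c(kautox = 58e-5, kb = 250, kh_obs = 95e-5), 1e-4)
  # steady-state variant at substoichiometric iron: kb drops out and the
  # Fe(III)-transparent approximation recovers the rates to a few percent
  p <- autox_params(kautox = 215e-5, kb = 5e3, kh_obs = 13.7e-5,
                    eps_L = c(`470` = 12000, `650` = 300),
                    eps_ML = c(`470` = 8800, `650` = 7200))
  tr3 <- make_kinetic_traces("autox", p, list(L0 = 50e-6, M0 = 25e-6),
                             seq(0, 900, 15), noise_spec(sigma = 0))
  fit3 <- fit_autox(tr3, 50e-6, 25e-6, mode = "steady_state_FeIII",
                    eps_ML = p$eps_ML)
  expect_rel_equal(fit3$estimates[c("kautox", "kh_obs")],
                   c(kautox = 215e-5, kh_obs = 13.7e-5), 0.05)
  # full mode at ratio <= 1 is allowed but flagged
  expect_warning(fit_autox(tr3, 50e-6, 25e-6, mode = "full"),
                 "weakly identified")
})
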