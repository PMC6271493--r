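test_that("conjugated-diene simulation starts at the hydroperoxide seed", {
  p <- perox_params(r2 = 2.1, ki1 = 3e3)
  cond <- perox_conditions()
  sim <- simulate_cd(p, cond, seq(0, 300, 10))
  expect_equal(sim$trace$A_234[1], 24e3 * 1e-6)
  expect_error(simulate_cd(p, cond, c(10, 20)), "start at 0")
})

test_that("without propagation the hydroperoxide pool only decays", {
  p <- perox_params(r2 = 0, ki1 = 3e3)
  st <- simulate_cd(p, perox_conditions(), seq(0, 1800, 10))$states
  expect_true(all(diff(st$LOOH) <= 1e-15))
})

test_that("heme is conserved, states stay nonnegative, antioxidant only depletes", {
  p <- perox_params(r2 = 2.1, AE = 11, n = 4, ki1 = 3e3)
  cond <- perox_conditions(AH0 = 2.5e-6)
  st <- simulate_cd(p, cond, seq(0, 1800, 10))$states
  expect_rel_equal(st$MbIII + st$MbIV, rep(cond$Mb0, nrow(st)), 1e-9)
  expect_true(all(diff(st$AHu) <= 1e-18))
  expect_true(all(as.matrix(st[-1]) >= -1e-15))
})

test_that("early uninhibited growth matches the closed-form sqrt dynamics", {
  # with MbFe(IV) at quasi-steady state both heme channels initiate at the
  # same rate, so Ri = 2*ki1*[MbIII][LOOH]; including first-order LOOH
  # consumption, sqrt(LOOH) obeys d(sqrt y)/dt = c - a*sqrt(y) with
  # c = r2*LH0*sqrt(2*ki1*Mb0)/2 and a = ki1*Mb0/2, solved exactly.
  p <- perox_params(r2 = 2.1, ki1 = 3e3)
  cond <- perox_conditions()
  tt <- seq(0, 30, 1)
  y <- simulate_cd(p, cond, tt)$states$LOOH
  c0 <- 0.5 * p$r2 * cond$LH0 * sqrt(2 * p$ki1 * cond$Mb0)
  a <- p$ki1 * cond$Mb0 / 2
  closed <- (c0 / a + (sqrt(cond$LOOH0) - c0 / a) * exp(-a * tt))^2
  expect_rel_equal(y, closed, 0.02)
})

test_that("uninhibited curves accelerate out of a lag and deplete the lipid", {
  p <- perox_params(r2 = 2.1, ki1 = 3e3)
  st <- simulate_cd(p, perox_conditions(), seq(0, 7200, 30))$states
  A <- 24e3 * st$LOOH
  growth <- diff(A)
  # the growth rate accelerates well beyond its initial (lag-phase) value
  expect_gt(max(growth), 3 * growth[1])
  expect_gt(which.max(growth), 3)
  # growth is monotone while the lipid pool is still substantial
  expect_true(all(growth[st$LH[-1] > 0.5 * 7e-4] > 0))
  # the lipid is eventually consumed, after which hydroperoxides decay
  expect_lt(st$LH[nrow(st)], 0.01 * 7e-4)
  expect_lt(growth[length(growth)], 0)
})

test_that("stronger or more concentrated antioxidants slow diene accumulation", {
  t_grid <- seq(0, 900, 10)
  A_end <- function(AH0, n = 4) {
    A <- simulate_cd(perox_params(r2 = 2.1, AE = 11, n = n, ki1 = 3e3),
                     perox_conditions(AH0 = AH0), t_grid)$trace$A_234
    A[length(A)]
  }
  expect_gt(A_end(0), A_end(0.5e-6))
  expect_gt(A_end(0.5e-6), A_end(1e-6))
  expect_gt(A_end(1e-6), A_end(2e-6))
  expect_gt(A_end(2e-6, n = 2), A_end(2e-6, n = 6))
})

test_that("uninhibited fit recovers ki1 and r2 and flags truncated traces", {
  cond <- perox_conditions()
  tr <- make_kinetic_traces("perox", perox_params(r2 = 2.1, ki1 = 3e3),
                            cond, seq(0, 1800, 10), noise_spec(sigma = 0))
  fit <- fit_uninhibited(tr, cond)
  expect_rel_equal(fit$estimates[c("ki1", "r2")],
                   c(ki1 = 3e3, r2 = 2.1), 1e-5)
  expect_gt(fit$correlation_r, 0.999)
  # a trace stopping before the growth phase leaves r2 poorly determined
  short <- make_kinetic_traces("perox", perox_params(r2 = 2.1, ki1 = 3e3),
                               cond, seq(0, 90, 3),
                               noise_spec("additive", 0.005, seed = 5))
  sfit <- suppressWarnings(fit_uninhibited(short, cond))
  rel_se <- sfit$std_errors[["r2"]] / sfit$estimates[["r2"]]
  expect_true(is.na(rel_se) || rel_se > 10 * fit$std_errors[["r2"]] /
                max(fit$estimates[["r2"]], 1e-12))
})

test_that("inhibited fit recovers oxidizability, efficiency and stoichiometry", {
  cond <- perox_conditions(AH0 = 2.5e-6)
  p <- perox_params(r2 = 2.1, AE = 11, n = 4, ki1 = 3e3)
  tr <- make_kinetic_traces("perox", p, cond, seq(0, 1800, 10),
                            noise_spec(sigma = 0))
  fit <- fit_inhibited(tr, cond, ki1_fixed = 3e3)
  expect_rel_equal(fit$estimates[c("r2", "AE", "n")],
                   c(r2 = 2.1, AE = 11, n = 4), 1e-4)
  expect_true(fit$converged)
})
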