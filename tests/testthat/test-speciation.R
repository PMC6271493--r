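test_that("mole fractions are a normalized distribution for random constants and pH", {
  set.seed(11)
  for (i in 1:1000) {
    k <- eq_constants(pKa1 = runif(1, 2, 8), pKa2 = runif(1, 5, 12),
                      pKh_app = runif(1, 1, 7))
    fr <- mole_fractions(k, pH = runif(1, 0, 14))
    expect_equal(sum(fr), 1, tolerance = 1e-12)
    expect_true(all(fr >= 0))
  }
})

test_that("symmetric constants give equal flavylium, base and chalcone fractions", {
  k <- eq_constants(pKa1 = 4, pKa2 = Inf, pKh_app = 4)
  fr <- mole_fractions(k, pH = 4)
  expect_equal(unname(fr[["AH+"]]), unname(fr[["A"]]))
  expect_equal(unname(fr[["A"]]), unname(fr[["CE"]]))
  expect_equal(unname(fr[["A-"]]), 0)
})

test_that("P1 at pH 7.4 shows a ~3:1 chalcone-to-colored-forms ratio", {
  k <- eq_constants(pKa1 = 4.44, pKa2 = 7.12, pKh_app = 3.45)
  fr <- mole_fractions(k, 7.4)
  ratio <- fr[["CE"]] / (fr[["A"]] + fr[["A-"]])
  # direct arithmetic, independent of the implementation
  expected <- 10^(7.4 - 3.45) / (10^(7.4 - 4.44) * (1 + 10^(7.4 - 7.12)))
  expect_equal(ratio, expected, tolerance = 1e-12)
  expect_equal(round(ratio), 3)
})

test_that("mole_fractions rejects invalid inputs", {
  k <- eq_constants(pKa1 = 4.44, pKh_app = 3.45)
  expect_error(mole_fractions(k, -1), "pH")
  expect_error(mole_fractions(k, 15), "pH")
  expect_error(mole_fractions(list(), 7), "eq_constants")
  expect_error(eq_constants(pKa1 = Inf, pKh_app = 3), "finite")
  # a stated Ki inconsistent with the pK values (> 5%) is rejected
  expect_error(eq_constants(pKa1 = 4.44, pKh_app = 3.45, Ki = 12),
               "inconsistent")
  expect_silent(eq_constants(pKa1 = 4.44, pKh_app = 3.45, Ki = 9.8))
})

test_that("chalcone/base ratio follows 10^(pKa1 - pKh') and is reciprocal", {
  expect_equal(round(chalcone_base_ratio(4.44, 3.45)), 10)
  expect_equal(chalcone_base_ratio(4.44, 3.45), 10^0.99, tolerance = 1e-14)
  expect_equal(chalcone_base_ratio(5, 5), 1)
  expect_equal(chalcone_base_ratio(5, 3), 100)
  set.seed(21)
  for (i in 1:25) {
    a <- runif(1, 1, 8); b <- runif(1, 1, 8)
    expect_equal(chalcone_base_ratio(a, b) * chalcone_base_ratio(b, a), 1,
                 tolerance = 1e-12)
  }
})

test_that("titration curve has the Henderson-Hasselbalch midpoint and bounds", {
  expect_equal(titration_curve(7.12, 6.3, 0.3, 7.12), 0.3 * (1 + 6.3) / 2)
  # rA = 1 degenerates to a flat line
  expect_equal(titration_curve(7.12, 1, 0.3, seq(0, 14, 0.5)),
               rep(0.3, 29))
  # bounded between the two pure-species absorbances
  A <- titration_curve(7.12, 6.3, 0.3, seq(0, 14, 0.1))
  expect_true(all(A >= 0.3 - 1e-12 & A <= 6.3 * 0.3 + 1e-12))
  # closed form evaluated by hand at pH 6 and 8
  A6 <- 0.3 * (1 + 6.3 * 10^(6 - 7.12)) / (1 + 10^(6 - 7.12))
  A8 <- 0.3 * (1 + 6.3 * 10^(8 - 7.12)) / (1 + 10^(8 - 7.12))
  expect_equal(titration_curve(7.12, 6.3, 0.3, c(6, 8)), c(A6, A8),
               tolerance = 1e-14)
  expect_error(titration_curve(7, 2, 0.3, numeric(0)), "non-empty")
})

test_that("pKa2 fit recovers noiseless parameters and flags flat series", {
  d <- make_titration(7.12, 6.3, 0.3, seq(6, 8, 0.2), noise_spec(sigma = 0))
  fit <- fit_pka2(d)
  expect_true(fit$converged)
  expect_rel_equal(fit$estimates[c("pKa2", "rA", "A_neutral")],
                   c(pKa2 = 7.12, rA = 6.3, A_neutral = 0.3), 1e-6)
  # rA = 1 leaves pKa2 undetermined: flagged, not silently returned
  flat <- make_titration(7.12, 1, 0.3, seq(6, 8, 0.2),
                         noise_spec("additive", 5e-4, seed = 2))
  expect_warning(ffit <- fit_pka2(flat), "not identifiable")
  expect_false(ffit$identifiable)
})

test_that("first-order decay matches its closed form and half-lives", {
  expect_equal(first_order_decay(0.8, 0.1, 1e-3, 0), 0.8)
  # half-life of color loss at kh_obs = 120e-5 1/s is ~10 min
  t_half <- half_life(120e-5)
  expect_equal(t_half, 577.6, tolerance = 1e-4)
  expect_equal(round(t_half / 60), 10)
  # numerical-root oracle for kh_obs = 88e-5 1/s
  root <- uniroot(function(t) first_order_decay(1, 0, 88e-5, t) - 0.5,
                  c(1, 1e5), tol = 1e-10)$root
  expect_equal(half_life(88e-5), root, tolerance = 1e-8)
  expect_equal(half_life(88e-5), 787.7, tolerance = 1e-4)
  expect_error(first_order_decay(1, 0, 1e-3, -1), "t must")
})

test_that("first-order fit recovers parameters, including the shared two-wavelength mode", {
  tt <- seq(0, 7000, 30)
  p1 <- list(A0 = c(`530` = 0.5), A_inf = c(`530` = 0.02), kh_obs = 88e-5)
  tr <- make_kinetic_traces("first_order", p1, list(), tt, noise_spec(sigma = 0))
  fit <- fit_first_order(tr)
  expect_rel_equal(fit$estimates[c("A0", "A_inf", "kh_obs")],
                   c(A0 = 0.5, A_inf = 0.02, kh_obs = 88e-5), 1e-8)
  # decay at 470 nm and rise at 375 nm share one rate constant
  p2 <- list(A0 = c(`470` = 0.75, `375` = 0.15),
             A_inf = c(`470` = 0.05, `375` = 1.2), kh_obs = 140e-5)
  tr2 <- make_kinetic_traces("first_order", p2, list(), seq(0, 3000, 15),
                             noise_spec(sigma = 0))
  fit2 <- fit_first_order(tr2)
  expect_rel_equal(fit2$estimates[["kh_obs"]], 140e-5, 1e-8)
  expect_rel_equal(fit2$estimates[["A_inf_375"]], 1.2, 1e-7)
})
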