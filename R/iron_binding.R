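#' Parameters of the two-step Fe(III) binding model
#'
#' Irreversible 1:1 binding of Fe(III) to the pooled colored pigment forms
#' (second-order rate constant `kb`), followed by first-order rearrangement
#' of the kinetic complex FeL1 into the thermodynamic complex FeL2 (rate
#' constant `kr`). Molar absorption coefficients are supplied per
#' observation wavelength as named vectors (names are wavelengths in nm).
#'
#' @param kb second-order binding rate constant (M^-1 s^-1, > 0).
#' @param kr first-order rearrangement rate constant (s^-1, >= 0).
#' @param eps_L,eps_1,eps_2 named numeric vectors of molar absorption
#'   coefficients (M^-1 cm^-1, >= 0) of the free pigment, complex 1 and
#'   complex 2, sharing the same wavelength names.
#' @return list of class `"two_step_params"`.
#' @export
two_step_params <- function(kb, kr, eps_L, eps_1, eps_2) {
  if (!is.finite(kb) || kb <= 0) stop("kb must be > 0")
  if (!is.finite(kr) || kr < 0) stop("kr must be >= 0")
  wl <- names(eps_L)
  if (is.null(wl) || !identical(wl, names(eps_1)) || !identical(wl, names(eps_2)))
    stop("eps_L, eps_1, eps_2 must share identical wavelength names")
  if (any(c(eps_L, eps_1, eps_2) < 0)) stop("molar absorptions must be >= 0")
  structure(list(kb = kb, kr = kr, eps_L = eps_L,
                 eps_1 = eps_1, eps_2 = eps_2, wavelengths = wl),
            class = "two_step_params")
}

#' Parameters of the Fe(II) autoxidation/binding model
#'
#' Fe(II) undergoes apparent first-order autoxidation to Fe(III)
#' (`kautox`), which binds the pigment with second-order rate constant
#' `kb`; in parallel the free pigment is lost to the chalcone by water
#' addition (`kh_obs`, may be 0 when chalcone formation is negligible).
#'
#' @param kautox apparent first-order autoxidation rate constant (s^-1).
#' @param kb Fe(III)-pigment binding rate constant (M^-1 s^-1).
#' @param kh_obs apparent water-addition rate constant on the free pigment
#'   (s^-1; 0 turns hydration off).
#' @param eps_L,eps_ML,eps_CE named numeric vectors (wavelength names) of
#'   molar absorption coefficients of free pigment, Fe(III) complex and
#'   (E)-chalcone (M^-1 cm^-1).
#' @return list of class `"autox_params"`.
#' @export
autox_params <- function(kautox, kb, kh_obs = 0, eps_L, eps_ML,
                         eps_CE = NULL) {
  if (any(!is.finite(c(kautox, kb, kh_obs))) ||
      any(c(kautox, kb, kh_obs) < 0))
    stop("rate constants must be finite and >= 0")
  wl <- names(eps_L)
  if (is.null(wl) || !identical(wl, names(eps_ML)))
    stop("eps_L and eps_ML must share identical wavelength names")
  if (is.null(eps_CE)) eps_CE <- stats::setNames(rep(0, length(wl)), wl)
  if (!identical(wl, names(eps_CE)))
    stop("eps_CE must share the wavelength names of eps_L")
  if (any(c(eps_L, eps_ML, eps_CE) < 0)) stop("molar absorptions must be >= 0")
  structure(list(kautox = kautox, kb = kb, kh_obs = kh_obs,
                 eps_L = eps_L, eps_ML = eps_ML, eps_CE = eps_CE,
                 wavelengths = wl),
            class = "autox_params")
}

#' Parameters of the 1:1 reversible binding isotherm
#'
#' @param Kb equilibrium binding constant (M^-1, > 0).
#' @param delta_eps difference of molar absorption coefficients, complex
#'   minus free ligand, at the observation wavelength (M^-1 cm^-1).
#' @return list of class `"isotherm_params"`.
#' @export
isotherm_params <- function(Kb, delta_eps) {
  if (!is.finite(Kb) || Kb <= 0) stop("Kb must be > 0")
  if (!is.finite(delta_eps)) stop("delta_eps must be finite")
  structure(list(Kb = Kb, delta_eps = delta_eps), class = "isotherm_params")
}

ode_solve <- function(y0, times, rhs, parms, rtol = 1e-10, atol = 1e-16) {
  out <- deSolve::lsoda(y = y0, times = times, func = rhs, parms = parms,
                        rtol = rtol, atol = atol)
  if (attr(out, "istate")[1L] < 0)
    stop("ODE integration failed (lsoda istate = ",
         attr(out, "istate")[1L], ")")
  as.data.frame(out)
}

traces_from_states <- function(times, conc, eps_list, path = 1) {
  # conc: named list of concentration vectors; eps_list: named list of
  # per-wavelength eps vectors aligned with conc names
  wl <- names(eps_list[[1]])
  A <- sapply(wl, function(w) {
    Reduce(`+`, Map(function(sp, eps) eps[[w]] * sp, conc, eps_list)) * path
  })
  A <- matrix(A, nrow = length(times),
              dimnames = list(NULL, paste0("A_", wl)))
  cbind(data.frame(time_s = times), as.data.frame(A))
}

#' Simulate the two-step Fe(III) binding kinetics
#'
#' Integrates `d[L]/dt = -kb [Fe][L]`, `d[FeL1]/dt = kb [Fe][L] - kr [FeL1]`,
#' `d[FeL2]/dt = kr [FeL1]` with `[Fe] = M0 - [FeL1] - [FeL2]`, and maps
#' concentrations to absorbance `A(lambda, t) = (eps_L [L] + eps_1 [FeL1] +
#' eps_2 [FeL2]) * path`. Total pigment and total iron are conserved by
#' construction.
#'
#' @param params a [two_step_params()] object.
#' @param L0 total pigment concentration (M, > 0).
#' @param M0 total iron(III) concentration (M, > 0).
#' @param times sorted time grid in seconds starting at 0.
#' @param path optical path length (cm, default 1).
#' @param rtol,atol relative/absolute integrator tolerances.
#' @return list with `traces` (data frame `time_s`, `A_<nm>` ...) and
#'   `states` (concentration trajectories in M).
#' @export
simulate_two_step <- function(params, L0, M0, times, path = 1,
                              rtol = 1e-10, atol = 1e-16) {
  stopifnot(inherits(params, "two_step_params"))
  check_sim_inputs(L0, M0, times)
  rhs <- function(t, y, p) {
    Fe <- p$M0 - y[2L] - y[3L]
    v_bind <- p$kb * Fe * y[1L]
    v_rear <- p$kr * y[2L]
    list(c(-v_bind, v_bind - v_rear, v_rear))
  }
  sol <- ode_solve(c(L = L0, FeL1 = 0, FeL2 = 0), times, rhs,
                   list(kb = params$kb, kr = params$kr, M0 = M0),
                   rtol = rtol, atol = atol)
  sol$Fe <- M0 - sol$FeL1 - sol$FeL2
  traces <- traces_from_states(
    sol$time, list(L = sol$L, FeL1 = sol$FeL1, FeL2 = sol$FeL2),
    list(L = params$eps_L, FeL1 = params$eps_1, FeL2 = params$eps_2), path)
  list(traces = traces, states = sol)
}

check_sim_inputs <- function(L0, M0, times) {
  if (!is.finite(L0) || L0 <= 0 || !is.finite(M0) || M0 <= 0)
    stop("initial concentrations must be > 0")
  if (length(times) < 2L || is.unsorted(times, strictly = TRUE) ||
      times[1L] != 0)
    stop("times must be strictly increasing and start at 0")
  invisible(TRUE)
}

#' Fit the two-step binding model to a pair of kinetic traces
#'
#' Simultaneous weighted least-squares fit of the absorbance-vs-time curves
#' at two (or more) wavelengths to the two-step Fe(III) binding model,
#' estimating `kb`, `kr`, and the complex molar absorptions `eps1_<nm>`,
#' `eps2_<nm>` per wavelength. The free-pigment absorption at each
#' wavelength is fixed from the t = 0 absorbance (`A0 / L0`) rather than
#' fitted.
#'
#' @param traces data frame with `time_s` and two or more `A_<nm>` columns
#'   (>= 20 time points), synchronized.
#' @param L0,M0 total pigment / iron concentrations (M).
#' @param path optical path length (cm).
#' @param init optional named starting values.
#' @return a `"flavokin_fit"` object. `kr` estimates with large standard
#'   errors (short traces, `kr * t_max << 1`) are reported as such, not
#'   clipped.
#' @export
fit_two_step <- function(traces, L0, M0, path = 1, init = NULL) {
  stopifnot(is.data.frame(traces), "time_s" %in% names(traces))
  acols <- grep("^A_", names(traces), value = TRUE)
  if (length(acols) < 2L) stop("need traces at two or more wavelengths")
  if (nrow(traces) < 20L) stop("need at least 20 time points")
  t <- traces$time_s
  wl <- sub("^A_", "", acols)
  obs <- lapply(acols, function(cn) traces[[cn]])
  eps_L <- stats::setNames(
    vapply(obs, `[`, numeric(1), 1L) / (L0 * path), wl)

  cplx_end <- min(L0, M0)
  if (is.null(init)) {
    eps_end <- pmax(vapply(obs, function(y) y[length(y)], numeric(1)) /
                      (cplx_end * path), 1)
    # order-of-magnitude kb from the half-rise time of the fast binding
    # phase on the most responsive wavelength
    spans <- vapply(obs, function(y) abs(y[length(y)] - y[1L]), numeric(1))
    y <- obs[[which.max(spans)]]
    t_half <- t[which(abs(y - y[1L]) >= 0.5 * abs(y[length(y)] - y[1L]))[1L]]
    if (!is.finite(t_half) || t_half <= 0) t_half <- max(t) / 10
    # complex 1 dominates just after the fast phase; complex 2 at the end.
    # distinct eps1/eps2 starts keep the kr direction non-degenerate
    i1 <- which(t >= min(5 * t_half, max(t) / 4))[1L]
    eps_mid <- pmax(vapply(obs, `[`, numeric(1), i1) / (cplx_end * path), 1)
    init <- stats::setNames(
      c(1 / (t_half * min(L0, M0)), 2 / max(t), eps_mid, eps_end),
      c("kb", "kr", paste0("eps1_", wl), paste0("eps2_", wl)))
  }
  model <- function(p) {
    pars <- two_step_params(
      kb = p$kb, kr = p$kr, eps_L = eps_L,
      eps_1 = stats::setNames(unlist(p[paste0("eps1_", wl)]), wl),
      eps_2 = stats::setNames(unlist(p[paste0("eps2_", wl)]), wl))
    sim <- simulate_two_step(pars, L0, M0, t, path,
                             rtol = 1e-8, atol = 1e-13)
    lapply(paste0("A_", wl), function(cn) sim$traces[[cn]])
  }
  least_squares_fit(model, obs, init,
                    transform = stats::setNames(rep("log", length(init)),
                                                names(init)))
}

#' Equilibrium binding isotherm: absorbance change vs total metal
#'
#' For reversible 1:1 metal-ligand binding, the free metal concentration at
#' total metal `Mt` and total ligand `Lt` solves
#' `Mt = [Fe] (1 + Kb Lt / (1 + Kb [Fe]))`, a quadratic in `[Fe]`. The
#' numerically stable (Citardauq) root is used, and the absorbance change
#' is `deltaA = delta_eps * (Mt - [Fe]) * path` (bound metal equals bound
#' ligand for 1:1 stoichiometry).
#'
#' @param params an [isotherm_params()] object.
#' @param Lt total ligand concentration (M, >= 0).
#' @param Mt total metal concentration(s) (M, >= 0); vectorised.
#' @param path optical path length (cm).
#' @return absorbance change(s) (AU).
#' @export
isotherm_deltaA <- function(params, Lt, Mt, path = 1) {
  stopifnot(inherits(params, "isotherm_params"))
  if (Lt < 0 || any(Mt < 0)) stop("concentrations must be >= 0")
  params$delta_eps * bound_metal(params$Kb, Lt, Mt) * path
}

# bound-complex concentration from the smaller root of
# Kb*B^2 - (1 + Kb*(Lt + Mt))*B + Kb*Lt*Mt = 0, written without
# cancellation: the discriminant is 1 + 2Kb(Lt+Mt) + (Kb(Lt-Mt))^2, a sum
# of positive terms, and the root formula keeps every term positive
bound_metal <- function(Kb, Lt, Mt) {
  s <- sqrt(1 + 2 * Kb * (Lt + Mt) + (Kb * (Lt - Mt))^2)
  2 * Kb * Lt * Mt / (1 + Kb * (Lt + Mt) + s)
}

# free metal left over at equilibrium
free_metal <- function(Kb, Lt, Mt) {
  s <- sqrt(1 + 2 * Kb * (Lt + Mt) + (Kb * (Lt - Mt))^2)
  b <- 1 + Kb * (Lt - Mt)
  ifelse(b >= 0, 2 * Mt / (b + s), (s - b) / (2 * Kb))
}

#' Fit the 1:1 reversible binding isotherm
#'
#' Least-squares fit of [isotherm_deltaA()] to a titration series of
#' absorbance change vs total metal, estimating `Kb` and `delta_eps`.
#' Series far from saturation carry information only on the product
#' `Kb * delta_eps`; a parameter correlation beyond |rho| = 0.999 (or a
#' singular covariance) clears the `identifiable` flag with a warning.
#'
#' @param series data frame with columns `Mt` (M) and `deltaA` (AU),
#'   >= 4 points.
#' @param Lt total ligand concentration (M).
#' @param path optical path length (cm).
#' @param init optional named starting values for `Kb`, `delta_eps`.
#' @return a `"flavokin_fit"` object.
#' @export
fit_isotherm <- function(series, Lt, path = 1, init = NULL) {
  stopifnot(is.data.frame(series), all(c("Mt", "deltaA") %in% names(series)))
  if (nrow(series) < 4L) stop("need at least 4 titration points")
  Mt <- series$Mt
  dA <- series$deltaA
  if (is.null(init)) {
    init <- c(Kb = 2 / stats::median(Mt),
              delta_eps = max(dA) / (min(max(Mt), Lt) * path))
  }
  fit <- least_squares_fit(
    model = function(p)
      list(isotherm_deltaA(isotherm_params(p$Kb, p$delta_eps), Lt, Mt, path)),
    observed = list(dA),
    init = init,
    transform = c(Kb = "log", delta_eps = "log"))
  rho <- fit$param_correlation["Kb", "delta_eps"]
  if (!fit$identifiable || (is.finite(rho) && abs(rho) > 0.999)) {
    fit$identifiable <- FALSE
    warning("Kb and delta_eps are anticorrelated (|rho| > 0.999): ",
            "titration too far from saturation to separate them")
  }
  fit
}

#' Simulate Fe(II) autoxidation, Fe(III) binding and pigment hydration
#'
#' Integrates the five-species system: Fe(II) autoxidises to Fe(III)
#' (first-order `kautox`); Fe(III) binds the free pigment L (second-order
#' `kb`); L is also lost to the (E)-chalcone CE by water addition
#' (`kh_obs`). Absorbance is
#' `A(lambda, t) = (eps_L [L] + eps_ML [LFe] + eps_CE [CE]) * path`.
#' Total iron and total pigment are conserved.
#'
#' @param params an [autox_params()] object.
#' @param L0 total pigment concentration (M).
#' @param M0_FeII initial Fe(II) concentration (M).
#' @param times sorted time grid (s) starting at 0.
#' @param path optical path length (cm).
#' @param rtol,atol relative/absolute integrator tolerances.
#' @return list with `traces` and `states` as in [simulate_two_step()].
#' @export
simulate_autox <- function(params, L0, M0_FeII, times, path = 1,
                           rtol = 1e-10, atol = 1e-16) {
  stopifnot(inherits(params, "autox_params"))
  check_sim_inputs(L0, M0_FeII, times)
  rhs <- function(t, y, p) {
    # y = FeII, FeIII, L, LFe, CE
    v_aut <- p$kautox * y[1L]
    v_bind <- p$kb * y[2L] * y[3L]
    v_hyd <- p$kh_obs * y[3L]
    list(c(-v_aut, v_aut - v_bind, -v_bind - v_hyd, v_bind, v_hyd))
  }
  sol <- ode_solve(c(FeII = M0_FeII, FeIII = 0, L = L0, LFe = 0, CE = 0),
                   times, rhs,
                   list(kautox = params$kautox, kb = params$kb,
                        kh_obs = params$kh_obs),
                   rtol = rtol, atol = atol)
  traces <- traces_from_states(
    sol$time, list(L = sol$L, LFe = sol$LFe, CE = sol$CE),
    list(L = params$eps_L, LFe = params$eps_ML, CE = params$eps_CE), path)
  list(traces = traces, states = sol)
}

# steady-state-Fe(III) variant: every Fe(III) formed binds instantly while
# free pigment remains; used at iron/pigment ratios <= 1
simulate_autox_ss <- function(kautox, kh_obs, eps_L, eps_ML, eps_CE,
                              L0, M0_FeII, times, path = 1,
                              rtol = 1e-10, atol = 1e-16) {
  rhs <- function(t, y, p) {
    # y = FeII, L, LFe, CE
    gate <- y[2L] / (y[2L] + 1e-9)
    v_aut <- p$kautox * y[1L] * gate
    v_hyd <- p$kh_obs * y[2L]
    list(c(-v_aut, -v_aut - v_hyd, v_aut, v_hyd))
  }
  sol <- ode_solve(c(FeII = M0_FeII, L = L0, LFe = 0, CE = 0), times, rhs,
                   list(kautox = kautox, kh_obs = kh_obs),
                   rtol = rtol, atol = atol)
  traces <- traces_from_states(
    sol$time, list(L = sol$L, LFe = sol$LFe, CE = sol$CE),
    list(L = eps_L, LFe = eps_ML, CE = eps_CE), path)
  list(traces = traces, states = sol)
}

#' Fit the Fe(II) autoxidation/binding model to kinetic traces
#'
#' In mode `"full"`, fits `(kautox, kb)` plus the complex absorption
#' `epsML_<nm>` at each wavelength (and `kh_obs` when `fit_kh = TRUE`, as
#' needed for pigments whose chalcone accumulates). In mode
#' `"steady_state_FeIII"` (appropriate for iron/pigment ratios <= 1) the
#' Fe(III) intermediate is assumed not to accumulate, `kb` drops out, and
#' `(kautox, kh_obs)` are fitted with the complex absorptions held
#' constant. The free-pigment absorption is fixed from the t = 0
#' absorbance in both modes.
#'
#' @param traces data frame with `time_s` and `A_<nm>` columns.
#' @param L0,M0 total pigment / initial Fe(II) concentrations (M).
#' @param mode `"full"` or `"steady_state_FeIII"`.
#' @param eps_ML named complex absorptions (required and held fixed in
#'   steady-state mode; used as starting values in full mode if supplied).
#' @param eps_CE named chalcone absorptions (fixed; default all 0).
#' @param kh_obs hydration rate constant: fixed value in full mode when
#'   `fit_kh = FALSE` (default 0).
#' @param fit_kh logical; fit `kh_obs` in full mode.
#' @param path optical path length (cm).
#' @return a `"flavokin_fit"` object. Full-mode fits at iron/pigment
#'   ratios <= 1 are allowed but flagged (`notes` field), since `kb` is
#'   then poorly determined.
#' @export
fit_autox <- function(traces, L0, M0,
                      mode = c("full", "steady_state_FeIII"),
                      eps_ML = NULL, eps_CE = NULL, kh_obs = 0,
                      fit_kh = FALSE, path = 1) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(traces), "time_s" %in% names(traces))
  acols <- grep("^A_", names(traces), value = TRUE)
  if (length(acols) < 2L) stop("need traces at two or more wavelengths")
  t <- traces$time_s
  wl <- sub("^A_", "", acols)
  obs <- lapply(acols, function(cn) traces[[cn]])
  eps_L <- stats::setNames(vapply(obs, `[`, numeric(1), 1L) / (L0 * path), wl)
  if (is.null(eps_CE)) eps_CE <- stats::setNames(rep(0, length(wl)), wl)

  if (mode == "steady_state_FeIII") {
    if (is.null(eps_ML))
      stop("steady-state mode requires fixed eps_ML values")
    init <- c(kautox = 1 / max(t), kh_obs = 0.3 / max(t))
    model <- function(p) {
      sim <- simulate_autox_ss(p$kautox, p$kh_obs, eps_L, eps_ML, eps_CE,
                               L0, M0, t, path, rtol = 1e-8, atol = 1e-13)
      lapply(paste0("A_", wl), function(cn) sim$traces[[cn]])
    }
    return(least_squares_fit(model, obs, init,
                             transform = c(kautox = "log", kh_obs = "log")))
  }

  eps0 <- if (!is.null(eps_ML)) eps_ML else
    stats::setNames(pmax(vapply(obs, function(y) y[length(y)], numeric(1)) /
                           (min(L0, M0) * path), 1), wl)
  init <- stats::setNames(c(1 / max(t), 2 / (L0 * max(t)), eps0),
                          c("kautox", "kb", paste0("epsML_", wl)))
  if (fit_kh) init <- c(init, kh_obs = 0.3 / max(t))
  model <- function(p) {
    pars <- autox_params(
      kautox = p$kautox, kb = p$kb,
      kh_obs = if (fit_kh) p$kh_obs else kh_obs,
      eps_L = eps_L,
      eps_ML = stats::setNames(unlist(p[paste0("epsML_", wl)]), wl),
      eps_CE = eps_CE)
    sim <- simulate_autox(pars, L0, M0, t, path, rtol = 1e-8, atol = 1e-13)
    lapply(paste0("A_", wl), function(cn) sim$traces[[cn]])
  }
  fit <- least_squares_fit(model, obs, init,
                           transform = stats::setNames(
                             rep("log", length(init)), names(init)))
  if (M0 / L0 <= 1) {
    fit$notes <- paste("iron/pigment ratio <= 1: kb is weakly identified;",
                       "consider mode = 'steady_state_FeIII'")
    warning(fit$notes)
  }
  fit
}
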