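#' Noise specification for synthetic datasets
#'
#' @param kind `"additive"` (Gaussian, sigma in AU) or `"multiplicative"`
#'   (Gaussian relative, sigma as a fraction; shot-noise-like, the default
#'   model for fluorescence).
#' @param sigma noise level (>= 0).
#' @param seed integer RNG seed; identical seeds give identical datasets.
#' @return list of class `"noise_spec"`.
#' @export
noise_spec <- function(kind = c("additive", "multiplicative"),
                       sigma = 0, seed = 1L) {
  kind <- match.arg(kind)
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0")
  structure(list(kind = kind, sigma = sigma, seed = as.integer(seed)),
            class = "noise_spec")
}

apply_noise <- function(x, noise) {
  if (noise$sigma == 0) return(x)
  set.seed(noise$seed)
  eps <- stats::rnorm(length(x), 0, noise$sigma)
  if (noise$kind == "additive") x + eps else x * (1 + eps)
}

reseed <- function(noise, offset) {
  noise$seed <- (noise$seed + as.integer(offset)) %% .Machine$integer.max
  noise
}

#' Generate synthetic kinetic traces with known ground truth
#'
#' Forward-simulates one of the kinetic model families and adds instrument
#' noise. The generating parameters are attached as the `"ground_truth"`
#' attribute.
#'
#' @param family `"two_step"`, `"autox"`, `"perox"` or `"first_order"`.
#' @param params the matching params object ([two_step_params()],
#'   [autox_params()], [perox_params()]); for `"first_order"`, a list with
#'   named-by-wavelength vectors `A0`, `A_inf` and scalar `kh_obs`.
#' @param conditions family-specific list: `L0`/`M0` for `two_step` and
#'   `autox`; a [perox_conditions()] object for `perox`; ignored for
#'   `first_order`.
#' @param time_grid sampling times (s), starting at 0.
#' @param noise a [noise_spec()].
#' @return data frame of noisy traces (`time_s`, `A_<nm>` ...), with
#'   attribute `ground_truth`.
#' @export
make_kinetic_traces <- function(family, params, conditions = list(),
                                time_grid, noise = noise_spec()) {
  clean <- switch(family,
    two_step = simulate_two_step(params, conditions$L0, conditions$M0,
                                 time_grid)$traces,
    autox = simulate_autox(params, conditions$L0, conditions$M0,
                           time_grid)$traces,
    perox = {
      tr <- simulate_cd(params, conditions, time_grid)$trace
      names(tr)[2L] <- "A_234"
      tr
    },
    first_order = {
      wl <- names(params$A0)
      A <- sapply(wl, function(w)
        first_order_decay(params$A0[[w]], params$A_inf[[w]],
                          params$kh_obs, time_grid))
      A <- matrix(A, nrow = length(time_grid),
                  dimnames = list(NULL, paste0("A_", wl)))
      cbind(data.frame(time_s = time_grid), as.data.frame(A))
    },
    stop("unknown model family: ", family))
  acols <- setdiff(names(clean), "time_s")
  noisy <- as.matrix(clean[acols])
  noisy[] <- apply_noise(as.numeric(noisy), noise)
  clean[acols] <- noisy
  attr(clean, "ground_truth") <- list(family = family, params = params,
                                      conditions = conditions)
  clean
}

#' Generate a synthetic equilibrium binding isotherm
#'
#' @param params an [isotherm_params()] object.
#' @param Lt total ligand concentration (M).
#' @param Mt vector of total metal concentrations (M).
#' @param noise a [noise_spec()].
#' @return data frame `Mt`, `deltaA` with attribute `ground_truth`.
#' @export
make_isotherm <- function(params, Lt, Mt, noise = noise_spec()) {
  dA <- apply_noise(isotherm_deltaA(params, Lt, Mt), noise)
  structure(data.frame(Mt = Mt, deltaA = dA),
            ground_truth = list(params = params, Lt = Lt))
}

#' Generate a synthetic pH titration series
#'
#' @param pKa2,rA,A_neutral generating values of [titration_curve()].
#' @param pH_grid vector of pH values.
#' @param noise a [noise_spec()].
#' @return data frame `pH`, `absorbance` with attribute `ground_truth`.
#' @export
make_titration <- function(pKa2, rA, A_neutral, pH_grid,
                           noise = noise_spec()) {
  A <- apply_noise(titration_curve(pKa2, rA, A_neutral, pH_grid), noise)
  structure(data.frame(pH = pH_grid, absorbance = A),
            ground_truth = list(pKa2 = pKa2, rA = rA,
                                A_neutral = A_neutral))
}

#' Generate a synthetic fluorescence quenching titration
#'
#' @param params a [quench_params()] object.
#' @param Lt vector of total ligand concentrations (M).
#' @param Pt total protein concentration (M).
#' @param noise a [noise_spec()]; the conventional fluorescence noise
#'   model is 1\% multiplicative.
#' @return data frame `ligand_total_M`, `fluorescence` with attribute
#'   `ground_truth`.
#' @export
make_quench_series <- function(params, Lt, Pt,
                               noise = noise_spec("multiplicative", 0.01)) {
  IF <- apply_noise(predicted_fluorescence(params, Lt, Pt), noise)
  structure(data.frame(ligand_total_M = Lt, fluorescence = IF),
            ground_truth = list(params = params, Pt = Pt))
}

#' Parameter-recovery study over noisy synthetic replicates
#'
#' Generates `n_replicates` noisy datasets from a known ground truth
#' (replicate i uses seed `noise$seed + i - 1`), fits each with the
#' family's fitter, and summarises the recovered parameters. Replicates
#' whose fit does not converge are counted in `n_failed` and excluded
#' from the summary, never silently dropped.
#'
#' @param scenario a scenario list as returned by [flavokin_scenarios()]
#'   (fields `family`, `params`/`truth`, and the design fields the family
#'   needs).
#' @param n_replicates number of replicates (>= 2).
#' @param noise optional [noise_spec()] overriding the scenario default.
#' @return data frame with columns `parameter`, `truth`, `mean`, `sd`,
#'   `bias`, `rmse`, `n_converged`, `n_failed`; the matrix of per-replicate
#'   estimates is attached as attribute `"estimates"`.
#' @export
recovery_study <- function(scenario, n_replicates, noise = NULL) {
  if (n_replicates < 2L) stop("need at least 2 replicates")
  if (is.null(noise)) noise <- scenario$noise
  family <- scenario$family

  runner <- switch(family,
    two_step = function(ns) {
      tr <- make_kinetic_traces("two_step", scenario$params,
                                list(L0 = scenario$L0, M0 = scenario$M0),
                                scenario$times, ns)
      fit_two_step(tr, scenario$L0, scenario$M0)
    },
    autox = function(ns) {
      tr <- make_kinetic_traces("autox", scenario$params,
                                list(L0 = scenario$L0, M0 = scenario$M0),
                                scenario$times, ns)
      fit_autox(tr, scenario$L0, scenario$M0, mode = "full",
                eps_CE = scenario$params$eps_CE,
                fit_kh = scenario$params$kh_obs > 0)
    },
    perox = function(ns) {
      tr <- make_kinetic_traces("perox", scenario$params, scenario$cond,
                                scenario$times, ns)
      if (scenario$cond$AH0 > 0)
        fit_inhibited(tr, scenario$cond, ki1_fixed = scenario$params$ki1)
      else
        fit_uninhibited(tr, scenario$cond)
    },
    first_order = function(ns) {
      tr <- make_kinetic_traces("first_order", scenario$params, list(),
                                scenario$times, ns)
      fit_first_order(tr)
    },
    isotherm = function(ns) {
      d <- make_isotherm(scenario$params, scenario$Lt, scenario$Mt, ns)
      fit_isotherm(d, scenario$Lt)
    },
    pka2 = function(ns) {
      tt <- scenario$truth
      d <- make_titration(tt[["pKa2"]], tt[["rA"]], tt[["A_neutral"]],
                          scenario$pH_grid, ns)
      fit_pka2(d)
    },
    quench = function(ns) {
      d <- make_quench_series(scenario$params, scenario$Lt, scenario$Pt, ns)
      fit_quench(d, scenario$Pt, epsL_ex = scenario$params$epsL_ex,
                 epsL_em = scenario$params$epsL_em,
                 path_l = scenario$params$path_l)
    },
    stop("unknown model family: ", family))

  truth_all <- scenario_truth(scenario)
  ests <- list()
  n_failed <- 0L
  for (i in seq_len(n_replicates)) {
    fit <- tryCatch(suppressWarnings(runner(reseed(noise, i - 1L))),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      n_failed <- n_failed + 1L
      next
    }
    ests[[length(ests) + 1L]] <- fit$estimates
  }
  if (!length(ests)) stop("no replicate converged")
  est_mat <- do.call(rbind, ests)
  pars <- intersect(names(truth_all), colnames(est_mat))
  if (!length(pars)) pars <- colnames(est_mat)
  summ <- do.call(rbind, lapply(pars, function(p) {
    v <- est_mat[, p]
    tv <- if (p %in% names(truth_all)) truth_all[[p]] else NA_real_
    data.frame(parameter = p, truth = tv, mean = mean(v), sd = stats::sd(v),
               bias = mean(v) - tv, rmse = sqrt(mean((v - tv)^2)),
               n_converged = nrow(est_mat), n_failed = n_failed)
  }))
  attr(summ, "estimates") <- est_mat
  summ
}

# flatten a scenario's generating values into a named vector matching the
# fitters' parameter names
scenario_truth <- function(scenario) {
  p <- scenario$params
  switch(scenario$family,
    two_step = {
      wl <- p$wavelengths
      stats::setNames(
        c(p$kb, p$kr, p$eps_1, p$eps_2),
        c("kb", "kr", paste0("eps1_", wl), paste0("eps2_", wl)))
    },
    autox = {
      wl <- p$wavelengths
      out <- stats::setNames(c(p$kautox, p$kb, p$eps_ML),
                             c("kautox", "kb", paste0("epsML_", wl)))
      if (p$kh_obs > 0) out <- c(out, kh_obs = p$kh_obs)
      out
    },
    perox = if (scenario$cond$AH0 > 0)
      c(r2 = p$r2, AE = p$AE, n = p$n) else c(ki1 = p$ki1, r2 = p$r2),
    first_order = {
      wl <- names(p$A0)
      if (length(wl) == 1L)
        c(A0 = unname(p$A0), A_inf = unname(p$A_inf), kh_obs = p$kh_obs)
      else
        stats::setNames(c(p$A0, p$A_inf, p$kh_obs),
                        c(paste0("A0_", wl), paste0("A_inf_", wl), "kh_obs"))
    },
    isotherm = c(Kb = p$Kb, delta_eps = p$delta_eps),
    pka2 = scenario$truth,
    quench = c(Kb = p$Kb, fP = p$fP))
}
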