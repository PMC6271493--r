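#' Equilibrium constants of flavylium structural transformations
#'
#' Bundles the constants governing the multistate equilibria of a flavylium
#' pigment: the flavylium cation AH+ loses a proton to the neutral quinonoid
#' base A (pKa1), which loses another to the anionic base A- (pKa2), while
#' water addition converts AH+ through transient intermediates (hemiketal
#' and (Z)-chalcone, which do not accumulate) into the (E)-chalcone CE with
#' apparent constant pK'h. Ki = (CE)/(A) is the equilibrium
#' chalcone-to-quinonoid-base ratio, fixed by Ki = 10^(pKa1 - pK'h); if a Ki
#' value is supplied alongside both pK values it must agree with that
#' identity within 5%. rA is the ratio of the molar absorption coefficients
#' of the anionic to the neutral quinonoid base at the observation
#' wavelength.
#'
#' @param pKa1,pKa2 acid dissociation exponents (dimensionless).
#' @param pKh_app apparent hydration exponent for AH+ = CE + H+.
#' @param Ki optional chalcone/base ratio; checked against
#'   `10^(pKa1 - pKh_app)`.
#' @param rA optional absorption-coefficient ratio (> 0).
#' @return list of class `"eq_constants"`.
#' @export
eq_constants <- function(pKa1, pKa2 = Inf, pKh_app, Ki = NULL, rA = NULL) {
  for (v in c(pKa1, pKh_app)) {
    if (!is.finite(v)) stop("pKa1 and pKh_app must be finite")
  }
  if (!(is.finite(pKa2) || identical(pKa2, Inf)))
    stop("pKa2 must be finite (or Inf for no second deprotonation)")
  if (!is.null(rA) && (!is.finite(rA) || rA <= 0)) stop("rA must be > 0")
  Ki_implied <- chalcone_base_ratio(pKa1, pKh_app)
  if (!is.null(Ki)) {
    if (!is.finite(Ki) || Ki <= 0) stop("Ki must be > 0")
    if (abs(Ki - Ki_implied) / Ki_implied > 0.05)
      stop(sprintf(
        "supplied Ki = %.4g inconsistent with 10^(pKa1 - pKh_app) = %.4g (> 5%%)",
        Ki, Ki_implied))
  }
  structure(list(pKa1 = pKa1, pKa2 = pKa2, pKh_app = pKh_app,
                 Ki = Ki_implied, rA = rA),
            class = "eq_constants")
}

#' Equilibrium mole fractions of the flavylium species
#'
#' Distribution of a flavylium pigment over its four accumulating forms
#' (flavylium cation AH+, neutral quinonoid base A, anionic base A-, and
#' (E)-chalcone CE) at a given pH, from the ratios relative to AH+:
#' \[A\]/\[AH+\] = Ka1/\[H+\], \[A-\]/\[AH+\] = Ka1 Ka2/\[H+\]^2,
#' \[CE\]/\[AH+\] = K'h/\[H+\]. The hemiketal and (Z)-chalcone are treated
#' as non-accumulating intermediates lumped into K'h.
#'
#' @param constants an [eq_constants()] object.
#' @param pH solution pH in \[0, 14\] (buffered, treated as exact).
#' @return named numeric vector of fractions `AH+`, `A`, `A-`, `CE`
#'   summing to 1.
#' @examples
#' k <- eq_constants(pKa1 = 4.44, pKa2 = 7.12, pKh_app = 3.45)
#' mole_fractions(k, pH = 7.4)
#' @export
mole_fractions <- function(constants, pH) {
  if (!inherits(constants, "eq_constants"))
    stop("constants must be an eq_constants object")
  if (!is.finite(pH) || pH < 0 || pH > 14)
    stop("pH must lie in [0, 14]")
  rel <- c(
    `AH+` = 1,
    A     = 10^(pH - constants$pKa1),
    `A-`  = if (is.finite(constants$pKa2))
              10^(2 * pH - constants$pKa1 - constants$pKa2) else 0,
    CE    = 10^(pH - constants$pKh_app)
  )
  rel / sum(rel)
}

#' Chalcone-to-quinonoid-base equilibrium ratio
#'
#' Ki = (CE)/(A) = 10^(pKa1 - pK'h): the ratio of (E)-chalcone to neutral
#' quinonoid base at equilibrium, independent of pH (both species derive
#' from AH+ by loss of one proton).
#'
#' @param pKa1,pKh_app finite pK values.
#' @return Ki (dimensionless).
#' @examples
#' chalcone_base_ratio(4.44, 3.45)  # ~ 10
#' @export
chalcone_base_ratio <- function(pKa1, pKh_app) {
  if (!is.finite(pKa1) || !is.finite(pKh_app))
    stop("pKa1 and pKh_app must be finite")
  10^(pKa1 - pKh_app)
}

#' Two-state spectrophotometric titration curve
#'
#' Absorbance of the quinonoid base pair as a function of pH, assuming the
#' neutral (absorption `A_neutral`) and anionic (absorption
#' `rA * A_neutral`) bases interconvert with a single pKa2:
#' `A(pH) = A_neutral * (1 + rA * 10^(pH - pKa2)) / (1 + 10^(pH - pKa2))`.
#' Monotone in pH whenever `rA != 1`; bounded between `A_neutral` and
#' `rA * A_neutral`.
#'
#' @param pKa2 acid dissociation exponent of the neutral base.
#' @param rA ratio of anionic to neutral molar absorption coefficients at
#'   the observation wavelength.
#' @param A_neutral absorbance of the fully neutral form (AU, > 0).
#' @param pH_grid numeric vector of pH values (non-empty).
#' @return numeric vector of absorbances (AU).
#' @export
titration_curve <- function(pKa2, rA, A_neutral, pH_grid) {
  if (length(pH_grid) == 0L) stop("pH_grid must be non-empty")
  if (!is.finite(A_neutral) || A_neutral <= 0) stop("A_neutral must be > 0")
  x <- 10^(pH_grid - pKa2)
  A_neutral * (1 + rA * x) / (1 + x)
}

#' Fit a pKa2 titration curve
#'
#' Least-squares fit of [titration_curve()] to an equilibrium absorbance vs
#' pH series, estimating `pKa2`, `rA` and `A_neutral`. Flat series
#' (`rA` near 1) leave pKa2 undetermined; this is detected through the
#' covariance (singular, or a pKa2 standard error above half a pH unit)
#' and reported via the `identifiable` flag with a warning rather than
#' returning an arbitrary value silently.
#'
#' @param series data frame with columns `pH` and `absorbance` (>= 4 points
#'   spanning the transition).
#' @param init optional named starting values for `pKa2`, `rA`, `A_neutral`.
#' @return a `"flavokin_fit"` object (see [least_squares_fit()]).
#' @export
fit_pka2 <- function(series, init = NULL) {
  stopifnot(is.data.frame(series), all(c("pH", "absorbance") %in% names(series)))
  if (nrow(series) < 4L) stop("need at least 4 titration points")
  pH <- series$pH
  A <- series$absorbance
  if (is.null(init)) {
    init <- c(pKa2 = stats::median(pH),
              rA = max(A[which.max(pH)] / A[which.min(pH)], 0.01),
              A_neutral = A[which.min(pH)])
  }
  fit <- least_squares_fit(
    model = function(p) list(titration_curve(p$pKa2, p$rA, p$A_neutral, pH)),
    observed = list(A),
    init = init,
    transform = c(rA = "log", A_neutral = "log")
  )
  se_pka2 <- fit$std_errors[["pKa2"]]
  if (!fit$identifiable || is.na(se_pka2) || se_pka2 > 0.5) {
    fit$identifiable <- FALSE
    warning("pKa2 is not identifiable from this series (flat titration, rA ~ 1?)")
  }
  fit
}

#' First-order absorbance decay (color loss)
#'
#' `A(t) = A_inf + (A0 - A_inf) * exp(-kh_obs * t)`: the apparent
#' first-order loss of flavylium color by water addition (chalcone
#' formation), with rate constant `kh_obs` (s^-1).
#'
#' @param A0 absorbance at t = 0 (AU).
#' @param A_inf asymptotic absorbance (AU).
#' @param kh_obs apparent first-order rate constant (s^-1, >= 0).
#' @param t time(s) in seconds, >= 0.
#' @return absorbance(s) (AU).
#' @export
first_order_decay <- function(A0, A_inf, kh_obs, t) {
  if (any(t < 0)) stop("t must be >= 0")
  if (kh_obs < 0) stop("kh_obs must be >= 0")
  A_inf + (A0 - A_inf) * exp(-kh_obs * t)
}

#' Fit first-order color decay, optionally at two wavelengths
#'
#' Fits [first_order_decay()] to one absorbance-vs-time trace, or
#' simultaneously to two synchronized traces (e.g., decay of the colored
#' band and rise of the chalcone band) sharing a single `kh_obs` with
#' per-wavelength amplitudes.
#'
#' @param trace data frame with column `time_s` and one or two `A_<nm>`
#'   absorbance columns.
#' @return a `"flavokin_fit"` object; parameters are `kh_obs` plus
#'   `A0`/`A_inf` (single trace) or `A0_<nm>`/`A_inf_<nm>` per wavelength.
#' @export
fit_first_order <- function(trace) {
  stopifnot(is.data.frame(trace), "time_s" %in% names(trace))
  acols <- grep("^A_", names(trace), value = TRUE)
  if (!length(acols) %in% 1:2)
    stop("trace must carry one or two A_<wavelength> columns")
  t <- trace$time_s
  if (any(t < 0)) stop("time must be >= 0")
  obs <- lapply(acols, function(cn) trace[[cn]])
  span <- diff(range(t))
  k0 <- log(2) / max(span / 3, .Machine$double.eps)

  if (length(acols) == 1L) {
    y <- obs[[1]]
    init <- c(A0 = y[1], A_inf = y[length(y)], kh_obs = k0)
    model <- function(p) list(first_order_decay(p$A0, p$A_inf, p$kh_obs, t))
  } else {
    suf <- sub("^A_", "", acols)
    init <- stats::setNames(
      c(vapply(obs, `[`, numeric(1), 1),
        vapply(obs, function(y) y[length(y)], numeric(1)),
        k0),
      c(paste0("A0_", suf), paste0("A_inf_", suf), "kh_obs"))
    model <- function(p) {
      lapply(suf, function(s)
        first_order_decay(p[[paste0("A0_", s)]],
                          p[[paste0("A_inf_", s)]], p$kh_obs, t))
    }
  }
  least_squares_fit(model, obs, init, transform = c(kh_obs = "log"))
}
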