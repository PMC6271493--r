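#' Nonlinear least-squares engine shared by all model fitters
#'
#' `least_squares_fit()` minimises the unweighted sum of squared residuals
#' pooled across one or more observed curves that share a parameter vector,
#' using the Levenberg--Marquardt algorithm of \pkg{minpack.lm}. Parameters
#' constrained to be positive are fitted on the log scale (declared through
#' `transform`), which enforces positivity without hard bounds. Standard
#' errors are linearised (Gauss--Newton) standard deviations: the residual
#' variance times the diagonal of the inverse approximate Hessian,
#' square-rooted, mapped back to the natural scale by the delta method.
#'
#' If the first attempt fails to converge (or reaches a non-finite
#' objective), up to three deterministically jittered restarts are tried and
#' the lowest-objective fit is kept.
#'
#' @param model function taking a named list of parameter values (free and
#'   fixed combined) and returning a list of predicted numeric vectors, one
#'   per observed curve, in the same order and of the same lengths.
#' @param observed a numeric vector, or a list of numeric vectors, of
#'   observations.
#' @param init named numeric vector of starting values for the free
#'   parameters.
#' @param fixed named list of parameters held constant during the fit.
#' @param transform named character vector mapping parameter names to
#'   `"log"` or `"identity"`; parameters not named default to `"identity"`.
#' @param weights optional list of numeric vectors (same shape as
#'   `observed`) of per-point weights multiplying the residuals; default
#'   equal weights.
#' @param multistart logical; try jittered restarts on failure (default
#'   `TRUE`).
#' @param maxiter maximum Levenberg--Marquardt iterations per start.
#'
#' @return An object of class `"flavokin_fit"`: a list with elements
#'   `estimates`, `std_errors` (both named, natural scale), `correlation_r`
#'   (Pearson correlation of pooled observed vs predicted), `residuals`
#'   (stacked), `residual_norm`, `converged`, `n_obs`, `n_params`,
#'   `covariance_condition` (condition number of the parameter correlation
#'   matrix; large values signal non-identifiability), `param_correlation`
#'   (estimated correlation matrix of the parameters), `identifiable`
#'   (`covariance_condition < 1e8`), `rss_trace` (objective values over
#'   accepted steps), `fixed`, and `message`.
#'
#' @examples
#' x <- seq(0, 10, length.out = 25)
#' obs <- 3.2 * exp(-0.4 * x)
#' fit <- least_squares_fit(
#'   model = function(p) list(p$a * exp(-p$k * x)),
#'   observed = list(obs),
#'   init = c(a = 1, k = 0.1),
#'   transform = c(a = "log", k = "log")
#' )
#' fit$estimates
#' @export
least_squares_fit <- function(model, observed, init, fixed = list(),
                              transform = NULL, weights = NULL,
                              multistart = TRUE, maxiter = 200L) {
  if (is.numeric(observed)) observed <- list(observed)
  stopifnot(is.list(observed), length(observed) >= 1L)
  if (any(!vapply(observed, is.numeric, logical(1))))
    stop("observed curves must be numeric vectors")
  obs_stacked <- unlist(observed, use.names = FALSE)
  n_obs <- length(obs_stacked)
  pnames <- names(init)
  if (is.null(pnames) || any(pnames == ""))
    stop("init must be a fully named numeric vector")
  n_par <- length(init)
  if (n_obs <= n_par)
    stop("need more observations than free parameters")

  tr <- rep("identity", n_par)
  names(tr) <- pnames
  if (!is.null(transform)) {
    bad <- setdiff(names(transform), pnames)
    if (length(bad)) stop("transform names not in init: ",
                          paste(bad, collapse = ", "))
    tr[names(transform)] <- transform
  }
  if (!all(tr %in% c("log", "identity")))
    stop("transform entries must be 'log' or 'identity'")
  if (any(tr == "log" & init <= 0))
    stop("log-transformed parameters need positive starting values")

  w_stacked <- if (is.null(weights)) NULL else unlist(weights, use.names = FALSE)

  to_internal <- function(p) ifelse(tr == "log", log(p), p)
  to_natural  <- function(q) {
    p <- ifelse(tr == "log", exp(q), q)
    names(p) <- pnames
    p
  }

  n_evals <- 0L
  resid_fn <- function(q) {
    p <- as.list(to_natural(q))
    # a trial point where the model cannot be evaluated (e.g. the ODE
    # integrator gives up at extreme rate constants) is penalized so the
    # optimizer backs off instead of aborting
    pred <- tryCatch({
      utils::capture.output(
        out <- suppressWarnings(model(c(p, fixed))), file = nullfile())
      out
    }, error = function(e) NULL)
    pred_stacked <- unlist(pred, use.names = FALSE)
    if (is.null(pred)) return(rep(1e6, n_obs))
    if (n_evals == 0L && length(pred_stacked) != n_obs)
      stop("model returned ", length(pred_stacked),
           " predictions for ", n_obs, " observations")
    n_evals <<- n_evals + 1L
    if (length(pred_stacked) != n_obs) return(rep(1e6, n_obs))
    r <- obs_stacked - pred_stacked
    if (!is.null(w_stacked)) r <- r * w_stacked
    if (any(!is.finite(r))) r[!is.finite(r)] <- 1e6
    r
  }

  run_one <- function(q0) {
    tryCatch(
      minpack.lm::nls.lm(par = q0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ftol = 1e-12,
                           ptol = 1e-12, gtol = 0)),
      error = function(e) NULL)
  }

  q0 <- to_internal(init)
  starts <- list(q0)
  if (multistart) {
    # deterministic jitters in internal coordinates; no RNG involved
    jit <- list(rep(c(0.5, -0.5), length.out = n_par),
                rep(c(-1, 1), length.out = n_par),
                rep(0.25, n_par))
    starts <- c(starts, lapply(jit, function(j) q0 + j))
  }

  best <- NULL
  for (i in seq_along(starts)) {
    res <- run_one(starts[[i]])
    if (is.null(res)) next
    ok <- res$info %in% c(1L, 2L, 3L)
    if (is.null(best) || (res$deviance < best$fit$deviance)) {
      best <- list(fit = res, converged = ok)
    }
    if (i == 1L && ok) break  # first start converged: accept it
  }
  if (is.null(best))
    stop("least_squares_fit: all optimizer starts failed")

  fit <- best$fit
  q_hat <- fit$par
  est <- to_natural(q_hat)
  pred_final <- unlist(model(c(as.list(est), fixed)), use.names = FALSE)
  resid_final <- obs_stacked - pred_final

  # linearised covariance on the internal scale
  H <- as.matrix(fit$hessian)
  dof <- n_obs - n_par
  sigma2 <- fit$deviance / dof
  dH <- sqrt(diag(H))
  cond <- Inf
  if (all(is.finite(dH)) && all(dH > 0)) {
    Hn <- H / tcrossprod(dH)
    cond <- tryCatch(kappa(Hn, exact = TRUE), error = function(e) Inf)
  }
  se_internal <- rep(NA_real_, n_par)
  param_cor <- matrix(NA_real_, n_par, n_par,
                      dimnames = list(pnames, pnames))
  cov_ok <- tryCatch({
    cv <- solve(H) * sigma2
    se_internal <- sqrt(pmax(diag(cv), 0))
    if (all(diag(cv) > 0)) {
      param_cor <- stats::cov2cor(cv)
      dimnames(param_cor) <- list(pnames, pnames)
    }
    TRUE
  }, error = function(e) FALSE)
  se <- ifelse(tr == "log", est * se_internal, se_internal)
  names(se) <- pnames
  if (!cov_ok) se[] <- NA_real_

  r_pearson <- if (stats::sd(pred_final) > 0 && stats::sd(obs_stacked) > 0)
    stats::cor(obs_stacked, pred_final) else NA_real_

  structure(list(
    estimates = est,
    std_errors = se,
    correlation_r = r_pearson,
    residuals = resid_final,
    residual_norm = sqrt(sum(resid_final^2)),
    converged = isTRUE(best$converged),
    n_obs = n_obs,
    n_params = n_par,
    covariance_condition = cond,
    param_correlation = param_cor,
    identifiable = is.finite(cond) && cond < 1e8 && cov_ok,
    rss_trace = fit$rsstrace,
    fixed = fixed,
    message = fit$message
  ), class = "flavokin_fit")
}

#' Stack residuals of several curves sharing one parameter vector
#'
#' Assembles the pooled residual vector for a simultaneous multi-curve fit:
#' curve residuals are concatenated in the order the curves are supplied, so
#' the stacked length equals the total number of observations.
#'
#' @param model function of a named parameter list returning a list of
#'   predicted vectors.
#' @param params named list of parameter values.
#' @param observed list of observed numeric vectors.
#' @return numeric vector of residuals (observed minus predicted), stacked.
#' @export
multi_curve_residuals <- function(model, params, observed) {
  if (is.numeric(observed)) observed <- list(observed)
  pred <- model(params)
  if (length(pred) != length(observed))
    stop("model returned ", length(pred), " curves for ",
         length(observed), " observed curves")
  lens_p <- lengths(pred)
  lens_o <- lengths(observed)
  if (any(lens_p != lens_o))
    stop("curve length mismatch: predicted ",
         paste(lens_p, collapse = "/"), " vs observed ",
         paste(lens_o, collapse = "/"))
  unlist(observed, use.names = FALSE) - unlist(pred, use.names = FALSE)
}

#' @export
print.flavokin_fit <- function(x, ...) {
  cat("Nonlinear least-squares fit (", x$n_params, " parameters, ",
      x$n_obs, " observations)\n", sep = "")
  tab <- data.frame(estimate = x$estimates, std_error = x$std_errors)
  print(format(tab, digits = 4))
  cat(sprintf("r = %.4f   residual norm = %.4g   converged: %s\n",
              x$correlation_r, x$residual_norm, x$converged))
  if (!x$identifiable)
    cat("warning: parameters poorly identifiable (covariance condition ",
        format(x$covariance_condition, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.flavokin_fit <- function(x, ...) {
  data.frame(parameter = names(x$estimates),
             estimate = unname(x$estimates),
             std_error = unname(x$std_errors),
             row.names = NULL)
}
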