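#' Read a kinetic trace CSV
#'
#' Expected dialect: a mandatory header row with a `time_s` column and one
#' `A_<wavelength-nm>` absorbance column per wavelength. Concentration and
#' time units are SI (s, AU). Malformed input is rejected with the
#' offending line number.
#'
#' @param path path to a CSV file.
#' @return data frame `time_s`, `A_<nm>` ...
#' @export
read_trace_csv <- function(path) {
  d <- read_checked_csv(path, required = "time_s")
  acols <- grep("^A_", names(d), value = TRUE)
  if (!length(acols))
    stop("no A_<wavelength> columns found in ", path)
  t <- d$time_s
  if (anyNA(t) || is.unsorted(t, strictly = TRUE)) {
    bad <- which(c(FALSE, diff(t) <= 0) | is.na(t))[1L]
    stop("time_s must be strictly increasing: violation at line ",
         bad + 1L, " of ", path)
  }
  d[c("time_s", acols)]
}

#' Write a kinetic trace CSV
#'
#' @param traces data frame `time_s`, `A_<nm>` ...
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(traces, path) {
  stopifnot(is.data.frame(traces), "time_s" %in% names(traces))
  utils::write.csv(traces, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an equilibrium titration CSV (`pH, absorbance`)
#'
#' @param path path to a CSV file.
#' @return data frame `pH`, `absorbance`.
#' @export
read_titration_csv <- function(path) {
  read_checked_csv(path, required = c("pH", "absorbance"))
}

#' Read a fluorescence titration CSV (`ligand_total_M, fluorescence`)
#'
#' Ligand concentrations must be in molar units (scientific notation),
#' never micromolar, to avoid silent 1e6 scale errors.
#'
#' @param path path to a CSV file.
#' @return data frame `ligand_total_M`, `fluorescence`.
#' @export
read_quench_csv <- function(path) {
  d <- read_checked_csv(path, required = c("ligand_total_M", "fluorescence"))
  if (any(d$ligand_total_M > 1))
    stop("ligand_total_M > 1 M: concentrations must be molar, not uM")
  d
}

#' Read a metal-binding isotherm CSV (`Mt, deltaA`)
#'
#' @param path path to a CSV file.
#' @return data frame `Mt`, `deltaA`.
#' @export
read_isotherm_csv <- function(path) {
  d <- read_checked_csv(path, required = c("Mt", "deltaA"))
  if (any(d$Mt > 1))
    stop("Mt > 1 M: concentrations must be molar, not uM")
  d
}

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(first))
    stop("empty file: ", path)
  d <- utils::read.csv(path, check.names = FALSE)
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols))
    stop("missing column(s) ", paste(missing_cols, collapse = ", "),
         " in ", path, " (header row is mandatory)")
  if (nrow(d) == 0L) stop("no data rows in ", path)
  for (cn in names(d)) {
    v <- d[[cn]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn)) {
        bad <- which(is.na(vn))[1L]
        stop("non-numeric value in column '", cn, "' at line ",
             bad + 1L, " of ", path)
      }
      d[[cn]] <- vn
    } else if (anyNA(v)) {
      stop("missing value in column '", cn, "' at line ",
           which(is.na(v))[1L] + 1L, " of ", path)
    }
  }
  d
}

#' Write a fit report
#'
#' Serialises a fit as a flat `parameter, estimate, std_error` CSV and, if
#' `text_path` is given, a human-readable summary echoing the layout of a
#' published kinetic table (estimate with its standard deviation in
#' parentheses, plus the pooled correlation coefficient). Fixed parameters
#' are echoed so the report is self-describing.
#'
#' @param fit a `"flavokin_fit"` object.
#' @param path output CSV path.
#' @param text_path optional output path for the text summary.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path, text_path = NULL) {
  stopifnot(inherits(fit, "flavokin_fit"))
  utils::write.csv(as.data.frame(fit), path, row.names = FALSE,
                   quote = FALSE)
  if (!is.null(text_path)) {
    lines <- c(
      "Nonlinear least-squares fit report",
      sprintf("observations: %d   parameters: %d   converged: %s",
              fit$n_obs, fit$n_params, fit$converged),
      sprintf("%-12s %s", names(fit$estimates),
              sprintf("%.6g (+/-%.2g)", fit$estimates, fit$std_errors)),
      if (length(fit$fixed))
        sprintf("fixed: %s",
                paste(names(fit$fixed),
                      vapply(fit$fixed, function(x)
                        paste(format(x, digits = 6), collapse = "/"),
                        character(1)),
                      sep = " = ", collapse = "; ")),
      sprintf("r = %.4f   residual norm = %.4g",
              fit$correlation_r, fit$residual_norm))
    writeLines(lines, text_path)
  }
  invisible(path)
}
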