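#' Hill dose-response parameters for one rate
#'
#' Four-parameter Hill curve mapping drug concentration to a rate:
#' Hill(C) = e_min + (e_max - e_min) / (1 + (ec50 / C)^k). \code{e_min} is the
#' rate without drug, \code{e_max} the rate at infinite concentration (below
#' \code{e_min} for an inhibited progression rate, above it for an induced
#' death rate), \code{ec50} the half-maximal concentration and \code{k} the
#' steepness.
#'
#' @param e_min rate at zero concentration (1/hour)
#' @param e_max rate at saturating concentration (1/hour)
#' @param ec50 half-maximal concentration (nM, > 0)
#' @param k unitless steepness (> 0)
#' @return an object of class \code{hill_params}
#' @export
hill_params <- function(e_min, e_max, ec50, k) {
  if (!is.finite(ec50) || ec50 <= 0) stop("ec50 must be > 0")
  if (!is.finite(k) || k <= 0) stop("steepness k must be > 0")
  if (!is.finite(e_min) || e_min < 0 || !is.finite(e_max) || e_max < 0)
    stop("e_min and e_max must be >= 0")
  structure(list(e_min = e_min, e_max = e_max, ec50 = ec50, k = k),
            class = "hill_params")
}

#' Evaluate a Hill dose-response curve
#'
#' @param concentration concentration(s) in nM, >= 0; 0 is handled as the
#'   zero-dose limit \code{e_min}
#' @param params a \code{\link{hill_params}}
#' @return rate(s) in 1/hour
#' @export
hill <- function(concentration, params) {
  stopifnot(inherits(params, "hill_params"))
  if (any(!is.finite(concentration)) || any(concentration < 0))
    stop("concentration must be finite and >= 0")
  out <- rep(params$e_min, length(concentration))
  pos <- concentration > 0
  out[pos] <- params$e_min + (params$e_max - params$e_min) /
    (1 + (params$ec50 / concentration[pos])^params$k)
  out
}

#' Dose-response profile of one drug over all model rates
#'
#' Maps concentration to a full \code{\link{rate_set}}. Every rate slot shares
#' one EC50 and one steepness per drug; the zero-dose values (e_min) are the
#' drug-free control rates shared across drugs, with death e_min = 0 by
#' default (no appreciable death in untreated cultures). Saturating effects
#' are given per rate family and recycled across parts; a slot whose e_max
#' equals its e_min is unaffected by the drug.
#'
#' @param drug_name label
#' @param control_rates drug-free \code{\link{rate_set}} (the e_min values)
#' @param ec50 shared half-maximal concentration (nM)
#' @param k shared steepness
#' @param emax_alpha,emax_beta saturating progression rates per part
#'   (default: the control rates, i.e. no effect)
#' @param emax_gamma1,emax_gamma2 saturating death rates per part (default:
#'   the control death rates)
#' @return an object of class \code{drug_response_profile}
#' @export
drug_response_profile <- function(drug_name, control_rates, ec50, k,
                                  emax_alpha = NULL, emax_beta = NULL,
                                  emax_gamma1 = NULL, emax_gamma2 = NULL) {
  stopifnot(inherits(control_rates, "rate_set"))
  s <- control_rates$structure
  fill <- function(x, ctrl, n, nm) {
    if (is.null(x)) return(ctrl)
    if (length(x) == 1L) x <- rep(x, n)
    if (length(x) != n) stop(sprintf("%s must have length 1 or %d", nm, n))
    if (any(!is.finite(x)) || any(x < 0)) stop(sprintf("%s must be >= 0", nm))
    as.numeric(x)
  }
  emax <- list(
    alpha = fill(emax_alpha, control_rates$alpha, s$g1_parts, "emax_alpha"),
    beta = fill(emax_beta, control_rates$beta, s$sg2_parts, "emax_beta"),
    gamma1 = fill(emax_gamma1, control_rates$gamma1, s$g1_parts, "emax_gamma1"),
    gamma2 = fill(emax_gamma2, control_rates$gamma2, s$sg2_parts, "emax_gamma2")
  )
  if (ec50 <= 0 || k <= 0) stop("ec50 and k must be > 0")
  structure(list(drug_name = drug_name, control_rates = control_rates,
                 ec50 = ec50, k = k, emax = emax),
            class = "drug_response_profile")
}

#' @export
print.drug_response_profile <- function(x, ...) {
  cat(sprintf("drug_response_profile '%s': EC50 = %.3g nM, k = %.3g\n",
              x$drug_name, x$ec50, x$k))
  cat("  saturating rates (1/hour):\n")
  for (nm in names(x$emax))
    cat(sprintf("    %-6s: %s\n", nm, paste(signif(x$emax[[nm]], 4), collapse = " ")))
  invisible(x)
}

#' Rate set of a drug at a given concentration
#'
#' Applies the drug's Hill curves to every rate slot. At concentration 0 the
#' control rates are returned exactly.
#'
#' @param profile a \code{\link{drug_response_profile}}
#' @param concentration nM, >= 0
#' @return a \code{\link{rate_set}}
#' @export
rates_at_concentration <- function(profile, concentration) {
  stopifnot(inherits(profile, "drug_response_profile"))
  ctrl <- profile$control_rates
  if (length(concentration) != 1L) stop("concentration must be a single value")
  if (concentration == 0) return(ctrl)
  hv <- function(emin, emax)
    mapply(function(a, b) hill(concentration, hill_params(a, b, profile$ec50, profile$k)),
           emin, emax)
  rate_set(alpha = hv(ctrl$alpha, profile$emax$alpha),
           beta = hv(ctrl$beta, profile$emax$beta),
           gamma1 = hv(ctrl$gamma1, profile$emax$gamma1),
           gamma2 = hv(ctrl$gamma2, profile$emax$gamma2),
           structure = ctrl$structure)
}
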