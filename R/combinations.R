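#' Scaled (fractional) drug effect on a progression rate
#'
#' Progression effects are saturable, so they are expressed on a 0-1 scale
#' relative to control: effect = (control - rate) / control, with 0 meaning
#' no effect and 1 a complete block. \code{unscale_effect} is the exact
#' inverse.
#'
#' @param rate drugged rate(s), 1/hour, with 0 <= rate <= control
#' @param control_rate drug-free rate(s), > 0
#' @return fractional effect(s) in [0, 1]
#' @export
scale_effect <- function(rate, control_rate) {
  if (any(control_rate <= 0)) stop("control rate must be > 0")
  if (any(rate < 0)) stop("rate must be >= 0")
  if (any(rate > control_rate + 1e-12))
    stop("rate exceeds control: a progression effect cannot be negative")
  (control_rate - pmin(rate, control_rate)) / control_rate
}

#' @rdname scale_effect
#' @param effect fractional effect(s) in [0, 1]
#' @export
unscale_effect <- function(effect, control_rate) {
  if (any(effect < 0 | effect > 1)) stop("effect must lie in [0, 1]")
  control_rate * (1 - effect)
}

#' Bliss-independent combination of two drugs' rate effects
#'
#' Progression rates (saturable) are combined on the fractional-effect scale
#' by Bliss independence, E_ab = E_a + E_b - E_a E_b, per part-rate slot, and
#' mapped back to rates against the shared control. Death rates
#' (non-saturable) are combined by adding each drug's absolute added death
#' rate to the control.
#'
#' @param rates_a,rates_b single-drug \code{\link{rate_set}}s at the doses to
#'   combine
#' @param control the shared drug-free \code{\link{rate_set}}
#' @return combined \code{\link{rate_set}}
#' @export
bliss_combine_rates <- function(rates_a, rates_b, control) {
  stopifnot(inherits(rates_a, "rate_set"), inherits(rates_b, "rate_set"),
            inherits(control, "rate_set"))
  comb_prog <- function(a, b, ctrl) {
    ea <- scale_effect(a, ctrl); eb <- scale_effect(b, ctrl)
    unscale_effect(ea + eb - ea * eb, ctrl)
  }
  comb_death <- function(a, b, ctrl) {
    da <- a - ctrl; db <- b - ctrl
    if (any(da < -1e-12) || any(db < -1e-12))
      stop("death rate below control: added death effects must be >= 0")
    ctrl + pmax(da, 0) + pmax(db, 0)
  }
  rate_set(alpha = comb_prog(rates_a$alpha, rates_b$alpha, control$alpha),
           beta = comb_prog(rates_a$beta, rates_b$beta, control$beta),
           gamma1 = comb_death(rates_a$gamma1, rates_b$gamma1, control$gamma1),
           gamma2 = comb_death(rates_a$gamma2, rates_b$gamma2, control$gamma2),
           structure = control$structure)
}

#' Predict a two-drug combination trajectory from rate-level Bliss
#'
#' Evaluates each drug's rates at its dose, combines them with
#' \code{\link{bliss_combine_rates}} against the shared control, and
#' simulates the mean-field trajectory.
#'
#' @param profile_a,profile_b \code{\link{drug_response_profile}}s sharing
#'   the same control rates
#' @param dose_a,dose_b concentrations in nM (a zero dose reduces the
#'   prediction to the other drug alone)
#' @param times uniform grid in hours
#' @param initial_g1_fraction starting G1 fraction
#' @param ... further arguments to \code{\link{simulate_mean_field}}
#' @return a \code{population_trajectory}
#' @export
predict_combination_trajectory <- function(profile_a, profile_b, dose_a, dose_b,
                                           times = seq(0, 96, by = 0.5),
                                           initial_g1_fraction = 0.75, ...) {
  ctrl_a <- profile_a$control_rates
  ctrl_b <- profile_b$control_rates
  same <- isTRUE(all.equal(ctrl_a$alpha, ctrl_b$alpha)) &&
    isTRUE(all.equal(ctrl_a$beta, ctrl_b$beta)) &&
    isTRUE(all.equal(ctrl_a$gamma1, ctrl_b$gamma1)) &&
    isTRUE(all.equal(ctrl_a$gamma2, ctrl_b$gamma2))
  if (!same) stop("profiles must share the same control rates")
  ra <- rates_at_concentration(profile_a, dose_a)
  rb <- rates_at_concentration(profile_b, dose_b)
  comb <- bliss_combine_rates(ra, rb, ctrl_a)
  simulate_mean_field(comb, initial_g1_fraction, times, ...)
}

#' Bliss combination applied directly to cell numbers (baseline)
#'
#' The conventional benchmark: per timepoint, each drug's count is scaled to
#' a fractional effect against the control count, the effects are combined by
#' Bliss independence, and the result is scaled back to a count. Effects are
#' clipped into [0, 1] (a count above control carries no inhibition).
#'
#' @param count_a,count_b single-drug count series at matching timepoints
#' @param count_control control count series (or a scalar; must be > 0)
#' @return predicted combination count series
#' @export
bliss_combine_cell_numbers <- function(count_a, count_b, count_control = 1) {
  if (any(count_control <= 0)) stop("control counts must be > 0")
  n <- length(count_a)
  if (length(count_b) != n) stop("count series lengths differ")
  clip01 <- function(x) pmin(pmax(x, 0), 1)
  ea <- clip01((count_control - count_a) / count_control)
  eb <- clip01((count_control - count_b) / count_control)
  count_control * (1 - (ea + eb - ea * eb))
}
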