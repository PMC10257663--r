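#' Specification of a simultaneous multi-drug fit
#'
#' Defines the free-parameter layout for fitting the chain model to processed
#' G1/S-G2 series across drugs and doses. Drug-free parameters (control
#' progression rates and, optionally, the initial G1 fraction) are shared
#' across all drugs and concentrations; each drug contributes one EC50, one
#' steepness, and saturating effects (e_max) for the rate families it
#' affects. Unaffected families keep their control values (progression) or
#' stay at zero (death). Rates and EC50s are searched on a log10 scale,
#' fractions on a logit scale, all with finite box bounds.
#'
#' Setting \code{structure = phase_structure(1, 1, 1, 1)} turns the fit into
#' the two-state exponential baseline model (one subphase per phase),
#' enabling a like-for-like model comparison.
#'
#' @param drug_doses named list: for each drug, the numeric dose series (nM)
#'   present in the data
#' @param affects named list: for each drug, a character vector drawn from
#'   \code{c("alpha", "beta", "gamma1", "gamma2")} naming the rate families
#'   the drug may affect
#' @param structure a \code{\link{phase_structure}}
#' @param tie_parts one shared value per rate family across parts (TRUE,
#'   default) or a free value per part
#' @param g1_fraction a number to fix the initial G1 fraction, or
#'   \code{"free"}
#' @param rate_bounds,death_bounds,k_bounds,fraction_bounds search intervals
#' @param init_spread initial subphase spread used in model evaluation
#' @return an object of class \code{fit_spec}
#' @export
fit_spec <- function(drug_doses, affects,
                     structure = phase_structure(),
                     tie_parts = TRUE,
                     g1_fraction = 0.75,
                     rate_bounds = c(1e-4, 10),
                     death_bounds = c(1e-6, 2),
                     k_bounds = c(0.1, 10),
                     fraction_bounds = c(0.01, 0.99),
                     init_spread = "uniform") {
  stopifnot(inherits(structure, "phase_structure"))
  if (!identical(sort(names(drug_doses)), sort(names(affects))))
    stop("drug_doses and affects must name the same drugs")
  fams <- c("alpha", "beta", "gamma1", "gamma2")
  for (d in names(affects))
    if (!all(affects[[d]] %in% fams))
      stop("affects entries must be among: ", paste(fams, collapse = ", "))

  tbl <- list()
  add <- function(name, transform, lo, hi)
    tbl[[length(tbl) + 1L]] <<- data.frame(name = name, transform = transform,
                                           lower = lo, upper = hi)
  nparts <- function(fam) if (fam %in% c("alpha", "gamma1")) structure$g1_parts else structure$sg2_parts
  slot_names <- function(prefix, fam) {
    k <- if (tie_parts) 1L else nparts(fam)
    if (k == 1L) prefix else paste0(prefix, "_", seq_len(k))
  }
  for (nm in slot_names("ctrl_alpha", "alpha"))
    add(nm, "log10", log10(rate_bounds[1]), log10(rate_bounds[2]))
  for (nm in slot_names("ctrl_beta", "beta"))
    add(nm, "log10", log10(rate_bounds[1]), log10(rate_bounds[2]))
  if (identical(g1_fraction, "free"))
    add("g1_fraction", "logit", stats::qlogis(fraction_bounds[1]),
        stats::qlogis(fraction_bounds[2]))
  for (d in names(drug_doses)) {
    pos <- drug_doses[[d]][drug_doses[[d]] > 0]
    if (!length(pos)) stop(sprintf("drug %s has no positive doses", d))
    add(paste0("ec50_", d), "log10", log10(min(pos) / 10), log10(max(pos) * 10))
    add(paste0("k_", d), "log10", log10(k_bounds[1]), log10(k_bounds[2]))
    for (fam in affects[[d]]) {
      b <- if (fam %in% c("alpha", "beta")) rate_bounds else death_bounds
      for (nm in slot_names(paste0("emax_", fam, "_", d), fam))
        add(nm, "log10", log10(b[1]), log10(b[2]))
    }
  }
  tbl <- do.call(rbind, tbl)
  out <- list(param_table = tbl, drug_doses = drug_doses, affects = affects,
              structure = structure, tie_parts = tie_parts,
              g1_fraction = g1_fraction, init_spread = init_spread)
  class(out) <- "fit_spec"
  out
}

back_transform <- function(x, transform) {
  switch(transform, log10 = 10^x, logit = stats::plogis(x),
         stop("unknown transform"))
}

forward_transform <- function(v, transform) {
  switch(transform, log10 = log10(v), logit = stats::qlogis(v),
         stop("unknown transform"))
}

#' Unpack a parameter vector into model objects
#'
#' @param par numeric vector on the transformed (search) scale, in the order
#'   of \code{spec$param_table}
#' @param spec a \code{\link{fit_spec}}
#' @return list with \code{control} (\code{rate_set}), \code{g1_fraction},
#'   and \code{profiles} (named list of \code{drug_response_profile})
#' @export
unpack_params <- function(par, spec) {
  tbl <- spec$param_table
  if (length(par) != nrow(tbl)) stop("parameter vector length mismatch")
  nat <- mapply(back_transform, par, tbl$transform)
  names(nat) <- tbl$name
  s <- spec$structure
  pick <- function(prefix, n) {
    v <- nat[names(nat) == prefix | names(nat) %in% paste0(prefix, "_", seq_len(n))]
    if (length(v) == 1L) rep(unname(v), n) else unname(v)
  }
  ctrl <- rate_set(alpha = pick("ctrl_alpha", s$g1_parts),
                   beta = pick("ctrl_beta", s$sg2_parts),
                   gamma1 = 0, gamma2 = 0, structure = s)
  f <- if (identical(spec$g1_fraction, "free")) unname(nat["g1_fraction"]) else spec$g1_fraction
  profiles <- list()
  for (d in names(spec$drug_doses)) {
    args <- list(drug_name = d, control_rates = ctrl,
                 ec50 = unname(nat[paste0("ec50_", d)]),
                 k = unname(nat[paste0("k_", d)]))
    for (fam in spec$affects[[d]]) {
      n <- if (fam %in% c("alpha", "gamma1")) s$g1_parts else s$sg2_parts
      args[[paste0("emax_", fam)]] <- pick(paste0("emax_", fam, "_", d), n)
    }
    profiles[[d]] <- do.call(drug_response_profile, args)
  }
  list(control = ctrl, g1_fraction = f, profiles = profiles)
}

#' Group processed series for fitting
#'
#' @param processed a \code{\link{process_population}} result (columns drug,
#'   concentration, time_h, g1, sg2)
#' @return list of per-(drug, dose) blocks used by \code{\link{sse_cost}}
#' @export
prepare_fit_data <- function(processed) {
  need <- c("drug", "concentration", "time_h", "g1", "sg2")
  if (!all(need %in% names(processed)))
    stop("processed data must have columns: ", paste(need, collapse = ", "))
  blocks <- split(processed, list(processed$drug, processed$concentration), drop = TRUE)
  lapply(unname(blocks), function(b) {
    b <- b[order(b$time_h), , drop = FALSE]
    check_uniform_grid(b$time_h)
    list(drug = as.character(b$drug[1L]), concentration = b$concentration[1L],
         times = b$time_h, g1 = b$g1, sg2 = b$sg2)
  })
}

# model-vs-data squared error for one block
block_sse <- function(block, params, spec) {
  rates <- if (block$concentration == 0) params$control
           else rates_at_concentration(params$profiles[[block$drug]], block$concentration)
  m <- sim_phase_totals(rates, params$g1_fraction, block$times,
                        init_spread = spec$init_spread)
  # apply the data's normalization convention (mean of the first three
  # timepoints) to the model so both series share one scale
  k <- min(3L, length(m$g1))
  scale <- mean(m$g1[seq_len(k)] + m$sg2[seq_len(k)])
  sum((m$g1 / scale - block$g1)^2) + sum((m$sg2 / scale - block$sg2)^2)
}

#' Sum-of-squared-error cost of a parameter vector
#'
#' The cost is the squared difference between model and data G1 and S-G2 cell
#' numbers summed over all timepoints, concentrations and drugs. The model
#' prediction is normalized to the mean of its first three timepoints, the
#' same convention applied to observed counts, so that model and data share a
#' scale. A parameter
#' vector whose model evaluation fails returns a large finite penalty.
#'
#' @param par transformed parameter vector
#' @param spec a \code{\link{fit_spec}}
#' @param blocks output of \code{\link{prepare_fit_data}}
#' @param by_drug also return the per-drug decomposition
#' @return scalar SSE, or a named list when \code{by_drug = TRUE}
#' @export
sse_cost <- function(par, spec, blocks, by_drug = FALSE) {
  res <- tryCatch({
    params <- unpack_params(par, spec)
    vapply(blocks, block_sse, numeric(1L), params = params, spec = spec)
  }, error = function(e) NULL)
  if (is.null(res)) {
    if (by_drug) return(list(total = 1e12, by_drug = NULL))
    return(1e12)
  }
  if (!by_drug) return(sum(res))
  drugs <- vapply(blocks, `[[`, character(1L), "drug")
  list(total = sum(res), by_drug = tapply(res, drugs, sum))
}

#' Fit the model to processed series by differential evolution
#'
#' Minimizes \code{\link{sse_cost}} over the free parameters of \code{spec}
#' with the seeded DE optimizer. Deterministic given \code{seed}.
#'
#' @param spec a \code{\link{fit_spec}}
#' @param processed a \code{\link{process_population}} result
#' @param seed RNG seed for the optimizer
#' @param n_pop,max_iter DE settings (defaults scale with dimension)
#' @param init optional matrix of starting parameter vectors (transformed
#'   scale)
#' @return object of class \code{lct_fit}: \code{par}, \code{params}
#'   (unpacked), \code{sse}, \code{sse_by_drug}, \code{trace},
#'   \code{converged}, \code{seed}, \code{spec}
#' @export
fit_model <- function(spec, processed, seed = 1, n_pop = NULL,
                      max_iter = 150L, init = NULL) {
  blocks <- prepare_fit_data(processed)
  if (!length(blocks)) stop("no data blocks to fit")
  obj <- function(p) sse_cost(p, spec, blocks)
  tbl <- spec$param_table
  de <- de_optimize(obj, tbl$lower, tbl$upper, n_pop = n_pop,
                    max_iter = max_iter, seed = seed, init = init)
  dec <- sse_cost(de$par, spec, blocks, by_drug = TRUE)
  out <- list(par = stats::setNames(de$par, tbl$name),
              params = unpack_params(de$par, spec),
              sse = de$value, sse_by_drug = dec$by_drug,
              trace = de$trace, converged = de$converged,
              iterations = de$iterations, seed = seed, spec = spec)
  class(out) <- "lct_fit"
  out
}

#' @export
print.lct_fit <- function(x, ...) {
  cat(sprintf("lct_fit: SSE = %.6g after %d DE generations (converged: %s)\n",
              x$sse, x$iterations, x$converged))
  dur <- tryCatch(average_phase_durations(x$params$control), error = function(e) NULL)
  if (!is.null(dur))
    cat(sprintf("  control durations: G1 = %.1f h, S-G2 = %.1f h\n", dur["g1"], dur["sg2"]))
  for (d in names(x$params$profiles))
    cat(sprintf("  %s: EC50 = %.3g nM, k = %.3g\n", d,
                x$params$profiles[[d]]$ec50, x$params$profiles[[d]]$k))
  invisible(x)
}

#' Local sensitivity analysis of a fit
#'
#' Re-evaluates the cost while scaling one fitted parameter at a time across
#' a multiplicative factor grid spanning 0.1 to 10, holding the others at
#' their optimum. A parameter is flagged identifiable when the cost rises by
#' more than 1 percent at factors 0.5 and 2.
#'
#' @param fit an \code{\link{fit_model}} result
#' @param processed the data the fit used
#' @param factors multiplicative grid (must contain 0.5, 1 and 2)
#' @return data frame with columns \code{param}, \code{factor}, \code{cost},
#'   plus an \code{"identifiable"} attribute (named logical)
#' @export
sensitivity_profile <- function(fit, processed,
                                factors = c(0.1, 0.2, 0.5, 1, 2, 5, 10)) {
  stopifnot(inherits(fit, "lct_fit"))
  if (!all(c(0.5, 1, 2) %in% factors))
    stop("factor grid must contain 0.5, 1 and 2")
  spec <- fit$spec
  blocks <- prepare_fit_data(processed)
  tbl <- spec$param_table
  rows <- list()
  ident <- logical(nrow(tbl))
  names(ident) <- tbl$name
  for (i in seq_len(nrow(tbl))) {
    v0 <- back_transform(fit$par[i], tbl$transform[i])
    costs <- vapply(factors, function(f) {
      v <- v0 * f
      if (tbl$transform[i] == "logit" && (v <= 0 || v >= 1)) return(NA_real_)
      p <- unname(fit$par)
      p[i] <- forward_transform(v, tbl$transform[i])
      sse_cost(p, spec, blocks)
    }, numeric(1L))
    rows[[i]] <- data.frame(param = tbl$name[i], factor = factors, cost = costs)
    c_half <- costs[factors == 0.5]; c_two <- costs[factors == 2]
    c_one <- costs[factors == 1]
    ident[i] <- isTRUE(c_half > 1.01 * c_one) && isTRUE(c_two > 1.01 * c_one)
  }
  out <- do.call(rbind, rows)
  attr(out, "identifiable") <- ident
  out
}
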