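#' Extract completed phase durations from a lineage table
#'
#' G1 durations are taken from daughter cells (born at a tracked division, so
#' the phase is entered at its start) whose G1-to-S transition was observed;
#' cells already mid-phase at time zero would contribute only residual
#' durations and are excluded. S-G2 durations come from cells whose
#' transition and subsequent division were both observed. Censored and
#' death-truncated intervals are excluded, mirroring the tracking exclusions
#' of incomplete lineages (this right-truncates long durations near the
#' assay horizon).
#'
#' @param records a \code{\link{simulate_cells}} result
#' @param phase \code{"G1"} or \code{"SG2"}
#' @return numeric vector of durations (hours)
#' @export
phase_durations <- function(records, phase = c("G1", "SG2")) {
  phase <- match.arg(phase)
  stopifnot(inherits(records, "cell_records"))
  if (phase == "G1") {
    ok <- records$birth_phase == "G1" & !is.na(records$g1s_time) &
      !is.na(records$parent_id)
    records$g1s_time[ok] - records$birth_time[ok]
  } else {
    ok <- !is.na(records$g1s_time) & records$fate == "divided"
    records$end_time[ok] - records$g1s_time[ok]
  }
}

#' Estimate the gamma shape of phase durations
#'
#' Maximum-likelihood gamma fit (location fixed at zero) to a sample of
#' completed phase durations. The integer subphase count of the chain model
#' is the fitted shape rounded to the nearest integer (half up), floored at 1.
#'
#' @param durations positive durations in hours, n >= 30
#' @return list with \code{shape}, \code{rate}, \code{scale},
#'   \code{subphases} (integer), \code{mean} (fitted mean shape/rate),
#'   \code{loglik}, \code{n}
#' @export
estimate_gamma_shape <- function(durations) {
  x <- durations[!is.na(durations)]
  if (length(x) < 30L) stop("need at least 30 complete durations")
  if (any(x <= 0)) stop("durations must be > 0")
  if (stats::sd(x) == 0) stop("degenerate sample: all durations equal")
  # moment start keeps the MLE stable at large shapes
  m <- mean(x); v <- stats::var(x)
  start <- list(shape = m^2 / v, rate = m / v)
  fit <- MASS::fitdistr(x, "gamma", start = start, lower = c(1e-8, 1e-8))
  shape <- unname(fit$estimate["shape"])
  rate <- unname(fit$estimate["rate"])
  list(shape = shape, rate = rate, scale = 1 / rate,
       subphases = max(1L, as.integer(floor(shape + 0.5))),
       mean = shape / rate, loglik = fit$loglik, n = length(x))
}

#' Correlation between paired G1 and S-G2 durations
#'
#' @param g1,sg2 paired per-cell durations (hours), >= 10 complete pairs
#' @param method \code{"pearson"} (default) or \code{"spearman"}
#' @return list with \code{r}, \code{n}, \code{method}
#' @export
phase_correlation <- function(g1, sg2, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(g1, sg2)
  g1 <- g1[ok]; sg2 <- sg2[ok]
  if (length(g1) < 10L) stop("need at least 10 complete pairs")
  if (stats::sd(g1) == 0 || stats::sd(sg2) == 0)
    stop("correlation undefined: a duration array is constant")
  list(r = stats::cor(g1, sg2, method = method), n = length(g1), method = method)
}

#' Mean and variance of a duration sample
#'
#' @param durations numeric durations (hours), n >= 1
#' @return list with \code{mean}, \code{variance} (unbiased; 0 and flagged
#'   degenerate when n = 1), \code{n}, \code{degenerate}
#' @export
duration_summary <- function(durations) {
  x <- durations[!is.na(durations)]
  if (length(x) < 1L) stop("empty duration sample")
  degenerate <- length(x) == 1L
  list(mean = mean(x),
       variance = if (degenerate) 0 else stats::var(x),
       n = length(x), degenerate = degenerate)
}
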