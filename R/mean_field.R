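#' Generator matrix of the mean-field linear chain system
#'
#' Builds the matrix A such that d(state)/dt = A state for the chain of G1 and
#' S-G2 subphases. Each subphase loses mass at its part's progression plus
#' death rate; progression feeds the next subphase; exit from the final S-G2
#' subphase feeds the first G1 subphase multiplied by \code{division_factor}
#' (2 for a division producing two daughters). With
#' \code{include_dead_compartments = TRUE} two absorbing rows accumulate the
#' death outflow of each phase, giving exact expected cumulative deaths.
#'
#' @param rates a \code{\link{rate_set}}
#' @param structure a \code{\link{phase_structure}} (defaults to the one
#'   carried by \code{rates})
#' @param division_factor offspring per division (default 2; 1 turns the chain
#'   into a mass-conserving loop when death is zero)
#' @param include_dead_compartments append absorbing dead-in-G1 and
#'   dead-in-S-G2 states
#' @return a dense square matrix; with the default structure 28 x 28, or
#'   30 x 30 with dead compartments
#' @export
build_generator <- function(rates, structure = rates$structure,
                            division_factor = 2,
                            include_dead_compartments = FALSE) {
  stopifnot(inherits(rates, "rate_set"), inherits(structure, "phase_structure"))
  if (!identical(unclass(structure), unclass(rates$structure)))
    stop("structure does not match the structure the rate_set was built for")
  if (!is.finite(division_factor) || division_factor < 0)
    stop("division_factor must be a non-negative number")
  n1 <- structure$n_g1; n2 <- structure$n_sg2
  n <- n1 + n2
  sr <- subphase_rates(rates)
  dim_out <- n + if (include_dead_compartments) 2L else 0L
  A <- matrix(0, dim_out, dim_out)
  # losses on the diagonal, progression on the sub-diagonal
  for (j in seq_len(n)) {
    A[j, j] <- -(sr$prog[j] + sr$death[j])
    if (j > 1L) A[j, j - 1L] <- sr$prog[j - 1L]
  }
  # division: last S-G2 subphase feeds the first G1 subphase
  A[1L, n] <- division_factor * sr$prog[n]
  if (include_dead_compartments) {
    A[n + 1L, seq_len(n1)] <- sr$death[seq_len(n1)]
    A[n + 2L, n1 + seq_len(n2)] <- sr$death[n1 + seq_len(n2)]
  }
  A
}

# initial expected-mass vector over subphases; the model fixes only the G1
# fraction, so the within-phase spread is a modelling choice
initial_state <- function(structure, initial_g1_fraction,
                          init_spread = c("uniform", "first_subphase", "stationary"),
                          rates = NULL, total = 1) {
  init_spread <- match.arg(init_spread)
  f <- initial_g1_fraction
  if (!is.finite(f) || f < 0 || f > 1)
    stop("initial_g1_fraction must lie in [0, 1]")
  n1 <- structure$n_g1; n2 <- structure$n_sg2
  x <- numeric(n1 + n2)
  if (init_spread == "uniform") {
    x[seq_len(n1)] <- f / n1
    x[n1 + seq_len(n2)] <- (1 - f) / n2
  } else if (init_spread == "first_subphase") {
    x[1L] <- f
    x[n1 + 1L] <- 1 - f
  } else {
    if (is.null(rates))
      stop("init_spread = 'stationary' needs the rate_set to compute the dominant eigenvector")
    A <- build_generator(rates, structure)
    e <- eigen(A)
    v <- abs(Re(e$vectors[, which.max(Re(e$values))]))
    vg1 <- v[seq_len(n1)]; vs <- v[n1 + seq_len(n2)]
    if (sum(vg1) <= 0 || sum(vs) <= 0)
      stop("degenerate dominant eigenvector; cannot form stationary spread")
    x[seq_len(n1)] <- f * vg1 / sum(vg1)
    x[n1 + seq_len(n2)] <- (1 - f) * vs / sum(vs)
  }
  x * total
}

check_uniform_grid <- function(times) {
  if (length(times) < 2L) stop("time grid needs at least 2 points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  dt <- diff(times)
  if (max(dt) - min(dt) > 1e-9 * max(dt))
    stop("non-uniform time grid: the propagator is precomputed for one step size")
  dt[1L]
}

#' Simulate the mean-field population trajectory
#'
#' Propagates the expected subphase occupancies of the linear chain model from
#' a unit starting population, split \code{initial_g1_fraction} :
#' (1 - \code{initial_g1_fraction}) between G1 and S-G2 and spread across
#' subphases according to \code{init_spread}. Propagation uses a single matrix
#' exponential of the generator per step size, applied repeatedly over the
#' uniform grid; expected cumulative deaths come from absorbing compartments,
#' i.e. the exact integral of the instantaneous death flux.
#'
#' @param rates a \code{\link{rate_set}}
#' @param initial_g1_fraction fraction of the starting population in G1
#' @param times uniform time grid in hours (default 0 to 96 by 0.5)
#' @param init_spread how the unit mass is spread over the subphases of each
#'   phase: \code{"uniform"} (default), \code{"first_subphase"} or
#'   \code{"stationary"} (dominant right eigenvector, renormalized per phase)
#' @param division_factor offspring per division (default 2)
#' @param track_dead keep absorbing dead compartments (default TRUE)
#' @param keep_subphases attach the full per-subphase state matrix as
#'   attribute \code{"subphases"}
#' @return a data frame of class \code{population_trajectory} with columns
#'   \code{time_h}, \code{g1}, \code{sg2}, \code{total}, \code{dead_g1},
#'   \code{dead_sg2}, \code{dead_cum} and \code{death_rate} (the instantaneous
#'   death flux n(t), cells/hour)
#' @export
simulate_mean_field <- function(rates, initial_g1_fraction = 0.75,
                                times = seq(0, 96, by = 0.5),
                                init_spread = c("uniform", "first_subphase", "stationary"),
                                division_factor = 2,
                                track_dead = TRUE,
                                keep_subphases = FALSE) {
  init_spread <- match.arg(init_spread)
  structure <- rates$structure
  dt <- check_uniform_grid(times)
  n <- structure$n_total
  A <- build_generator(rates, structure, division_factor = division_factor,
                       include_dead_compartments = track_dead)
  x0 <- initial_state(structure, initial_g1_fraction, init_spread, rates = rates)
  if (track_dead) x0 <- c(x0, 0, 0)
  E <- step_propagator(A, dt)
  nt <- length(times)
  states <- matrix(0, nt, length(x0))
  states[1L, ] <- x0
  for (i in seq_len(nt - 1L)) states[i + 1L, ] <- E %*% states[i, ]
  live <- states[, seq_len(n), drop = FALSE]
  sr <- subphase_rates(rates)
  n1 <- structure$n_g1
  out <- data.frame(
    time_h = times,
    g1 = rowSums(live[, seq_len(n1), drop = FALSE]),
    sg2 = rowSums(live[, n1 + seq_len(structure$n_sg2), drop = FALSE])
  )
  out$total <- out$g1 + out$sg2
  if (track_dead) {
    out$dead_g1 <- states[, n + 1L]
    out$dead_sg2 <- states[, n + 2L]
    out$dead_cum <- out$dead_g1 + out$dead_sg2
  } else {
    out$dead_g1 <- out$dead_sg2 <- out$dead_cum <- NA_real_
  }
  out$death_rate <- as.numeric(live %*% sr$death)
  class(out) <- c("population_trajectory", "data.frame")
  attr(out, "structure") <- structure
  attr(out, "rates") <- rates
  attr(out, "init_spread") <- init_spread
  if (keep_subphases) attr(out, "subphases") <- live
  out
}

# one matrix exponential per (generator, step) pair
step_propagator <- function(A, dt) {
  as.matrix(Matrix::expm(Matrix::Matrix(A * dt)))
}

# lean inner loop for the fitting cost: phase totals only, no bookkeeping
sim_phase_totals <- function(rates, initial_g1_fraction, times,
                             init_spread = "uniform") {
  structure <- rates$structure
  dt <- times[2L] - times[1L]
  A <- build_generator(rates, structure)
  x <- initial_state(structure, initial_g1_fraction, init_spread, rates = rates)
  E <- step_propagator(A, dt)
  nt <- length(times)
  n1 <- structure$n_g1
  g1 <- numeric(nt); sg2 <- numeric(nt)
  g1[1L] <- sum(x[seq_len(n1)]); sg2[1L] <- sum(x[-seq_len(n1)])
  for (i in 2:nt) {
    x <- E %*% x
    g1[i] <- sum(x[seq_len(n1)])
    sg2[i] <- sum(x[-seq_len(n1)])
  }
  list(g1 = g1, sg2 = sg2)
}

#' Accumulate expected deaths by discrete summation of the death flux
#'
#' Computes the cumulative death count N(T) by summing the instantaneous
#' per-subphase death flux n(t) = sum_ij G_ij(t) gamma_ij over the time grid.
#' \code{weight = "dt"} applies a trapezoidal step weight so the sum converges
#' to the exact absorbing-compartment integral as dt shrinks;
#' \code{weight = "none"} is the raw unweighted running sum of n(t).
#'
#' @param trajectory a \code{population_trajectory} produced with
#'   \code{keep_subphases = TRUE}
#' @param weight \code{"dt"} (trapezoidal quadrature, default) or
#'   \code{"none"} (plain running sum)
#' @return numeric vector of N(T), one per timepoint
#' @export
accumulate_dead <- function(trajectory, weight = c("dt", "none")) {
  weight <- match.arg(weight)
  live <- attr(trajectory, "subphases")
  if (is.null(live))
    stop("per-subphase counts missing: rerun simulate_mean_field(..., keep_subphases = TRUE)")
  rates <- attr(trajectory, "rates")
  sr <- subphase_rates(rates)
  n_t <- as.numeric(live %*% sr$death)
  if (weight == "none") return(cumsum(n_t))
  dt <- diff(trajectory$time_h)
  c(0, cumsum((n_t[-length(n_t)] + n_t[-1L]) / 2 * dt))
}

#' Mean G1 and S-G2 phase durations implied by the progression rates
#'
#' The dwell time in part j of G1 is Erlang with shape equal to the subphases
#' per part and rate alpha_j, so the mean G1 duration is
#' sum_j (subphases_per_part / alpha_j), and likewise for S-G2 with beta.
#' Death rates do not enter: these are the durations of cells that complete
#' the phase.
#'
#' @param rates a \code{\link{rate_set}} with strictly positive progression rates
#' @return named numeric vector \code{c(g1 = , sg2 = )} in hours
#' @export
average_phase_durations <- function(rates) {
  s <- rates$structure
  if (any(rates$alpha <= 0) || any(rates$beta <= 0))
    stop("zero progression rate implies an infinite phase duration")
  c(g1 = sum(s$g1_subphases_per_part / rates$alpha),
    sg2 = sum(s$sg2_subphases_per_part / rates$beta))
}

#' Two-state exponential baseline model
#'
#' The classical two-compartment model: dG1/dt = 2 beta G2 - (alpha + gamma1) G1,
#' dG2/dt = alpha G1 - (beta + gamma2) G2, solved with the same
#' matrix-exponential propagation as the chain model. Phase exit times are
#' exponential, so this model cannot produce sustained oscillations in the G1
#' fraction. \code{sg2_loss_uses_gamma1 = TRUE} uses gamma1 in the S-G2 loss
#' term instead of gamma2.
#'
#' @param alpha,beta scalar progression rates (1/hour)
#' @param gamma1,gamma2 scalar death rates (1/hour)
#' @param initial_g1_fraction starting G1 fraction
#' @param times uniform grid in hours
#' @param division_factor offspring per division (default 2)
#' @param sg2_loss_uses_gamma1 use gamma1 as the S-G2 loss rate (a variant form of the two-state equations in circulation)
#' @return a \code{population_trajectory} data frame
#' @export
simulate_exponential_baseline <- function(alpha, beta, gamma1 = 0, gamma2 = 0,
                                          initial_g1_fraction = 0.75,
                                          times = seq(0, 96, by = 0.5),
                                          division_factor = 2,
                                          sg2_loss_uses_gamma1 = FALSE) {
  rates <- c(alpha = alpha, beta = beta, gamma1 = gamma1, gamma2 = gamma2)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    bad <- names(rates)[which(!is.finite(rates) | rates < 0)[1L]]
    stop(sprintf("negative or non-finite rate: %s", bad))
  }
  if (!is.finite(initial_g1_fraction) || initial_g1_fraction < 0 || initial_g1_fraction > 1)
    stop("initial_g1_fraction must lie in [0, 1]")
  dt <- check_uniform_grid(times)
  g2_loss_death <- if (sg2_loss_uses_gamma1) gamma1 else gamma2
  A <- matrix(0, 4, 4)
  A[1, 1] <- -(alpha + gamma1); A[1, 2] <- division_factor * beta
  A[2, 1] <- alpha;             A[2, 2] <- -(beta + g2_loss_death)
  A[3, 1] <- gamma1
  A[4, 2] <- g2_loss_death
  x <- c(initial_g1_fraction, 1 - initial_g1_fraction, 0, 0)
  E <- step_propagator(A, dt)
  nt <- length(times)
  states <- matrix(0, nt, 4)
  states[1L, ] <- x
  for (i in seq_len(nt - 1L)) states[i + 1L, ] <- E %*% states[i, ]
  out <- data.frame(
    time_h = times,
    g1 = states[, 1], sg2 = states[, 2]
  )
  out$total <- out$g1 + out$sg2
  out$dead_g1 <- states[, 3]; out$dead_sg2 <- states[, 4]
  out$dead_cum <- out$dead_g1 + out$dead_sg2
  out$death_rate <- gamma1 * out$g1 + g2_loss_death * out$sg2
  class(out) <- c("population_trajectory", "data.frame")
  out
}
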