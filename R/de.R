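#' Seeded differential-evolution minimizer with box bounds
#'
#' Classic rand/1/bin differential evolution with a dithered mutation factor
#' (F drawn uniformly in [0.5, 1] per trial, a standard self-adaptation that
#' removes the need to tune F). Deterministic given \code{seed}.
#'
#' @param fn objective taking a numeric vector, returning a scalar
#' @param lower,upper box bounds (finite, equal length)
#' @param n_pop population size (default 10 per dimension, minimum 15)
#' @param max_iter generations (default 200)
#' @param cr crossover probability (default 0.9)
#' @param seed RNG seed
#' @param init optional matrix of initial members (rows), clipped to bounds
#' @param tol population-spread convergence tolerance (default 1e-8)
#' @return list with \code{par}, \code{value}, \code{trace} (best value per
#'   generation), \code{converged}, \code{iterations}, \code{n_eval}
#' @export
de_optimize <- function(fn, lower, upper, n_pop = NULL, max_iter = 200L,
                        cr = 0.9, seed = NULL, init = NULL, tol = 1e-8) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(is.finite(lower)), all(is.finite(upper)),
            all(upper > lower))
  if (is.null(n_pop)) n_pop <- max(15L, 10L * d)
  if (!is.null(seed)) set.seed(seed)
  span <- upper - lower
  pop <- matrix(stats::runif(n_pop * d), n_pop, d)
  pop <- sweep(sweep(pop, 2L, span, `*`), 2L, lower, `+`)
  if (!is.null(init)) {
    init <- matrix(pmin(pmax(t(init), lower), upper), ncol = d, byrow = TRUE)
    k <- min(nrow(init), n_pop)
    pop[seq_len(k), ] <- init[seq_len(k), , drop = FALSE]
  }
  fv <- apply(pop, 1L, fn)
  n_eval <- n_pop
  trace <- numeric(max_iter)
  converged <- FALSE
  iter_done <- 0L
  for (iter in seq_len(max_iter)) {
    for (i in seq_len(n_pop)) {
      r <- sample(seq_len(n_pop)[-i], 3L)
      Fd <- stats::runif(1L, 0.5, 1)
      mutant <- pop[r[1L], ] + Fd * (pop[r[2L], ] - pop[r[3L], ])
      mutant <- pmin(pmax(mutant, lower), upper)
      cross <- stats::runif(d) < cr
      cross[sample.int(d, 1L)] <- TRUE
      trial <- ifelse(cross, mutant, pop[i, ])
      ft <- fn(trial)
      n_eval <- n_eval + 1L
      if (ft <= fv[i]) {
        pop[i, ] <- trial
        fv[i] <- ft
      }
    }
    trace[iter] <- min(fv)
    iter_done <- iter
    if (max(fv) - min(fv) < tol * (abs(min(fv)) + tol)) {
      converged <- TRUE
      break
    }
  }
  # stagnation also counts as convergence: less than 1% improvement of the
  # best value over the final quarter of the run
  if (!converged && iter_done >= 20L) {
    q <- floor(iter_done * 0.75)
    converged <- (trace[q] - trace[iter_done]) <=
      0.01 * (abs(trace[q]) + 1e-12)
  }
  b <- which.min(fv)
  list(par = pop[b, ], value = fv[b], trace = trace[seq_len(iter_done)],
       converged = converged, iterations = iter_done, n_eval = n_eval)
}
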