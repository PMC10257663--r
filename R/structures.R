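#' Chain layout of the two-phase cell-cycle model
#'
#' Defines how the G1 and S-G2 phases are partitioned into parts (each part
#' carrying its own progression and death rate) and how many identical
#' subphases make up each part. With the defaults, G1 has 4 parts of 2
#' subphases (8 chain states) and S-G2 has 4 parts of 5 subphases (20 chain
#' states), so that death-free phase durations are Erlang with shapes 8 and 20.
#'
#' @param g1_parts number of G1 parts (default 4)
#' @param g1_subphases_per_part subphases per G1 part (default 2)
#' @param sg2_parts number of S-G2 parts (default 4)
#' @param sg2_subphases_per_part subphases per S-G2 part (default 5)
#' @return an object of class \code{phase_structure}
#' @export
phase_structure <- function(g1_parts = 4L, g1_subphases_per_part = 2L,
                            sg2_parts = 4L, sg2_subphases_per_part = 5L) {
  vals <- c(g1_parts = g1_parts, g1_subphases_per_part = g1_subphases_per_part,
            sg2_parts = sg2_parts, sg2_subphases_per_part = sg2_subphases_per_part)
  if (any(!is.finite(vals)) || any(vals < 1) || any(vals != round(vals)))
    stop("all phase_structure counts must be integers >= 1")
  out <- list(
    g1_parts = as.integer(g1_parts),
    g1_subphases_per_part = as.integer(g1_subphases_per_part),
    sg2_parts = as.integer(sg2_parts),
    sg2_subphases_per_part = as.integer(sg2_subphases_per_part)
  )
  out$n_g1 <- out$g1_parts * out$g1_subphases_per_part
  out$n_sg2 <- out$sg2_parts * out$sg2_subphases_per_part
  out$n_total <- out$n_g1 + out$n_sg2
  class(out) <- "phase_structure"
  out
}

#' @export
print.phase_structure <- function(x, ...) {
  cat(sprintf("phase_structure: G1 = %d parts x %d subphases (%d states), S-G2 = %d parts x %d subphases (%d states)\n",
              x$g1_parts, x$g1_subphases_per_part, x$n_g1,
              x$sg2_parts, x$sg2_subphases_per_part, x$n_sg2))
  invisible(x)
}

#' Per-part progression and death rates at one condition
#'
#' Holds the per-part G1 progression rates (alpha), S-G2 progression rates
#' (beta), and the per-part death rates in G1 (gamma1) and S-G2 (gamma2), all
#' in 1/hour. Scalars are recycled across parts.
#'
#' @param alpha G1 progression rates, one per G1 part (1/hour)
#' @param beta S-G2 progression rates, one per S-G2 part (1/hour)
#' @param gamma1 G1 death rates per part (1/hour), default 0
#' @param gamma2 S-G2 death rates per part (1/hour), default 0
#' @param structure a \code{\link{phase_structure}}
#' @return an object of class \code{rate_set}
#' @export
rate_set <- function(alpha, beta, gamma1 = 0, gamma2 = 0,
                     structure = phase_structure()) {
  stopifnot(inherits(structure, "phase_structure"))
  expand <- function(x, n, nm) {
    if (length(x) == 1L) x <- rep(x, n)
    if (length(x) != n)
      stop(sprintf("%s must have length 1 or %d, got %d", nm, n, length(x)))
    if (any(!is.finite(x)))
      stop(sprintf("%s contains non-finite values", nm))
    if (any(x < 0))
      stop(sprintf("negative rate in %s: rates must be >= 0", nm))
    as.numeric(x)
  }
  out <- list(
    alpha = expand(alpha, structure$g1_parts, "alpha"),
    beta = expand(beta, structure$sg2_parts, "beta"),
    gamma1 = expand(gamma1, structure$g1_parts, "gamma1"),
    gamma2 = expand(gamma2, structure$sg2_parts, "gamma2"),
    structure = structure
  )
  class(out) <- "rate_set"
  out
}

#' @export
print.rate_set <- function(x, ...) {
  cat("rate_set (1/hour):\n")
  cat("  alpha :", signif(x$alpha, 4), "\n")
  cat("  beta  :", signif(x$beta, 4), "\n")
  cat("  gamma1:", signif(x$gamma1, 4), "\n")
  cat("  gamma2:", signif(x$gamma2, 4), "\n")
  invisible(x)
}

# per-subphase progression and death rate vectors (length n_total)
subphase_rates <- function(rates) {
  s <- rates$structure
  part_g1 <- rep(seq_len(s$g1_parts), each = s$g1_subphases_per_part)
  part_sg2 <- rep(seq_len(s$sg2_parts), each = s$sg2_subphases_per_part)
  list(prog = c(rates$alpha[part_g1], rates$beta[part_sg2]),
       death = c(rates$gamma1[part_g1], rates$gamma2[part_sg2]))
}
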