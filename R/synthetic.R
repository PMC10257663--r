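#' Stochastic single-cell branching-process simulation
#'
#' Simulates individual cells traversing the subphase chain. Within each
#' subphase a cell draws an exponential dwell time at the combined rate
#' (part progression + part death) and dies there with probability
#' death / (progression + death) -- the exact competing-risk counterpart of
#' the mean-field equations, so ensemble averages converge to
#' \code{\link{simulate_mean_field}}. Exit from the last S-G2 subphase is a
#' division spawning two G1 daughters. Lineages are censored at \code{t_max}.
#'
#' To bound runtime the population is capped: a newborn generation larger
#' than \code{max_cells} is uniformly subsampled down to it and the kept
#' cells carry a compensating statistical weight, so weighted population
#' counts remain unbiased (attribute \code{"capped"} flags this).
#'
#' @param rates a \code{\link{rate_set}}
#' @param n0 number of starting cells
#' @param initial_g1_fraction probability a starting cell is in G1
#' @param t_max observation horizon in hours
#' @param seed RNG seed (set for reproducibility; \code{NULL} leaves the RNG
#'   state untouched)
#' @param init_spread subphase assignment of starting cells, as in
#'   \code{\link{simulate_mean_field}}
#' @param max_cells population cap (default 50000)
#' @return a data frame of class \code{cell_records} with one row per cell:
#'   \code{cell_id}, \code{parent_id}, \code{birth_time}, \code{g1s_time}
#'   (G1-to-S transition, NA if not observed), \code{end_time}, \code{fate}
#'   (divided / died_g1 / died_sg2 / censored), \code{phase_at_end},
#'   \code{birth_phase}, \code{weight}
#' @export
simulate_cells <- function(rates, n0, initial_g1_fraction = 0.75, t_max = 96,
                           seed = NULL,
                           init_spread = c("uniform", "first_subphase", "stationary"),
                           max_cells = 50000L) {
  init_spread <- match.arg(init_spread)
  if (!is.numeric(n0) || n0 < 1) stop("n0 must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  structure_ <- rates$structure
  n1 <- structure_$n_g1
  ntot <- structure_$n_total
  sr <- subphase_rates(rates)
  p0 <- initial_state(structure_, initial_g1_fraction, init_spread, rates = rates)
  start_sub <- sample.int(ntot, n0, replace = TRUE, prob = p0)

  wave <- data.frame(id = seq_len(n0), parent = NA_integer_, birth = 0,
                     start_sub = start_sub, weight = 1)
  next_id <- n0 + 1L
  capped <- FALSE
  recs <- list()
  n_recorded <- 0L

  while (nrow(wave) > 0L) {
    m <- nrow(wave)
    elapsed <- numeric(m)
    dead <- logical(m)
    death_sub <- rep(NA_integer_, m)
    death_elapsed <- rep(NA_real_, m)
    g1s_elapsed <- rep(NA_real_, m)
    for (s in seq_len(ntot)) {
      idx <- which(wave$start_sub <= s & !dead)
      if (length(idx) == 0L) next
      rt <- sr$prog[s] + sr$death[s]
      if (rt <= 0) {
        elapsed[idx] <- Inf
        next
      }
      elapsed[idx] <- elapsed[idx] + stats::rexp(length(idx), rt)
      if (sr$death[s] > 0) {
        died_now <- stats::runif(length(idx)) < sr$death[s] / rt
        di <- idx[died_now]
        dead[di] <- TRUE
        death_sub[di] <- s
        death_elapsed[di] <- elapsed[di]
      }
      if (s == n1) {
        ok <- idx[!dead[idx] & wave$start_sub[idx] <= n1]
        g1s_elapsed[ok] <- elapsed[ok]
      }
    }
    end_raw <- wave$birth + ifelse(dead, death_elapsed, elapsed)
    g1s_raw <- wave$birth + g1s_elapsed

    fate <- rep("censored", m)
    observed <- end_raw <= t_max
    fate[dead & observed & death_sub <= n1] <- "died_g1"
    fate[dead & observed & death_sub > n1] <- "died_sg2"
    fate[!dead & observed] <- "divided"
    end_time <- ifelse(observed, end_raw, t_max)
    g1s_time <- ifelse(!is.na(g1s_raw) & g1s_raw <= end_time, g1s_raw, NA_real_)
    birth_phase <- ifelse(wave$start_sub <= n1, "G1", "SG2")
    phase_at_end <- ifelse(fate == "died_g1", "G1",
                    ifelse(fate %in% c("died_sg2", "divided"), "SG2",
                    ifelse(is.na(g1s_time) & birth_phase == "G1", "G1", "SG2")))

    recs[[length(recs) + 1L]] <- data.frame(
      cell_id = wave$id, parent_id = wave$parent, birth_time = wave$birth,
      g1s_time = g1s_time, end_time = end_time, fate = fate,
      phase_at_end = phase_at_end, birth_phase = birth_phase,
      weight = wave$weight
    )
    n_recorded <- n_recorded + m

    div <- which(fate == "divided" & end_raw < t_max)
    if (length(div) == 0L) break
    kb <- rep(div, each = 2L)
    kids <- data.frame(id = seq.int(next_id, length.out = 2L * length(div)),
                       parent = wave$id[kb], birth = end_raw[kb],
                       start_sub = 1L, weight = wave$weight[kb])
    next_id <- next_id + nrow(kids)
    if (nrow(kids) > max_cells) {
      keep <- sort(sample.int(nrow(kids), max_cells))
      inflate <- nrow(kids) / max_cells
      kids <- kids[keep, , drop = FALSE]
      kids$weight <- kids$weight * inflate
      capped <- TRUE
    }
    wave <- kids
  }

  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  class(out) <- c("cell_records", "data.frame")
  attr(out, "rates") <- rates
  attr(out, "t_max") <- t_max
  attr(out, "n0") <- n0
  attr(out, "seed") <- seed
  attr(out, "capped") <- capped
  out
}

# weighted cumulative count of events at or before each grid time
wcount <- function(event_times, w, grid) {
  keep <- !is.na(event_times)
  et <- event_times[keep]; w <- w[keep]
  if (length(et) == 0L) return(numeric(length(grid)))
  o <- order(et)
  cw <- cumsum(w[o])
  i <- findInterval(grid, et[o])
  c(0, cw)[i + 1L]
}

#' Bin a lineage table into population counts on a time grid
#'
#' Counts cells present in G1 and S-G2 at each grid time (weighted if the
#' simulation was capped), plus cumulative deaths per phase.
#'
#' @param records a \code{\link{simulate_cells}} result
#' @param times time grid (hours); must not extend past the record horizon
#' @return data frame with columns \code{time_h}, \code{g1}, \code{sg2},
#'   \code{total}, \code{dead_g1}, \code{dead_sg2}, \code{dead_cum}
#' @export
bin_population <- function(records, times = seq(0, attr(records, "t_max"), by = 0.5)) {
  stopifnot(inherits(records, "cell_records"))
  if (max(times) > attr(records, "t_max") + 1e-9)
    stop("time grid extends past the simulated horizon")
  r <- records
  in_g1 <- r$birth_phase == "G1"
  # G1 residence: entry at birth, exit at G1->S or death in G1; censored-in-G1 never exits
  g1_exit <- ifelse(!is.na(r$g1s_time), r$g1s_time,
                    ifelse(r$fate == "died_g1", r$end_time, NA_real_))
  g1 <- wcount(ifelse(in_g1, r$birth_time, NA_real_), r$weight, times) -
        wcount(ifelse(in_g1, g1_exit, NA_real_), r$weight, times)
  # S-G2 residence: entry at G1->S (or birth for cells born there), exit at division/death
  sg2_entry <- ifelse(in_g1, r$g1s_time, r$birth_time)
  sg2_exit <- ifelse(r$fate %in% c("divided", "died_sg2"), r$end_time, NA_real_)
  sg2 <- wcount(sg2_entry, r$weight, times) - wcount(sg2_exit, r$weight, times)
  dead_g1 <- wcount(ifelse(r$fate == "died_g1", r$end_time, NA_real_), r$weight, times)
  dead_sg2 <- wcount(ifelse(r$fate == "died_sg2", r$end_time, NA_real_), r$weight, times)
  data.frame(time_h = times, g1 = g1, sg2 = sg2, total = g1 + sg2,
             dead_g1 = dead_g1, dead_sg2 = dead_sg2, dead_cum = dead_g1 + dead_sg2)
}

#' Sample completed phase durations directly
#'
#' Draws phase transit times from the subphase chain (sum of exponential
#' dwells, with death competing in each subphase). Only durations of cells
#' that complete the phase are returned; with zero death and equal part rates
#' these are exactly Erlang distributed.
#'
#' @param rates a \code{\link{rate_set}}
#' @param n number of cells to start the phase
#' @param phase \code{"G1"} or \code{"SG2"}
#' @param seed optional RNG seed
#' @return numeric vector of completed durations (hours), length <= n
#' @export
sample_phase_durations <- function(rates, n, phase = c("G1", "SG2"), seed = NULL) {
  phase <- match.arg(phase)
  if (!is.null(seed)) set.seed(seed)
  s <- rates$structure
  if (phase == "G1") {
    prog <- rep(rates$alpha, each = s$g1_subphases_per_part)
    death <- rep(rates$gamma1, each = s$g1_subphases_per_part)
  } else {
    prog <- rep(rates$beta, each = s$sg2_subphases_per_part)
    death <- rep(rates$gamma2, each = s$sg2_subphases_per_part)
  }
  if (any(prog <= 0)) stop("progression rates must be > 0 to sample durations")
  dur <- numeric(n)
  alive <- rep(TRUE, n)
  for (j in seq_along(prog)) {
    rt <- prog[j] + death[j]
    idx <- which(alive)
    dur[idx] <- dur[idx] + stats::rexp(length(idx), rt)
    if (death[j] > 0)
      alive[idx[stats::runif(length(idx)) < death[j] / rt]] <- FALSE
  }
  dur[alive]
}

#' Sample paired (G1, S-G2) durations of single cells
#'
#' Durations of the two phases are drawn independently, mirroring the model
#' assumption that G1 and S-G2 are independently regulated.
#'
#' @param rates a \code{\link{rate_set}} (death ignored: complete cycles only)
#' @param n number of cells
#' @param seed optional RNG seed
#' @return data frame with columns \code{g1} and \code{sg2} (hours)
#' @export
sample_cycle_durations <- function(rates, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nodeath <- rate_set(rates$alpha, rates$beta, 0, 0, rates$structure)
  data.frame(g1 = sample_phase_durations(nodeath, n, "G1"),
             sg2 = sample_phase_durations(nodeath, n, "SG2"))
}

#' Generate a synthetic multi-dose, multi-replicate dataset
#'
#' Emulates the live-imaging assay design: populations followed on a fixed
#' cadence over the assay window across a dose series, in replicate. Counts
#' receive multiplicative lognormal noise with coefficient of variation
#' \code{noise_cv}; the G1 fraction receives binomial sampling noise; counts
#' are then normalized to the mean of the first three timepoints.
#' \code{method = "mean_field"} replaces the agent-based simulation by the
#' exact expectation (the noiseless, infinite-population limit).
#'
#' @param profile a \code{\link{drug_response_profile}}
#' @param concentrations dose series in nM (include 0 for the control arm)
#' @param replicates replicates per dose (default 3)
#' @param cadence sampling interval in hours (default 0.5)
#' @param t_max assay length in hours (default 96)
#' @param n0 starting cells per replicate (default 500)
#' @param noise_cv coefficient of variation of count noise (default 0.05)
#' @param seed RNG seed (recorded in metadata)
#' @param initial_g1_fraction starting G1 fraction (default 0.75)
#' @param method \code{"agent"} (stochastic single cells) or
#'   \code{"mean_field"} (exact expectation)
#' @param keep_lineage also return the lineage tables (agent method only)
#' @return an object of class \code{synthetic_dataset}: list with
#'   \code{population} (tidy data frame: drug, concentration, replicate,
#'   time_h, count_norm, frac_g1), optional \code{lineage} (named list of
#'   \code{cell_records}), and \code{metadata} (seed, truth, noise model)
#' @export
generate_dose_response_dataset <- function(profile, concentrations,
                                           replicates = 3, cadence = 0.5,
                                           t_max = 96, n0 = 500,
                                           noise_cv = 0.05, seed = 1,
                                           initial_g1_fraction = 0.75,
                                           method = c("agent", "mean_field"),
                                           keep_lineage = FALSE) {
  method <- match.arg(method)
  if (replicates < 1) stop("replicates must be >= 1")
  if (method == "agent" && n0 < 100)
    warning("n0 < 100 gives unstable G1 fractions; consider a larger population")
  set.seed(seed)
  times <- seq(0, t_max, by = cadence)
  sdlog <- sqrt(log(1 + noise_cv^2))
  rows <- list()
  lineage <- list()
  for (conc in concentrations) {
    rates <- rates_at_concentration(profile, conc)
    mf <- NULL
    if (method == "mean_field")
      mf <- simulate_mean_field(rates, initial_g1_fraction, times)
    for (rep_i in seq_len(replicates)) {
      if (method == "agent") {
        rec <- simulate_cells(rates, n0 = n0,
                              initial_g1_fraction = initial_g1_fraction,
                              t_max = t_max)
        pop <- bin_population(rec, times)
        if (keep_lineage)
          lineage[[sprintf("%s_%g_r%d", profile$drug_name, conc, rep_i)]] <- rec
        count <- pop$total
        frac <- ifelse(pop$total > 0, pop$g1 / pop$total, NA_real_)
      } else {
        count <- mf$total * n0
        frac <- ifelse(mf$total > 0, mf$g1 / mf$total, NA_real_)
      }
      if (noise_cv > 0) {
        count <- count * stats::rlnorm(length(count), -sdlog^2 / 2, sdlog)
        ntrial <- pmax(1L, round(count))
        frac <- stats::rbinom(length(frac), ntrial, pmin(pmax(frac, 0), 1)) / ntrial
      }
      rows[[length(rows) + 1L]] <- data.frame(
        drug = profile$drug_name, concentration = conc, replicate = rep_i,
        time_h = times,
        count_norm = count / mean(count[seq_len(min(3L, length(count)))]),
        frac_g1 = frac
      )
    }
  }
  out <- list(population = do.call(rbind, rows),
              lineage = if (keep_lineage) lineage else NULL,
              metadata = list(seed = seed, profile = profile,
                              concentrations = concentrations,
                              replicates = replicates, cadence = cadence,
                              t_max = t_max, n0 = n0, noise_cv = noise_cv,
                              initial_g1_fraction = initial_g1_fraction,
                              method = method,
                              noise_model = "lognormal counts, binomial G1 fraction"))
  class(out) <- "synthetic_dataset"
  out
}

#' Summarize cell fates in a lineage table
#'
#' Fractions of the starting cells that divided, died or were censored; the
#' fraction of their daughters that divided again; and the relative death
#' count (cumulative deaths divided by the starting cell number, the
#' model-free measure of cytotoxicity).
#'
#' @param records a \code{\link{simulate_cells}} result
#' @return list with \code{n_initial}, \code{divided_frac}, \code{died_frac},
#'   \code{censored_frac}, \code{second_division_frac},
#'   \code{relative_deaths}, \code{relative_deaths_g1},
#'   \code{relative_deaths_sg2}
#' @export
fate_summary <- function(records) {
  stopifnot(inherits(records, "cell_records"))
  if (nrow(records) == 0L) stop("empty lineage table")
  init <- records[is.na(records$parent_id), , drop = FALSE]
  n_init <- nrow(init)
  first_div <- init$cell_id[init$fate == "divided"]
  kids <- records[!is.na(records$parent_id) & records$parent_id %in% first_div, , drop = FALSE]
  died <- records$fate %in% c("died_g1", "died_sg2")
  list(
    n_initial = n_init,
    divided_frac = mean(init$fate == "divided"),
    died_frac = mean(init$fate %in% c("died_g1", "died_sg2")),
    censored_frac = mean(init$fate == "censored"),
    second_division_frac = if (nrow(kids)) mean(kids$fate == "divided") else NA_real_,
    relative_deaths = sum(records$weight[died]) / n_init,
    relative_deaths_g1 = sum(records$weight[records$fate == "died_g1"]) / n_init,
    relative_deaths_sg2 = sum(records$weight[records$fate == "died_sg2"]) / n_init
  )
}
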