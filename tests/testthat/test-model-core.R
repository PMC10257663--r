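test_that("generator has the chain dimensions and conserves mass appropriately", {
  A <- build_generator(fx$control)
  expect_equal(dim(A), c(28L, 28L))
  expect_equal(dim(build_generator(fx$control, include_dead_compartments = TRUE)),
               c(30L, 30L))

  # closed loop: no death, one offspring per division -> columns sum to zero
  r <- rate_set(0.4, 1.0)
  A1 <- build_generator(r, division_factor = 1)
  expect_equal(max(abs(colSums(A1))), 0)

  # two offspring: net creation of beta_4 at the final S-G2 subphase only
  A2 <- build_generator(r, division_factor = 2)
  cs <- colSums(A2)
  expect_equal(cs[28], 1.0)
  expect_equal(max(abs(cs[-28])), 0)

  # with dead compartments every column of the augmented system sums to
  # zero except the division column (deaths are rerouted, not lost)
  rd <- hetero_rates()
  Ad <- build_generator(rd, division_factor = 1, include_dead_compartments = TRUE)
  expect_equal(max(abs(colSums(Ad)[1:28])), 0)
})

test_that("invalid rates and structures are rejected with informative errors", {
  expect_error(rate_set(-0.1, 1), "alpha")
  expect_error(rate_set(0.4, 1, gamma2 = c(0, 0, -1, 0)), "gamma2")
  expect_error(rate_set(c(0.4, 0.4), 1), "length")
  expect_error(phase_structure(g1_parts = 0), "integers")
  s2 <- phase_structure(2, 2, 2, 2)
  expect_error(build_generator(rate_set(0.4, 1), structure = s2), "structure")
})

test_that("null and pure-death dynamics match closed forms", {
  r0 <- rate_set(0, 0, 0, 0)
  tr <- simulate_mean_field(r0, 0.6)
  expect_equal(tr$total, rep(1, nrow(tr)), tolerance = 1e-12)
  expect_equal(max(tr$dead_cum), 0)

  gam <- 0.1
  rd <- rate_set(0, 0, gam, gam)
  trd <- simulate_mean_field(rd, 0.75)
  expect_lt(max(abs(trd$total - exp(-gam * trd$time_h))), 1e-6)
  expect_lt(max(abs(trd$dead_cum - (1 - exp(-gam * trd$time_h)))), 1e-6)
})

test_that("trajectory invariants hold for a heterogeneous rate set", {
  tr <- simulate_mean_field(hetero_rates(), 0.7)
  expect_equal(tr$total, tr$g1 + tr$sg2)
  expect_true(all(diff(tr$dead_cum) >= -1e-12))
  expect_true(all(tr$g1 >= 0 & tr$sg2 >= 0 & tr$dead_cum >= 0))
  expect_equal(tr$total[1], 1)
})

test_that("propagation over k fine steps equals one coarse step", {
  r <- hetero_rates()
  fine <- simulate_mean_field(r, 0.75, times = seq(0, 96, by = 0.5))
  coarse <- simulate_mean_field(r, 0.75, times = seq(0, 96, by = 4))
  idx <- match(coarse$time_h, fine$time_h)
  expect_equal(coarse$total, fine$total[idx], tolerance = 1e-8)
  expect_equal(coarse$dead_cum, fine$dead_cum[idx], tolerance = 1e-8)
})

test_that("input contracts of simulate_mean_field are enforced", {
  r <- rate_set(0.4, 1)
  expect_error(simulate_mean_field(r, 1.2), "initial_g1_fraction")
  expect_error(simulate_mean_field(r, 0.5, times = c(0, 1, 3)), "non-uniform")
  expect_error(simulate_mean_field(r, 0.5, times = 5), "2 points")
})

test_that("initial spread options agree on the starting split", {
  r <- fx$control
  for (sp in c("uniform", "first_subphase", "stationary")) {
    tr <- simulate_mean_field(r, 0.75, init_spread = sp)
    expect_equal(tr$g1[1], 0.75)
    expect_equal(tr$sg2[1], 0.25)
  }
})

test_that("average phase durations evaluate the per-part Erlang means", {
  expect_equal(unname(average_phase_durations(rate_set(0.4, 1.0))),
               c(4 * 2 / 0.4, 4 * 5 / 1.0))
  r <- rate_set(c(0.2, 0.4, 0.8, 0.4), 1.0)
  expect_equal(unname(average_phase_durations(r)["g1"]),
               2 / 0.2 + 2 / 0.4 + 2 / 0.8 + 2 / 0.4)
  expect_error(average_phase_durations(rate_set(0, 1)), "infinite")
})

test_that("mean duration matches death-free simulated durations", {
  r <- rate_set(c(0.2, 0.4, 0.8, 0.4), 1.0)
  d <- sample_phase_durations(r, 10000, "G1", seed = 21)
  expect_equal(mean(d), unname(average_phase_durations(r)["g1"]), tolerance = 0.02)
})

test_that("discrete-sum dead accounting converges to the absorbing compartments", {
  r <- hetero_rates()
  tr <- simulate_mean_field(r, 0.75, keep_subphases = TRUE)
  nt <- accumulate_dead(tr, weight = "dt")
  expect_lt(max(abs(nt - tr$dead_cum)), 0.01 * max(tr$dead_cum))
  # unweighted (printed) form differs by a 1/dt scale
  raw <- accumulate_dead(tr, weight = "none")
  expect_gt(max(raw), max(nt))
  # no per-subphase resolution -> rejected
  tr2 <- simulate_mean_field(r, 0.75)
  expect_error(accumulate_dead(tr2), "per-subphase")
  # zero death: identically zero
  tr0 <- simulate_mean_field(rate_set(0.4, 1), 0.75, keep_subphases = TRUE)
  expect_equal(max(accumulate_dead(tr0)), 0)
})

test_that("pure-death discrete-sum accumulation is within 1% of the closed form", {
  r <- rate_set(0, 0, 0.1, 0.1)
  tr <- simulate_mean_field(r, 0.75, keep_subphases = TRUE)
  N <- accumulate_dead(tr, weight = "dt")
  expect_lt(abs(N[length(N)] / (1 - exp(-9.6)) - 1), 0.01)
})

test_that("exponential baseline is the two-state linear system", {
  tr0 <- simulate_exponential_baseline(0, 0, 0, 0, 0.6)
  expect_equal(tr0$total, rep(1, nrow(tr0)), tolerance = 1e-12)

  # long-run growth at the dominant eigenvalue of the 2x2 generator
  a <- 0.05
  A <- matrix(c(-a, a, 2 * a, -a), 2, 2)
  lam <- max(Re(eigen(A)$values))
  tr <- simulate_exponential_baseline(a, a, 0, 0, 0.75,
                                      times = seq(0, 400, by = 0.5))
  n <- nrow(tr)
  slope <- (log(tr$total[n]) - log(tr$total[n - 100])) / (0.5 * 100)
  expect_equal(slope, lam, tolerance = 1e-4)

  # no sustained oscillation: the detrended G1 fraction amplitude decays
  pct <- tr$g1 / tr$total
  early <- max(abs(pct[tr$time_h <= 100] - pct[n]))
  late <- max(abs(pct[tr$time_h >= 300] - pct[n]))
  expect_lt(late, early / 10)
})

test_that("the gamma1-in-SG2-loss variant alters the two-state dynamics", {
  default <- simulate_exponential_baseline(0.3, 0.4, 0.02, 0.1, 0.75)
  strict <- simulate_exponential_baseline(0.3, 0.4, 0.02, 0.1, 0.75,
                                          sg2_loss_uses_gamma1 = TRUE)
  expect_gt(max(abs(default$total - strict$total)), 1e-6)
  # identical when the two death rates coincide
  d2 <- simulate_exponential_baseline(0.3, 0.4, 0.05, 0.05, 0.75)
  s2 <- simulate_exponential_baseline(0.3, 0.4, 0.05, 0.05, 0.75,
                                      sg2_loss_uses_gamma1 = TRUE)
  expect_equal(d2$total, s2$total)
})
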