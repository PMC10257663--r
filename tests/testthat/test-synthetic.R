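test_that("the simulator is byte-identical under a fixed seed", {
  r <- hetero_rates()
  a <- simulate_cells(r, n0 = 200, t_max = 48, seed = 9)
  b <- simulate_cells(r, n0 = 200, t_max = 48, seed = 9)
  expect_identical(as.data.frame(a), as.data.frame(b))

  da <- generate_dose_response_dataset(fx$g1_blocker, c(0, 50), replicates = 2,
                                       n0 = 150, t_max = 24, seed = 3)
  db <- generate_dose_response_dataset(fx$g1_blocker, c(0, 50), replicates = 2,
                                       n0 = 150, t_max = 24, seed = 3)
  expect_identical(da$population, db$population)
})

test_that("lineage records respect their structural invariants", {
  rec <- simulate_cells(hetero_rates(), n0 = 300, t_max = 72, seed = 14)
  with_g1s <- !is.na(rec$g1s_time)
  expect_true(all(rec$g1s_time[with_g1s] >= rec$birth_time[with_g1s]))
  expect_true(all(rec$g1s_time[with_g1s] <= rec$end_time[with_g1s]))
  expect_true(all(rec$end_time <= 72 + 1e-9))
  expect_true(all(rec$end_time[rec$fate == "censored"] == 72))
  # divided cells have exactly two recorded children (unless capped)
  kids <- table(rec$parent_id[!is.na(rec$parent_id)])
  expect_true(all(kids == 2L))
  div_interior <- rec$cell_id[rec$fate == "divided" & rec$end_time < 72]
  expect_true(all(div_interior %in% as.integer(names(kids))))
})

test_that("overwhelming death hazards kill every cell before division", {
  r <- rate_set(0.4, 1.0, gamma1 = 400, gamma2 = 1000)
  rec <- simulate_cells(r, n0 = 400, t_max = 96, seed = 5)
  expect_equal(sum(rec$fate == "divided"), 0)
  expect_gt(mean(rec$fate %in% c("died_g1", "died_sg2")), 0.999)
})

test_that("death-free equal-rate G1 durations are Erlang(8)", {
  alpha <- 8 / 22.3
  d <- sample_phase_durations(rate_set(alpha, 1.0), 5000, "G1", seed = 8)
  expect_equal(length(d), 5000L)
  ks <- suppressWarnings(stats::ks.test(d, stats::pgamma, shape = 8, rate = alpha))
  expect_gt(ks$p.value, 0.01)
})

test_that("paired G1 and S-G2 durations are uncorrelated by construction", {
  pairs <- sample_cycle_durations(fx$control, 1000, seed = 31)
  r <- phase_correlation(pairs$g1, pairs$sg2)
  expect_lt(abs(r$r), 0.1)
  expect_equal(r$n, 1000L)
})

test_that("ensemble means track the mean-field solution", {
  r <- hetero_rates()
  set.seed(77)
  em <- ensemble_mean(r, runs = 25, n0 = 250)
  mf <- simulate_mean_field(r, 0.75)
  target <- cbind(mf$g1, mf$sg2, mf$dead_cum)
  d <- abs(em$mean - target)
  z <- d / pmax(em$se, 1e-12)
  z[d < 1e-12] <- 0
  # pointwise 3-sigma band with a small allowance for the expected extreme
  # over ~580 correlated comparisons
  expect_lt(mean(z > 3), 0.02)
  expect_lt(max(z), 5)
})

test_that("noiseless replicate-averaged datasets match the mean-field model", {
  ds <- generate_dose_response_dataset(fx$g1_blocker, 50, replicates = 3,
                                       n0 = 5000, noise_cv = 0, seed = 5)
  pop <- ds$population
  avg_count <- tapply(pop$count_norm, pop$time_h, mean)
  avg_frac <- tapply(pop$frac_g1, pop$time_h, mean)
  mf <- simulate_mean_field(rates_at_concentration(fx$g1_blocker, 50), 0.75)
  expect_lt(max(abs(avg_count / (mf$total / mean(mf$total[1:3])) - 1)), 0.02)
  expect_lt(max(abs(avg_frac - mf$g1 / mf$total)), 0.02)
})

test_that("normalization makes the early counts start near one", {
  ds <- generate_dose_response_dataset(fx$g1_blocker, c(0, 400), replicates = 2,
                                       n0 = 400, t_max = 48, noise_cv = 0.05,
                                       seed = 12)
  first <- ds$population$count_norm[ds$population$time_h == 0]
  expect_true(all(abs(first - 1) < 0.2))
  # the mean of the first three points is exactly 1 by construction
  f3 <- subset(ds$population, time_h <= 1 & replicate == 1 & concentration == 0)
  expect_equal(mean(f3$count_norm), 1)
})

test_that("cytostatic and cytotoxic profiles separate on final counts", {
  times <- seq(0, 96, 0.5)
  block <- simulate_mean_field(rates_at_concentration(fx$g1_blocker, 2000), 0.75, times)
  expect_gte(tail(block$total, 1), 1)
  # plateau: negligible late growth
  expect_lt(abs(block$total[193] - block$total[145]) / block$total[193], 0.05)
  kill <- simulate_mean_field(rates_at_concentration(fx$s_phase_drug, 30), 0.75, times)
  expect_lt(tail(kill$total, 1), 1)
})

test_that("fate summaries match mean-field death accounting", {
  r <- rate_set(8 / 22.3, 20 / 22.3, gamma1 = 0.01, gamma2 = 0.02)
  rec <- simulate_cells(r, n0 = 4000, t_max = 96, seed = 20)
  fs <- fate_summary(rec)
  mf <- simulate_mean_field(r, 0.75)
  expect_equal(fs$relative_deaths, tail(mf$dead_cum, 1), tolerance = 0.1)
  expect_equal(fs$relative_deaths_g1, tail(mf$dead_g1, 1), tolerance = 0.15)

  # death-free, long horizon: essentially all starting cells divide
  rec0 <- simulate_cells(rate_set(0.5, 1.2), n0 = 500, t_max = 96, seed = 2)
  expect_gt(fate_summary(rec0)$divided_frac, 0.99)

  # pure death: every cell dies, one death per starting cell
  recd <- simulate_cells(rate_set(1e-6, 1e-6, 0.3, 0.3), n0 = 500,
                         t_max = 96, seed = 4)
  expect_equal(fate_summary(recd)$relative_deaths, 1, tolerance = 0.01)
  expect_error(fate_summary(rec[0, ]), "empty")
})

test_that("the population cap subsamples with compensating weights", {
  rec <- simulate_cells(fx$control, n0 = 500, t_max = 96, seed = 6,
                        max_cells = 800)
  expect_true(attr(rec, "capped"))
  expect_gt(max(rec$weight), 1)
  pop <- bin_population(rec)
  mf <- simulate_mean_field(fx$control, 0.75)
  # weighted counts still estimate the expectation, within loose MC error
  expect_equal(tail(pop$total, 1) / 500, tail(mf$total, 1), tolerance = 0.25)
})
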