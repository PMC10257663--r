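test_that("the DE optimizer minimizes a smooth bowl deterministically", {
  sphere <- function(x) sum((x - c(1, -2, 0.5))^2)
  a <- de_optimize(sphere, rep(-5, 3), rep(5, 3), n_pop = 20, max_iter = 80, seed = 1)
  b <- de_optimize(sphere, rep(-5, 3), rep(5, 3), n_pop = 20, max_iter = 80, seed = 1)
  expect_identical(a$par, b$par)
  expect_lt(a$value, 1e-6)
  # a supplied start at the optimum is never lost (greedy selection)
  c <- de_optimize(sphere, rep(-5, 3), rep(5, 3), n_pop = 15, max_iter = 5,
                   seed = 2, init = matrix(c(1, -2, 0.5), nrow = 1))
  expect_lte(c$value, 1e-12)
})

make_small_problem <- function(doses = c(0, 12.5, 50, 200), seed = 1) {
  ds <- generate_dose_response_dataset(fx$g1_blocker, doses, replicates = 1,
                                       noise_cv = 0, seed = seed,
                                       method = "mean_field")
  proc <- process_population(ds$population, window = 1)
  spec <- fit_spec(list(g1_blocker = doses), list(g1_blocker = "alpha"))
  list(proc = proc, spec = spec,
       truth = c(log10(8 / 22.3), log10(20 / 22.3), log10(50), log10(2),
                 log10(0.02 * 8 / 22.3)))
}

test_that("the SSE cost is zero at the generating parameters and positive off them", {
  pb <- make_small_problem()
  blocks <- prepare_fit_data(pb$proc)
  expect_lt(sse_cost(pb$truth, pb$spec, blocks), 1e-6)
  bumped <- pb$truth + c(log10(1.1), 0, 0, 0, 0)
  expect_gt(sse_cost(bumped, pb$spec, blocks), 1e-4)
})

test_that("the cost decomposes additively over drugs and ignores row order", {
  doses <- c(0, 25, 100)
  dsA <- generate_dose_response_dataset(fx$g1_blocker, doses, replicates = 1,
                                        noise_cv = 0, seed = 2, method = "mean_field")
  dsB <- generate_dose_response_dataset(fx$s_phase_drug, c(0, 5, 20), replicates = 1,
                                        noise_cv = 0, seed = 2, method = "mean_field")
  pop <- rbind(dsA$population, dsB$population)
  proc <- process_population(pop, window = 1)
  spec <- fit_spec(list(g1_blocker = doses, s_phase_drug = c(0, 5, 20)),
                   list(g1_blocker = "alpha", s_phase_drug = c("beta", "gamma2")))
  par <- (spec$param_table$lower + spec$param_table$upper) / 2
  blocks <- prepare_fit_data(proc)
  dec <- sse_cost(par, spec, blocks, by_drug = TRUE)
  expect_equal(dec$total, sum(dec$by_drug))
  shuffled <- proc[sample.int(nrow(proc)), ]
  expect_equal(sse_cost(par, spec, prepare_fit_data(shuffled)), dec$total)
})

test_that("parameter packing round-trips through unpack_params", {
  pb <- make_small_problem()
  params <- unpack_params(pb$truth, pb$spec)
  expect_equal(params$control$alpha, rep(8 / 22.3, 4))
  expect_equal(params$control$beta, rep(20 / 22.3, 4))
  expect_equal(params$g1_fraction, 0.75)
  prof <- params$profiles$g1_blocker
  expect_equal(prof$ec50, 50)
  expect_equal(prof$k, 2)
  expect_equal(prof$emax$alpha, rep(0.02 * 8 / 22.3, 4))
  # unaffected families stay at control / zero
  expect_equal(prof$emax$beta, params$control$beta)
  expect_equal(prof$emax$gamma1, rep(0, 4))
  expect_error(unpack_params(pb$truth[-1], pb$spec), "length")
})

test_that("untied specs expose one free value per part", {
  spec <- fit_spec(list(d = c(0, 10)), list(d = "alpha"), tie_parts = FALSE,
                   g1_fraction = "free")
  nm <- spec$param_table$name
  expect_equal(sum(startsWith(nm, "ctrl_alpha_")), 4L)
  expect_true("g1_fraction" %in% nm)
  par <- (spec$param_table$lower + spec$param_table$upper) / 2
  params <- unpack_params(par, spec)
  expect_length(params$profiles$d$emax$alpha, 4L)
  expect_equal(params$g1_fraction, plogis(mean(qlogis(c(0.01, 0.99)))))
})

test_that("short fits are seed-deterministic and stable under restart", {
  pb <- make_small_problem()
  f1 <- fit_model(pb$spec, pb$proc, seed = 3, n_pop = 12, max_iter = 6)
  f2 <- fit_model(pb$spec, pb$proc, seed = 3, n_pop = 12, max_iter = 6)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$sse, f2$sse)
  # refitting from the found optimum cannot increase the cost
  f3 <- fit_model(pb$spec, pb$proc, seed = 4, n_pop = 12, max_iter = 6,
                  init = matrix(unname(f1$par), nrow = 1))
  expect_lte(f3$sse, f1$sse + 1e-12)
})

test_that("sensitivity profiles recover the optimum and flag dead parameters", {
  pb <- make_small_problem()
  # evaluate around the known optimum without a costly global search
  fit <- fit_model(pb$spec, pb$proc, seed = 5, n_pop = 8, max_iter = 2,
                   init = matrix(pb$truth, nrow = 1))
  sens <- sensitivity_profile(fit, pb$proc, factors = c(0.5, 1, 2))
  at1 <- sens$cost[sens$factor == 1]
  expect_equal(at1, rep(fit$sse, nrow(pb$spec$param_table)))
  ident <- attr(sens, "identifiable")
  # every free parameter shapes the noiseless likelihood here
  expect_true(all(ident))

  # a drug present in the spec but absent from the data is unidentifiable
  spec2 <- fit_spec(list(g1_blocker = c(0, 12.5, 50, 200), ghost = c(0, 10)),
                    list(g1_blocker = "alpha", ghost = "alpha"))
  init2 <- matrix(c(pb$truth, log10(10), log10(1), log10(0.1)), nrow = 1)
  fit2 <- fit_model(spec2, pb$proc, seed = 6, n_pop = 8, max_iter = 2, init = init2)
  sens2 <- sensitivity_profile(fit2, pb$proc, factors = c(0.5, 1, 2))
  ident2 <- attr(sens2, "identifiable")
  expect_false(any(ident2[c("ec50_ghost", "k_ghost", "emax_alpha_ghost")]))
})
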