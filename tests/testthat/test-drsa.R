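test_that("exploration probability follows its closed form", {
  expect_equal(p_explore(0, 100, 3), 1.0)
  expect_equal(p_explore(0, 50, 0.7), 1.0)
  expect_equal(p_explore(100, 100, 3), exp(-3))
  ts <- 0:100
  expect_true(all(diff(p_explore(ts, 100, 3)) < 0))
  expect_error(p_explore(1, 0, 3), "t_max")
  expect_error(p_explore(-1, 10, 3), "t out of")
})

test_that("the ES disturbance factor behaves as specified", {
  for (r in c(-1, 0, 1)) expect_equal(es_factor(100, 100, r = r), 0)
  expect_equal(es_factor(0, 100, r = 1), 2.0)
  expect_equal(es_factor(0, 100, r = -1), -2.0)
  expect_equal(es_factor(50, 100, r = 1), 1.0)

  draws <- withr::with_seed(12, replicate(3000, es_factor(0, 100)))
  expect_setequal(unique(draws), c(-2, 0, 2))
  freqs <- table(draws) / 3000
  expect_true(all(abs(freqs - 1 / 3) < 0.03))
})

test_that("behavior updates match hand-substituted values", {
  comp <- drsa_components(best = 1.0, x = 0.6, x_r = 0.5, mean_x = 0.55,
                          lb = 0, ub = 1, alpha = 0.1, epsilon = 1e-10)
  expect_equal(comp$R, 0.5, tolerance = 1e-9)
  expect_equal(comp$P, 0.1 + 0.05, tolerance = 1e-9)
  expect_equal(comp$eta, comp$P)

  expect_equal(
    drsa_behavior_value("belly_walk", best = 1.0, x_r = 0.5, R = 0, P = 0,
                        eta = 0, es = 2.0, u = 0.5), 0.5)
  expect_equal(
    drsa_behavior_value("coord_hunt", best = 0.8, x_r = 0, R = 0, P = 0.5,
                        eta = 0, es = 0, u = 1.0), 0.4)
  expect_equal(
    drsa_behavior_value("high_walk", best = 1.0, x_r = 0.5, R = 0.5, P = 0,
                        eta = 0.05, es = 0, u = 0.5, beta = 0.005),
    1 - 0.05 * 0.005 - 0.25)
  expect_equal(
    drsa_behavior_value("coop_hunt", best = 1.0, x_r = 0.5, R = 0.5, P = 0,
                        eta = 0.05, es = 0, u = 0.5, epsilon = 1e-10),
    1 - 0.05 * 1e-10 - 0.25)
})

test_that("DRSA minimizes the sphere and beats random search", {
  cfg <- drsa_config(seed = 1, lower_bound = -1, upper_bound = 1)
  opt <- run_drsa(function(v) sum(v^2), 5, cfg)
  expect_lt(opt$best_fitness, 1e-2)

  rand_best <- withr::with_seed(1, {
    min(apply(matrix(runif(3000 * 5, -1, 1), ncol = 5), 1,
              function(v) sum(v^2)))
  })
  expect_lt(opt$best_fitness, rand_best)

  # elitism and bound adherence
  expect_true(all(diff(opt$trace) <= 0))
  expect_true(all(opt$best_history >= -1 & opt$best_history <= 1))
  expect_true(all(opt$best_position >= -1 & opt$best_position <= 1))
})

test_that("walking-behavior frequency tracks the exploration schedule", {
  cfg <- drsa_config(seed = 21, t_max = 60, lower_bound = -1, upper_bound = 1)
  opt <- run_drsa(function(v) sum((v - 0.3)^2), 4, cfg)
  pex <- p_explore(seq_len(cfg$t_max), cfg$t_max, cfg$lambda_decay)
  expected <- cfg$pop_size * sum(pex)
  sd_bin <- sqrt(cfg$pop_size * sum(pex * (1 - pex)))
  observed <- sum(opt$behavior_counts[, "walk"])
  expect_lt(abs(observed - expected), 4 * sd_bin)
  expect_identical(rowSums(opt$behavior_counts),
                   rep(as.numeric(cfg$pop_size), cfg$t_max))
})

test_that("non-finite fitness is reported with the offending position", {
  cfg <- drsa_config(seed = 2, t_max = 3)
  expect_error(run_drsa(function(v) NA_real_, 3, cfg), "non-finite fitness")
})

test_that("DRSA-CARS recovers a noiseless planted subset exactly", {
  d <- gen_spectra(planted_band_spec(
    informative_band_indices = c(4L, 9L, 15L), coefficients = c(2, -1.5, 2),
    noise_sd = 0, n_samples = 120, n_bands = 20, seed = 5))
  res <- drsa_cars_select(d$spectra, d$target,
                          drsa_config(seed = 5, parsimony_weight = 0))
  expect_lt(res$best_rmsecv, 1e-4)
  expect_true(all(c(4, 9, 15) %in% res$selected_indices))
})

test_that("DRSA-CARS is deterministic and refine mode stays in its pool", {
  d <- planted_50(seed = 3)
  cars <- run_cars(d$spectra, d$target, n_runs = 60, seed = 3)
  cfg <- drsa_config(seed = 3, t_max = 40)
  r1 <- drsa_cars_select(d$spectra, d$target, cfg, cars_result = cars)
  r2 <- drsa_cars_select(d$spectra, d$target, cfg, cars_result = cars)
  expect_identical(r1$selected_indices, r2$selected_indices)
  expect_identical(r1$rmsecv_trace, r2$rmsecv_trace)
  expect_true(all(r1$selected_indices %in% cars$candidate_union))
  expect_identical(r1$mode, "refine")
  expect_length(r1$rmsecv_trace, cfg$t_max)
  # the returned subset's RMSECV matches the end of the trace
  expect_equal(r1$best_rmsecv, r1$rmsecv_trace[cfg$t_max])
})
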