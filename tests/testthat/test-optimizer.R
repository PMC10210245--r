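# Weight optimization: sampling, recovery, scans, two-step procedure.

test_that("the Monte-Carlo pool is reproducible and simplex-normalized", {
  p1 <- sample_initial_weights(20, 6, seed = 3)
  p2 <- sample_initial_weights(20, 6, seed = 3)
  expect_identical(p1, p2)
  expect_equal(rowSums(p1), rep(1, 20))
  expect_true(all(p1 >= 0))
  expect_equal(sample_initial_weights(5, 1, seed = 1),
               matrix(1, 5, 1))
})

test_that("pool components are symmetric across positions", {
  pool <- sample_initial_weights(1e4, 4, seed = 9)
  means <- colMeans(pool)
  se <- apply(pool, 2, stats::sd) / sqrt(1e4)
  expect_true(all(abs(means - 0.25) < 3 * se))
})

test_that("iterative resampling perturbs the incumbent reproducibly", {
  best <- c(0.7, 0.2, 0.1)
  p0 <- iterative_resampling(best, 6, seed = 4, jitter = 0,
                             frac_perturbed = 1)
  expect_equal(p0, matrix(best, 6, 3, byrow = TRUE))
  pa <- iterative_resampling(best, 8, seed = 4, jitter = 0.05)
  pb <- iterative_resampling(best, 8, seed = 4, jitter = 0.05)
  expect_identical(pa, pb)
  expect_equal(rowSums(pa), rep(1, 8))
})

test_that("noiseless synthetic weights are recovered to 1e-3", {
  fx <- small_fixture(noise_frac = 0)
  pe <- fx$experiment
  cfg <- optimization_config(n_init = 8, seed = 2)
  fit <- optimize_weights(pe$signal, NULL, fx$ensemble, fx$truth$params,
                          pe$reference, cfg, free_gamma = TRUE,
                          bin_width = 50)
  expect_lte(max(abs(fit$best_weights - fx$truth$weights)), 1e-3)
  g <- fit$best_params$gamma
  expect_equal(g, fx$truth$params$gamma, tolerance = 1e-6)
  expect_equal(fit$n_converged, 8L)
  # best F is the minimum over converged initial conditions
  conv <- fit$per_init[fit$per_init$converged, ]
  expect_equal(fit$F, min(conv$F))
})

test_that("optimization is invariant to the scale of an initial vector", {
  fx <- small_fixture(noise_frac = 0)
  pe <- fx$experiment
  cfg <- optimization_config(n_init = 1, seed = 2)
  init <- sample_initial_weights(1, fx$ensemble$n_tbf, seed = 6)
  f1 <- optimize_weights(pe$signal, NULL, fx$ensemble, fx$truth$params,
                         pe$reference, cfg, bin_width = 50, inits = init)
  f2 <- optimize_weights(pe$signal, NULL, fx$ensemble, fx$truth$params,
                         pe$reference, cfg, bin_width = 50,
                         inits = 0.2 * init)
  expect_equal(f1$best_weights, f2$best_weights, tolerance = 1e-9)
})

test_that("an experiment equal to the uniform model is matched at RAE <= 1", {
  fx <- small_fixture(noise_frac = 0)
  ens <- fx$ensemble
  n <- ens$n_tbf
  p <- fx$truth$params
  uni <- forward_model(ens, rep(1 / n, n), p, fx$experiment$reference,
                       fx$experiment$signal$q, fx$experiment$signal$t,
                       bin_width = 50)
  cfg <- optimization_config(n_init = 4, seed = 3)
  # tiny perturbation so the RAE denominator is nonzero
  uni_n <- uni
  set.seed(1)
  uni_n$values <- uni$values + stats::rnorm(length(uni$values), sd = 1e-4)
  fit <- optimize_weights(uni_n, NULL, ens, p, fx$experiment$reference,
                          cfg, bin_width = 50)
  F_uni <- target_function(uni$values, uni_n$values)
  expect_lte(fit$F, F_uni + 1e-12)
  expect_lte(fit$report$rae, 1 + 1e-9)
})

test_that("masking every data point raises the degenerate objective", {
  fx <- small_fixture(noise_frac = 0)
  pe <- fx$experiment
  conf <- confidence_matrix(matrix(0.5, length(pe$signal$q),
                                   length(pe$signal$t)))
  cfg <- optimization_config(n_init = 2, seed = 1, p_conf_min = 0.9)
  expect_error(optimize_weights(pe$signal, conf, fx$ensemble,
                                fx$truth$params, pe$reference, cfg,
                                bin_width = 50),
               "degenerate")
})

test_that("a 1x1 global scan reduces to a single weight optimization", {
  fx <- small_fixture(noise_frac = 0)
  pe <- fx$experiment
  p <- fx$truth$params
  cfg <- optimization_config(n_init = 4, seed = 5, t0_grid = p$t0,
                             tau_c_grid = p$tau_c,
                             scalar_grid = p$gamma)
  scan <- scan_globals(pe$signal, NULL, fx$ensemble, p, pe$reference, cfg,
                       bin_width = 50)
  expect_equal(nrow(scan$cells), 1L)
  direct <- optimize_weights(pe$signal, NULL, fx$ensemble, p,
                             pe$reference, cfg, bin_width = 50)
  expect_equal(scan$best$best_weights, direct$best_weights,
               tolerance = 1e-12)
  expect_equal(scan$best_cell$F, direct$F)
})

test_that("scanning recovers an interior time zero from synthetic data", {
  fx <- small_fixture(noise_frac = 0)   # truth: t0 = -30
  pe <- fx$experiment
  p <- fx$truth$params
  cfg <- optimization_config(n_init = 4, seed = 5,
                             t0_grid = c(-60, -30, 0),
                             tau_c_grid = p$tau_c,
                             scalar_grid = p$gamma)
  scan <- scan_globals(pe$signal, NULL, fx$ensemble, p, pe$reference, cfg,
                       bin_width = 50)
  expect_equal(scan$best_cell$t0, -30)
})

test_that("step one recovers on-grid globals for an equal-weight truth", {
  espec <- toy_ensemble_spec(n_bound = 2, n_dissociative = 4, t_max = 600,
                             dt = 20, seed = 8)
  ens <- make_toy_ensemble(espec)
  n <- ens$n_tbf
  truth_p <- global_params(t0 = -40, tau_c = 60, gamma = 0.04)
  ps <- pseudo_experiment_spec(rep(1 / n, n), truth_p,
                               q = seq(1, 6, by = 0.25),
                               exp_times = seq(-100, 500, by = 25),
                               bin_width = 25, noise_frac = 0, seed = 1)
  pe <- make_pseudo_experiment(ens, ps)
  s1 <- step1_fit_globals(pe$signal, ens, truth_p, pe$reference,
                          q_window = c(2, 5),
                          t0_grid = c(-80, -40, 0),
                          tau_c_grid = c(30, 60, 90), bin_width = 25)
  expect_equal(s1$table$t0[1], -40)
  expect_equal(s1$table$tau_c[1], 60)
  expect_equal(s1$table$gamma[1], 0.04, tolerance = 1e-9)
  expect_equal(s1$table$sse[1], 0, tolerance = 1e-12)
  # doubling the experimental amplitude doubles the fitted gamma
  pe2 <- pe$signal; pe2$values <- 2 * pe2$values
  s1b <- step1_fit_globals(pe2, ens, truth_p, pe$reference,
                           q_window = c(2, 5), t0_grid = -40,
                           tau_c_grid = 60, bin_width = 25)
  expect_equal(s1b$table$gamma[1], 0.08, tolerance = 1e-9)
})

test_that("the two-step round trip is self-consistent on clean data", {
  espec <- toy_ensemble_spec(n_bound = 2, n_dissociative = 4, t_max = 600,
                             dt = 20, seed = 8)
  ens <- make_toy_ensemble(espec)
  n <- ens$n_tbf
  truth_p <- global_params(t0 = -40, tau_c = 60, gamma = 0.04)
  ps <- pseudo_experiment_spec(rep(1 / n, n), truth_p,
                               q = seq(1, 6, by = 0.25),
                               exp_times = seq(-100, 500, by = 25),
                               bin_width = 25, noise_frac = 0, seed = 1)
  pe <- make_pseudo_experiment(ens, ps)
  s1 <- step1_fit_globals(pe$signal, ens, truth_p, pe$reference,
                          q_window = c(2, 5), t0_grid = c(-40, 0),
                          tau_c_grid = 60, bin_width = 25)
  cfg <- optimization_config(n_init = 4, seed = 2)
  s2 <- step2_fit_weights(pe$signal, NULL, ens, pe$reference, s1, cfg,
                          n_candidates = 2, bin_width = 25)
  expect_true(s2$consistent)
  expect_equal(s2$best$best_params$t0, -40)
  best_drift <- s2$candidates$drift[which.min(s2$candidates$F)]
  expect_lt(best_drift, 1e-6)
})
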