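# Apparatus mapping: percent difference, convolution, binning.

test_that("percent difference vanishes without structural change or excitation", {
  q <- 1:5; t <- c(0, 10, 20)
  ref <- c(10, 8, 6, 4, 2)
  flat <- signal_matrix(q, t, matrix(ref, 5, 3))
  p <- global_params(tau_c = 50, gamma = 0.4)
  expect_equal(percent_difference_model(flat, ref, p)$values,
               matrix(0, 5, 3))
  bumped <- signal_matrix(q, t, matrix(ref * 1.1, 5, 3))
  p0 <- global_params(tau_c = 50, gamma = 0)
  expect_equal(percent_difference_model(bumped, ref, p0)$values,
               matrix(0, 5, 3))
})

test_that("percent difference is linear in the excitation fraction", {
  q <- 1:4; t <- c(0, 5)
  ref <- rep(5, 4)
  sig <- signal_matrix(q, t, matrix(stats::runif(8, 4, 6), 4, 2))
  p1 <- global_params(tau_c = 50, gamma = 0.2)
  p2 <- global_params(tau_c = 50, gamma = 0.4)
  expect_equal(percent_difference_model(sig, ref, p2)$values,
               2 * percent_difference_model(sig, ref, p1)$values)
  expect_error(percent_difference_model(sig, c(5, 5, 0, 5), p1),
               "strictly positive")
})

test_that("a q-dependent excitation profile is interpolated and scaled by x", {
  prof <- list(q = c(1, 3), gamma = c(0.02, 0.06))
  p <- global_params(tau_c = 50, gamma_q = prof, x = 1.5)
  expect_equal(gamma_eff(p, 2), 1.5 * 0.04)
  expect_equal(gamma_eff(p, c(1, 3)), 1.5 * c(0.02, 0.06))
})

test_that("convolution: delta limit, constant rows, smoothed step", {
  t <- seq(0, 1000, by = 0.5)
  q <- c(1, 2)
  step <- matrix(rep(ifelse(t >= 400, 1, 0), each = 2), 2, length(t))
  sig <- signal_matrix(q, t, step)
  tiny <- convolve_time(sig, 0.05)   # FWHM below the grid step
  expect_equal(tiny$values, step, tolerance = 1e-6)

  const <- signal_matrix(q, t, matrix(3, 2, length(t)))
  conv <- convolve_time(const, 100)
  inner <- t > 300   # away from the zero-padded leading edge
  expect_equal(conv$values[, inner], const$values[, inner],
               tolerance = 1e-9)

  sm <- convolve_time(sig, 100)
  at_step <- which(t == 400)
  expect_equal(sm$values[1, at_step], 0.5, tolerance = 0.01)
  # closed-form Gaussian-smoothed step one sigma after the edge
  sigma <- 100 / (2 * sqrt(2 * log(2)))
  at <- which.min(abs(t - (400 + sigma)))
  expect_equal(sm$values[1, at], stats::pnorm(1), tolerance = 0.01)
})

test_that("unit-area convolution preserves the integral of a compact bump", {
  t <- seq(0, 2000, by = 2)
  bump <- exp(-((t - 1000) / 50)^2)
  sig <- signal_matrix(c(1), t, matrix(bump, 1))
  conv <- convolve_time(sig, 120)
  expect_equal(sum(conv$values), sum(bump), tolerance = 1e-6)
  expect_error(convolve_time(signal_matrix(1, c(0, 1, 3),
                                           matrix(0, 1, 3)), 10),
               "uniform")
})

test_that("mapping to the experimental axis shifts and bins as stated", {
  t <- seq(0, 500, by = 10)
  q <- c(1, 2)
  ramp <- matrix(rep(2 * t + 5, each = 2), 2, length(t))
  sig <- signal_matrix(q, t, ramp)
  # identity: t0 = 0, exp times on the grid, bin = model step
  sub <- seq(50, 450, by = 50)
  out <- map_to_experiment(sig, 0, sub, bin_width = 10)
  expect_equal(out$values, matrix(rep(2 * sub + 5, each = 2), 2),
               tolerance = 1e-12)
  # pure shift of a linear signal by t0
  out2 <- map_to_experiment(sig, -40, sub, bin_width = 10)
  expect_equal(out2$values[1, ], 2 * (sub + 40) + 5, tolerance = 1e-12)
  # box-averaging a linear ramp returns the midpoint value
  out3 <- map_to_experiment(sig, 0, c(100, 200), bin_width = 60)
  expect_equal(out3$values[1, ], c(205, 405), tolerance = 1e-12)
  expect_error(map_to_experiment(sig, 0, c(490, 600)), "covers")
})

test_that("forward model is affine in the weights and relabel-symmetric", {
  fx <- small_fixture()
  ens <- fx$ensemble; pe <- fx$experiment
  p <- fx$truth$params
  n <- ens$n_tbf
  q <- pe$signal$q; et <- pe$signal$t
  fm <- function(w, e = ens) forward_model(e, w, p, pe$reference, q, et,
                                           bin_width = 50)
  w1 <- rep(1 / n, n)
  w2 <- numeric(n); w2[4] <- 1
  a <- 0.25
  expect_equal(fm(a * w1 + (1 - a) * w2)$values,
               a * fm(w1)$values + (1 - a) * fm(w2)$values,
               tolerance = 1e-9)
  # permuting trajectories together with their weights changes nothing
  perm <- sample(n)
  ens_p <- ens
  ens_p$positions <- ens$positions[, , , perm]
  ens_p$ids <- ens$ids[perm]; ens_p$labels <- ens$labels[perm]
  w <- fx$truth$weights
  expect_equal(fm(w[perm], ens_p)$values, fm(w)$values, tolerance = 1e-12)
})

test_that("gamma scaling commutes with convolution in the pipeline", {
  fx <- small_fixture()
  pe <- fx$experiment
  p1 <- fx$truth$params
  p2 <- global_params(t0 = p1$t0, tau_c = p1$tau_c, gamma = p1$gamma / 2)
  m1 <- forward_model(fx$ensemble, fx$truth$weights, p1, pe$reference,
                      pe$signal$q, pe$signal$t, bin_width = 50)
  m2 <- forward_model(fx$ensemble, fx$truth$weights, p2, pe$reference,
                      pe$signal$q, pe$signal$t, bin_width = 50)
  expect_equal(m1$values, 2 * m2$values, tolerance = 1e-12)
})

test_that("a zero-noise pseudo-experiment is the forward model exactly", {
  fx <- small_fixture(noise_frac = 0)
  pe <- fx$experiment
  direct <- forward_model(fx$ensemble, fx$truth$weights, fx$truth$params,
                          pe$reference, pe$signal$q, pe$signal$t,
                          bin_width = 50)
  expect_identical(pe$signal$values, direct$values)
})
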