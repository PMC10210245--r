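# Shared fixtures, built in code at test time.

cs2_geometry <- function(r = 1.55) {
  list(symbols = c("C", "S", "S"),
       positions = rbind(c(0, 0, 0), c(0, 0, -r), c(0, 0, r)))
}

random_geometry <- function(n_atoms, seed) {
  set.seed(seed)
  syms <- sample(c("H", "C", "N", "O", "S"), n_atoms, replace = TRUE)
  list(symbols = syms,
       positions = matrix(stats::runif(3 * n_atoms, -2, 2), n_atoms, 3))
}

# a small, fast end-to-end fixture for optimizer tests
small_fixture <- function(seed = 11L, noise_frac = 0,
                          active = c(2L, 5L, 7L),
                          active_w = c(0.5, 0.3, 0.2),
                          t0 = -30, tau_c = 40, gamma = 0.06) {
  espec <- toy_ensemble_spec(n_bound = 3L, n_dissociative = 5L,
                             t_max = 600, dt = 20, seed = seed)
  ens <- make_toy_ensemble(espec)
  w <- numeric(ens$n_tbf)
  w[active] <- active_w / sum(active_w)
  params <- global_params(t0 = t0, tau_c = tau_c, gamma = gamma)
  ps <- pseudo_experiment_spec(
    true_weights = w, true_params = params,
    q = seq(1, 6, by = 0.25), exp_times = seq(-100, 500, by = 50),
    bin_width = 50, noise_frac = noise_frac, seed = seed + 1L)
  pe <- make_pseudo_experiment(ens, ps)
  list(ensemble = ens, experiment = pe, truth = pe$truth, spec = ps)
}

# write a small multi-frame XYZ file; frames is a list of matrices
write_xyz_text <- function(path, symbols, frames, times) {
  out <- character(0)
  for (k in seq_along(frames)) {
    out <- c(out, as.character(length(symbols)),
             sprintf("t = %g fs", times[k]),
             sprintf("%s %.6f %.6f %.6f", symbols,
                     frames[[k]][, 1], frames[[k]][, 2], frames[[k]][, 3]))
  }
  writeLines(out, path)
  path
}
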