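# Synthetic fixtures: toy trajectory ensembles with known class structure
# and pseudo-experimental signals with known ground-truth weights, noise
# and apparatus parameters, so every stage of the pipeline can be tested
# end to end without external data.
#
# The default toy molecule is a CS2-like linear triatomic. Bound
# trajectories perform damped symmetric-stretch oscillations; dissociative
# trajectories break one C-S bond after an onset delay and separate at a
# constant asymptotic speed. This reproduces the two qualitative signal
# motifs of the real photochemistry — an oscillating enhancement/depletion
# band at intermediate q from bound vibrations and a growing low-q rise
# from dissociation — so synthetic tests exercise the same
# identifiability structure the real inversions confront.

#' Specification of a toy trajectory ensemble
#'
#' @param n_bound,n_dissociative Trajectory counts per class.
#' @param symbols Atom symbols of the linear A-B-A triatomic (center atom
#'   second is not required: order is `end, center, end`).
#' @param r0 Equilibrium bond length (Angstrom).
#' @param period_range Range of bound-oscillation periods (fs); each
#'   trajectory draws its own period uniformly.
#' @param amplitude_range Range of oscillation amplitudes (Angstrom).
#' @param damping_range Range of exponential damping times (fs).
#' @param onset_range Range of dissociation onset delays (fs).
#' @param speed_range Range of asymptotic separation speeds (Angstrom/fs).
#' @param shift_range Range of excited-state mean bond elongations
#'   (Angstrom), switched on over `switch_on` fs: photoexcited molecules
#'   are vibrationally hot and structurally displaced from the ground
#'   state, so every excited trajectory carries an O(signal) structural
#'   change.
#' @param switch_on Rise time of the excited-state displacement (fs).
#' @param t_max,dt Time span and step of the trajectory frames (fs).
#' @param seed Integer seed.
#' @return An object of class `toy_ensemble_spec`.
#' @details Per-trajectory dynamical parameters are drawn uniformly from
#'   the stated ranges, and bound members additionally draw a relative
#'   phase between the two bonds (mixing symmetric and antisymmetric
#'   stretch character), emulating the diversity of a real semiclassical
#'   trajectory ensemble: members share the initial geometry but rapidly
#'   become structurally distinguishable, which is what makes the weight
#'   inversion well posed.
#' @export
toy_ensemble_spec <- function(n_bound = 10L, n_dissociative = 30L,
                              symbols = c("S", "C", "S"), r0 = 1.55,
                              period_range = c(50, 120),
                              amplitude_range = c(0.06, 0.25),
                              damping_range = c(250, 800),
                              onset_range = c(30, 400),
                              speed_range = c(0.006, 0.025),
                              shift_range = c(0.08, 0.18),
                              switch_on = 30, t_max = 1500, dt = 10,
                              seed = 42L) {
  stopifnot(n_bound >= 0L, n_dissociative >= 0L, r0 > 0,
            all(period_range > 0), all(amplitude_range > 0),
            all(damping_range > 0), all(speed_range > 0),
            all(shift_range >= 0), switch_on > 0, t_max > 0, dt > 0)
  structure(list(n_bound = as.integer(n_bound),
                 n_dissociative = as.integer(n_dissociative),
                 symbols = symbols, r0 = r0, period_range = period_range,
                 amplitude_range = amplitude_range,
                 damping_range = damping_range, onset_range = onset_range,
                 speed_range = speed_range, shift_range = shift_range,
                 switch_on = switch_on, t_max = t_max, dt = dt,
                 seed = as.integer(seed)),
            class = "toy_ensemble_spec")
}

#' Generate a toy trajectory ensemble
#'
#' Analytic bond-length time courses are converted to Cartesian frames of
#' a linear triatomic on the axis `z`; per-trajectory parameters are
#' jittered reproducibly from the seed, and class labels `"bound"` /
#' `"dissociative"` are attached.
#'
#' @param spec A [toy_ensemble_spec()].
#' @return A `trajectory_ensemble` on the spec's time grid.
#' @export
make_toy_ensemble <- function(spec) {
  n_tot <- spec$n_bound + spec$n_dissociative
  if (n_tot < 1L) stop("ensemble must contain at least one trajectory",
                       call. = FALSE)
  set.seed(spec$seed)
  times <- seq(0, spec$t_max, by = spec$dt)
  # stratified (Latin-hypercube style) draws per class: each parameter
  # covers its range in evenly spaced strata, randomly paired, so the
  # basis samples the dynamical space generously without chance
  # near-duplicates
  strat <- function(rng, n) {
    if (n == 0L) return(numeric(0))
    edges <- seq(rng[1], rng[2], length.out = n + 1L)
    lo <- edges[-(n + 1L)]
    sample(lo + stats::runif(n) * diff(edges))
  }
  nb <- spec$n_bound; nd <- spec$n_dissociative
  pars <- list(
    per = c(strat(spec$period_range, nb), strat(spec$period_range, nd)),
    amp = c(strat(spec$amplitude_range, nb),
            strat(spec$amplitude_range, nd)),
    damp = c(strat(spec$damping_range, nb),
             strat(spec$damping_range, nd)),
    phase = c(strat(c(0, 2 * pi), nb), strat(c(0, 2 * pi), nd)),
    dphase = c(strat(c(0, 2 * pi), nb), strat(c(0, 2 * pi), nd)),
    shift = c(strat(spec$shift_range, nb), strat(spec$shift_range, nd)),
    t_on = c(rep(NA_real_, nb), strat(spec$onset_range, nd)),
    v = c(rep(NA_real_, nb), strat(spec$speed_range, nd)))
  trajs <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    bound <- i <= spec$n_bound
    per <- pars$per[i]; amp <- pars$amp[i]; damp <- pars$damp[i]
    phase <- pars$phase[i]
    # each bond carries its own phase: a random mix of symmetric and
    # antisymmetric stretch character per trajectory
    dphase <- pars$dphase[i]
    mode <- function(ph) {
      o <- amp * exp(-times / damp) * sin(2 * pi * times / per + ph)
      o - o[1] * exp(-times / damp)  # all members start at equilibrium
    }
    # hot excited-state displacement of the mean bond length
    shift <- pars$shift[i] * (1 - exp(-times / spec$switch_on))
    r1 <- spec$r0 + shift + mode(phase)
    if (bound) {
      r2 <- spec$r0 + shift + mode(phase + dphase)
      label <- "bound"
    } else {
      r2 <- spec$r0 + shift + mode(phase + dphase) +
        pars$v[i] * pmax(times - pars$t_on[i], 0)
      label <- "dissociative"
    }
    nat <- length(spec$symbols)
    pos <- array(0, dim = c(nat, 3L, length(times)))
    pos[1, 3, ] <- -r1
    pos[3, 3, ] <- r2
    trajs[[i]] <- trajectory(sprintf("toy%03d", i), times, spec$symbols,
                             pos, label)
  }
  build_ensemble(trajs, times)
}

#' Specification of a pseudo-experiment
#'
#' @param true_weights Ground-truth weight vector on the simplex (sparse
#'   in the reference fixture).
#' @param true_params Ground-truth [global_params()].
#' @param q Momentum-transfer grid (inverse Angstrom).
#' @param exp_times Experimental time stamps (fs).
#' @param bin_width Temporal bin width (fs).
#' @param noise_frac Gaussian noise standard deviation as a fraction of
#'   the clean signal's peak absolute value (0 for noiseless).
#' @param sigma_q_scale Optional vector over q multiplying the noise sigma
#'   row-wise (heteroscedastic noise, e.g. to corrupt a band).
#' @param seed Integer noise seed.
#' @return An object of class `pseudo_experiment_spec`.
#' @export
pseudo_experiment_spec <- function(true_weights, true_params,
                                   q = seq(1, 8, by = 0.025),
                                   exp_times = seq(-200, 1400, by = 10),
                                   bin_width = 10, noise_frac = 0.1,
                                   sigma_q_scale = NULL, seed = 7L) {
  structure(list(true_weights = check_weights(true_weights),
                 true_params = true_params, q = q, exp_times = exp_times,
                 bin_width = bin_width, noise_frac = noise_frac,
                 sigma_q_scale = sigma_q_scale, seed = as.integer(seed)),
            class = "pseudo_experiment_spec")
}

#' Generate a pseudo-experimental signal
#'
#' Runs the full forward model at the ground-truth weights and parameters,
#' adds heteroscedastic Gaussian noise, and returns the signal together
#' with the sigma map, the derived confidence matrix, and a truth record
#' for recovery scoring. With `noise_frac = 0` the output equals the
#' forward model exactly.
#'
#' @param ensemble A `trajectory_ensemble`.
#' @param spec A [pseudo_experiment_spec()].
#' @param reference Optional `I_off(q)`; defaults to the IAM signal of the
#'   first frame of the first trajectory (the shared starting geometry).
#' @param probe Probe kind.
#' @return List with `signal` ([signal_matrix()]), `sigma` (matrix),
#'   `conf` ([confidence_matrix()]), `reference`, and `truth` (list:
#'   `weights`, `params`, `ids`, `labels`).
#' @export
make_pseudo_experiment <- function(ensemble, spec, reference = NULL,
                                   probe = "xray") {
  if (is.null(reference))
    reference <- reference_signal(get_geometry(ensemble, 1L, 1L), spec$q,
                                  probe)
  clean <- forward_model(ensemble, spec$true_weights, spec$true_params,
                         reference, spec$q, spec$exp_times, probe,
                         spec$bin_width)
  base_sigma <- spec$noise_frac * max(abs(clean$values))
  scale_q <- if (is.null(spec$sigma_q_scale)) rep(1, length(spec$q)) else
    spec$sigma_q_scale
  sigma <- matrix(base_sigma, length(spec$q), length(spec$exp_times)) *
    scale_q
  vals <- clean$values
  if (spec$noise_frac > 0) {
    set.seed(spec$seed)
    vals <- vals + matrix(stats::rnorm(length(vals), sd = as.numeric(sigma)),
                          nrow(vals), ncol(vals))
  }
  conf <- if (base_sigma > 0) confidence_from_sigma(sigma) else
    confidence_matrix(matrix(1, length(spec$q), length(spec$exp_times)))
  list(signal = signal_matrix(spec$q, spec$exp_times, vals, "percent"),
       clean = clean, sigma = sigma, conf = conf, reference = reference,
       truth = list(weights = spec$true_weights,
                    params = spec$true_params, ids = ensemble$ids,
                    labels = ensemble$labels))
}

#' Reference synthetic fixture
#'
#' The canonical end-to-end test case: 40 trajectories (10 bound, 30
#' dissociative), 8 of them active with a sparse weight pattern echoing
#' the concentration seen in real fits (two bound trajectories totalling
#' 28%), Gaussian noise at 10% of the peak signal, and known apparatus
#' parameters `t0 = -60 fs`, `tau_c = 40 fs`, `gamma = 0.05`. The
#' momentum-transfer grid spans 1 to 8 inverse Angstrom (below ~1 the
#' detector beam stop blocks real measurements) at the fine azimuthal
#' binning detectors deliver.
#'
#' @param seed Integer seed controlling ensemble jitter and noise.
#' @param noise_frac Noise level (fraction of peak signal).
#' @return List with `ensemble`, `experiment` (see
#'   [make_pseudo_experiment()]), and `spec`.
#' @export
reference_fixture <- function(seed = 42L, noise_frac = 0.1) {
  espec <- toy_ensemble_spec(n_bound = 10L, n_dissociative = 30L,
                             seed = seed)
  ensemble <- make_toy_ensemble(espec)
  w <- numeric(40)
  # active set: 2 bound (28% total) + 6 dissociative, sparse pattern
  active <- c(3, 7, 12, 18, 23, 29, 33, 38)
  wa <- c(0.178, 0.102, 0.447, 0.104, 0.0742, 0.0442, 0.0339, 0.0167)
  w[active] <- wa / sum(wa)
  params <- global_params(t0 = -60, tau_c = 40, gamma = 0.05)
  pspec <- pseudo_experiment_spec(true_weights = w, true_params = params,
                                  noise_frac = noise_frac,
                                  seed = seed + 1L)
  list(ensemble = ensemble,
       experiment = make_pseudo_experiment(ensemble, pspec),
       spec = pspec)
}

#' Score a recovered solution against the ground truth
#'
#' @param weights Recovered weight vector.
#' @param params Recovered [global_params()] (optional).
#' @param truth Truth record from [make_pseudo_experiment()].
#' @return List with `linf`, `l2` weight errors, `class_fraction_error`
#'   (named, percentage points per label), and `t0_error`, `tau_c_error`,
#'   `gamma_rel_error` when parameters are supplied.
#' @export
score_recovery <- function(weights, truth, params = NULL) {
  if (length(weights) != length(truth$weights))
    stop("recovered and true weight vectors differ in length",
         call. = FALSE)
  dw <- weights - truth$weights
  labs <- unique(truth$labels)
  cls <- vapply(labs, function(l) {
    sel <- truth$labels == l
    100 * abs(sum(weights[sel]) - sum(truth$weights[sel]))
  }, numeric(1))
  names(cls) <- labs
  out <- list(linf = max(abs(dw)), l2 = sqrt(sum(dw^2)),
              class_fraction_error = cls)
  if (!is.null(params)) {
    tp <- truth$params
    out$t0_error <- abs(params$t0 - tp$t0)
    out$tau_c_error <- abs(params$tau_c - tp$tau_c)
    g_true <- if (is.null(tp$gamma)) tp$x else tp$gamma
    g_rec <- if (is.null(params$gamma)) params$x else params$gamma
    out$gamma_rel_error <- abs(g_rec - g_true) / abs(g_true)
  }
  out
}
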