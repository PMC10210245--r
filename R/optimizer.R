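# Weight optimization: Monte-Carlo-initialized, bound-constrained
# nonlinear least squares over the trajectory weights, with grid scans
# over the global parameters and a two-step variant for noisy data.
#
# The simplex constraint is handled by box-constraining the raw weights to
# [0, 1] and renormalizing to sum 1 inside every model evaluation, which
# makes the objective scale-invariant along rays and reproduces
# sum(w) = 1 exactly by construction. Because the mapped model is linear
# in the normalized weights, each residual evaluation reduces to a
# matrix-vector product against a precomputed per-trajectory design
# matrix, and the Jacobian is available analytically.

#' Optimization configuration
#'
#' @param n_init Number of Monte-Carlo initial weight sets.
#' @param seed Integer seed for the initial-weight pool.
#' @param t0_grid,tau_c_grid Scan grids (fs) for [scan_globals()] and
#'   [step1_fit_globals()].
#' @param scalar_grid Scan grid for the excitation scalar (uniform `gamma`
#'   or the profile scale `x`).
#' @param p_conf_min Confidence threshold applied before optimization.
#' @param ftol,ptol Relative function/step convergence tolerances.
#' @param maxiter Maximum solver iterations per initial set.
#' @param report_threshold Weight above which a trajectory is listed as
#'   dominant (default 1%).
#' @return An object of class `optimization_config`.
#' @export
optimization_config <- function(n_init = 32L, seed = 1L,
                                t0_grid = 0, tau_c_grid = numeric(0),
                                scalar_grid = numeric(0),
                                p_conf_min = 0, ftol = 1e-8, ptol = 1e-8,
                                maxiter = 200L, report_threshold = 0.01) {
  stopifnot(n_init >= 1L, ftol > 0, ptol > 0, maxiter >= 1L)
  structure(list(n_init = as.integer(n_init), seed = as.integer(seed),
                 t0_grid = t0_grid, tau_c_grid = tau_c_grid,
                 scalar_grid = scalar_grid, p_conf_min = p_conf_min,
                 ftol = ftol, ptol = ptol, maxiter = as.integer(maxiter),
                 report_threshold = report_threshold),
            class = "optimization_config")
}

#' Monte-Carlo pool of initial weight vectors
#'
#' Each component is drawn i.i.d. uniform on `[0, 1]` and the vector is
#' normalized onto the simplex; fully reproducible from the seed.
#'
#' @param n_init Number of vectors.
#' @param n_tbf Vector length.
#' @param seed Integer seed.
#' @return Matrix `n_init x n_tbf`, rows summing to 1.
#' @export
sample_initial_weights <- function(n_init, n_tbf, seed) {
  stopifnot(n_init >= 1L, n_tbf >= 1L)
  set.seed(seed)
  u <- matrix(stats::runif(n_init * n_tbf), n_init, n_tbf)
  u / rowSums(u)
}

#' Jittered resampling of the initial-weight pool
#'
#' Simple targeted-refinement scheme for challenging fits: part of the new
#' pool perturbs the incumbent best weights (component-wise uniform jitter,
#' clipped to `[0, 1]`, renormalized), the rest are fresh uniform draws.
#'
#' @param best_weights Incumbent best weight vector.
#' @param n_init Pool size.
#' @param seed Integer seed.
#' @param jitter Jitter amplitude (component-wise half-width).
#' @param frac_perturbed Fraction of the pool built by perturbation.
#' @return Matrix `n_init x n_tbf`, rows summing to 1.
#' @export
iterative_resampling <- function(best_weights, n_init, seed, jitter = 0.05,
                                 frac_perturbed = 0.5) {
  n_tbf <- length(best_weights)
  set.seed(seed)
  n_pert <- round(n_init * frac_perturbed)
  pool <- matrix(NA_real_, n_init, n_tbf)
  if (n_pert > 0) {
    for (i in seq_len(n_pert)) {
      v <- pmin(pmax(best_weights +
                       stats::runif(n_tbf, -jitter, jitter), 0), 1)
      if (sum(v) == 0) v <- rep(1, n_tbf)
      pool[i, ] <- v / sum(v)
    }
  }
  if (n_pert < n_init) {
    u <- matrix(stats::runif((n_init - n_pert) * n_tbf),
                n_init - n_pert, n_tbf)
    pool[(n_pert + 1):n_init, ] <- u / rowSums(u)
  }
  pool
}

# residual and Jacobian machinery on the precomputed design matrix
.residual_fn <- function(par, D, y, sqrtp, scalar, free_scalar) {
  n_tbf <- ncol(D)
  u <- par[seq_len(n_tbf)]
  g <- if (free_scalar) par[n_tbf + 1L] else scalar
  S <- sum(u)
  if (S < 1e-12) return(rep(1e6, length(y)))
  sqrtp * (g * as.numeric(D %*% (u / S)) - y)
}

.jacobian_fn <- function(par, D, y, sqrtp, scalar, free_scalar) {
  n_tbf <- ncol(D)
  u <- par[seq_len(n_tbf)]
  g <- if (free_scalar) par[n_tbf + 1L] else scalar
  S <- sum(u)
  if (S < 1e-12) S <- 1e-12
  Dw <- as.numeric(D %*% (u / S))
  J <- (g / S) * sqrtp * (D - Dw)  # column-recycled subtraction
  if (free_scalar) J <- cbind(J, sqrtp * Dw)
  J
}

#' Optimize trajectory weights at fixed global parameters
#'
#' For each Monte-Carlo initial set, minimizes the confidence-weighted
#' residual `sqrt(p_ij) (%dI_mod(q_i, t_j; w, c) - %dI_exp(q_i, t_j))`
#' over the weights (and the excitation scalar when `free_gamma = TRUE`)
#' with box constraints, using bounded Levenberg-Marquardt least squares.
#' Converged candidates are ranked by the target function `F`; ties break
#' on lower RAE, then lower weight variance, then first-found init.
#' Non-converged inits are recorded, never silently dropped.
#'
#' @param exp_signal Experimental percent-difference [signal_matrix()].
#' @param conf A [confidence_matrix()] (or `NULL` for all-ones).
#' @param ensemble A [build_ensemble()] result.
#' @param params Fixed [global_params()] (`gamma` is the starting value
#'   when `free_gamma`).
#' @param reference `I_off(q)` vector.
#' @param cfg An [optimization_config()].
#' @param free_gamma Re-optimize the excitation scalar jointly with the
#'   weights.
#' @param probe Probe kind.
#' @param bin_width Temporal bin width (fs).
#' @param stack Optional [ensemble_signal_stack()].
#' @param inits Optional explicit initial-weight pool (overrides the
#'   Monte-Carlo pool).
#' @return An object of class `tbf_fit`: best weights, updated parameters,
#'   `F`, [fit_report()], dominant-trajectory table, per-init records.
#' @export
optimize_weights <- function(exp_signal, conf, ensemble, params, reference,
                             cfg = optimization_config(),
                             free_gamma = FALSE, probe = "xray",
                             bin_width = NULL, stack = NULL,
                             inits = NULL) {
  q <- exp_signal$q; exp_times <- exp_signal$t
  pv <- if (is.null(conf)) matrix(1, length(q), length(exp_times)) else
    confidence_matrix(conf$values, max(conf$p_min, cfg$p_conf_min))$values
  if (!identical(dim(pv), dim(exp_signal$values)))
    stop("confidence matrix shape differs from the experiment",
         call. = FALSE)
  if (all(pv == 0))
    stop("all data points masked (p_conf_min too high): degenerate objective",
         call. = FALSE)
  D <- .forward_design(ensemble, params, reference, q, exp_times, probe,
                       bin_width, stack)
  idx <- which(as.numeric(pv) > 0)
  sqrtp <- sqrt(as.numeric(pv))[idx]
  y <- as.numeric(exp_signal$values)[idx]
  Di <- D[idx, , drop = FALSE]
  scalar0 <- if (is.null(params$gamma)) params$x else params$gamma
  n_tbf <- ensemble$n_tbf

  if (is.null(inits)) inits <- sample_initial_weights(cfg$n_init, n_tbf,
                                                      cfg$seed)
  n_init <- nrow(inits)
  records <- vector("list", n_init)
  best <- NULL
  ctrl <- minpack.lm::nls.lm.control(ftol = cfg$ftol, ptol = cfg$ptol,
                                     maxiter = cfg$maxiter)
  for (i in seq_len(n_init)) {
    par0 <- as.numeric(inits[i, ])
    lower <- rep(0, n_tbf); upper <- rep(1, n_tbf)
    if (free_gamma) {
      par0 <- c(par0, scalar0); lower <- c(lower, 0)
      upper <- c(upper, if (is.null(params$gamma)) Inf else 1)
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                         fn = .residual_fn, jac = .jacobian_fn,
                         D = Di, y = y, sqrtp = sqrtp, scalar = scalar0,
                         free_scalar = free_gamma, control = ctrl),
      error = function(e) e)
    if (inherits(fit, "error")) {
      records[[i]] <- list(init = i, converged = FALSE, F = NA_real_,
                           info = NA_integer_, message = conditionMessage(fit))
      next
    }
    u <- fit$par[seq_len(n_tbf)]
    w <- if (sum(u) > 0) u / sum(u) else rep(1 / n_tbf, n_tbf)
    g <- if (free_gamma) fit$par[n_tbf + 1L] else scalar0
    Fval <- sum(.residual_fn(fit$par, Di, y, sqrtp, scalar0, free_gamma)^2)
    conv <- fit$info %in% 1:4
    records[[i]] <- list(init = i, converged = conv, F = Fval,
                         info = fit$info, niter = fit$niter,
                         message = fit$message)
    if (conv) {
      cand <- list(w = w, g = g, F = Fval, init = i)
      if (is.null(best) || .better_candidate(cand, best, Di, y, sqrtp,
                                             n_tbf))
        best <- cand
    }
  }
  if (is.null(best))
    stop(paste0("no initial set converged; per-init diagnostics: ",
                paste(vapply(records, function(r)
                  sprintf("[%d] %s", r$init,
                          if (is.null(r$message)) "error" else r$message),
                  character(1)), collapse = "; ")), call. = FALSE)

  out_params <- params
  if (free_gamma) {
    if (is.null(params$gamma)) out_params$x <- best$g else
      out_params$gamma <- best$g
  }
  model_vec <- best$g * as.numeric(D %*% best$w)
  model_sig <- signal_matrix(q, exp_times,
                             matrix(model_vec, length(q)), "percent")
  theory_vec <- scalar0 * as.numeric(D %*% rep(1 / n_tbf, n_tbf))
  theory_sig <- signal_matrix(q, exp_times,
                              matrix(theory_vec, length(q)), "percent")
  rep_ <- fit_report(F = best$F,
                     rae = tryCatch(rae(model_sig, theory_sig, exp_signal),
                                    error = function(e) NA_real_),
                     rmse = rmse(model_sig, exp_signal),
                     var_w = weight_variance(best$w))
  rec_df <- do.call(rbind, lapply(records, function(r)
    data.frame(init = r$init, converged = r$converged, F = r$F,
               info = if (is.null(r$info)) NA_integer_ else r$info)))
  dom <- order(best$w, decreasing = TRUE)
  dom <- dom[best$w[dom] > cfg$report_threshold]
  structure(list(
    best_weights = best$w, best_params = out_params, F = best$F,
    report = rep_, model = model_sig, theory = theory_sig,
    weights_table = data.frame(trajectory_id = ensemble$ids,
                               label = ensemble$labels,
                               weight = best$w),
    dominant = data.frame(trajectory_id = ensemble$ids[dom],
                          label = ensemble$labels[dom],
                          weight = best$w[dom]),
    per_init = rec_df, best_init = best$init, seed = cfg$seed,
    n_converged = sum(rec_df$converged)),
    class = "tbf_fit")
}

# rank candidates: F, then RAE, then Var_w, then init order
.better_candidate <- function(cand, best, D, y, sqrtp, n_tbf) {
  rel <- abs(cand$F - best$F) / max(best$F, 1e-300)
  if (rel > 1e-9) return(cand$F < best$F)
  sae <- function(c_) sum(abs(sqrtp * (c_$g * as.numeric(D %*% c_$w) - y)))
  d <- sae(cand) - sae(best)
  if (abs(d) > 1e-12) return(d < 0)
  dv <- weight_variance(cand$w) - weight_variance(best$w)
  if (abs(dv) > 1e-15) return(dv < 0)
  FALSE
}

#' @export
print.tbf_fit <- function(x, ...) {
  cat(sprintf("<tbf_fit: F = %.6g, %d/%d inits converged, best init %d>\n",
              x$F, x$n_converged, nrow(x$per_init), x$best_init))
  print(x$report)
  cat(sprintf("  dominant trajectories (n = %d):\n", nrow(x$dominant)))
  if (nrow(x$dominant)) {
    for (i in seq_len(nrow(x$dominant)))
      cat(sprintf("    %-12s %-14s %6.2f%%\n", x$dominant$trajectory_id[i],
                  x$dominant$label[i], 100 * x$dominant$weight[i]))
  }
  invisible(x)
}

#' Full factorial scan over global parameters
#'
#' Runs [optimize_weights()] for every combination of `t0`, `tau_c` and
#' the excitation scalar in the configured grids and returns the per-cell
#' table together with the argmin cell. A failed cell is recorded, not
#' fatal.
#'
#' @inheritParams optimize_weights
#' @param base_params Template [global_params()] supplying whatever the
#'   grids do not vary (e.g. the `gamma_q` profile).
#' @return List with `cells` (data frame: t0, tau_c, scalar, F, rae,
#'   converged), `results` (list of `tbf_fit`), `best` and `best_cell`.
#' @export
scan_globals <- function(exp_signal, conf, ensemble, base_params, reference,
                         cfg = optimization_config(), probe = "xray",
                         bin_width = NULL, stack = NULL) {
  if (is.null(stack))
    stack <- ensemble_signal_stack(ensemble, exp_signal$q, probe)
  t0g <- cfg$t0_grid
  tcg <- if (length(cfg$tau_c_grid)) cfg$tau_c_grid else base_params$tau_c
  scg <- if (length(cfg$scalar_grid)) cfg$scalar_grid else
    if (is.null(base_params$gamma)) base_params$x else base_params$gamma
  grid <- expand.grid(t0 = t0g, tau_c = tcg, scalar = scg,
                      KEEP.OUT.ATTRS = FALSE)
  results <- vector("list", nrow(grid))
  cells <- grid
  cells$F <- NA_real_; cells$rae <- NA_real_; cells$converged <- 0L
  for (i in seq_len(nrow(grid))) {
    p <- base_params
    p$t0 <- grid$t0[i]; p$tau_c <- grid$tau_c[i]
    if (is.null(p$gamma)) p$x <- grid$scalar[i] else p$gamma <- grid$scalar[i]
    res <- tryCatch(
      optimize_weights(exp_signal, conf, ensemble, p, reference, cfg,
                       free_gamma = FALSE, probe = probe,
                       bin_width = bin_width, stack = stack),
      error = function(e) e)
    if (inherits(res, "error")) {
      results[[i]] <- res
      next
    }
    results[[i]] <- res
    cells$F[i] <- res$F
    cells$rae[i] <- res$report$rae
    cells$converged[i] <- res$n_converged
  }
  ok <- which(!is.na(cells$F))
  if (!length(ok)) stop("every scan cell failed", call. = FALSE)
  best_i <- ok[which.min(cells$F[ok])]
  list(cells = cells, results = results, best = results[[best_i]],
       best_cell = cells[best_i, , drop = FALSE])
}

#' Step one: global parameters from the integrated signal
#'
#' Approximates the early-time wave function by an equally weighted sum of
#' trajectories and, for each `(t0, tau_c)` grid cell, fits the excitation
#' scalar by one-dimensional least squares between the integrated
#' experimental and model signals over the high-confidence q window.
#' Cells are ranked by the sum of squared error.
#'
#' @inheritParams optimize_weights
#' @param q_window Length-2 vector: bounds of the highest-confidence band
#'   (inverse Angstrom) for [integrated_signal()].
#' @param t0_grid,tau_c_grid Scan grids (fs).
#' @param base_params Template [global_params()].
#' @return List with `table` (ranked data frame: t0, tau_c, gamma, sse,
#'   rmse, rae_int) and `candidates` (list of [global_params()], best
#'   first).
#' @export
step1_fit_globals <- function(exp_signal, ensemble, base_params, reference,
                              q_window, t0_grid, tau_c_grid,
                              probe = "xray", bin_width = NULL,
                              stack = NULL) {
  if (is.null(stack))
    stack <- ensemble_signal_stack(ensemble, exp_signal$q, probe)
  y <- integrated_signal(exp_signal, q_window[1], q_window[2])
  grid <- expand.grid(t0 = t0_grid, tau_c = tau_c_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$gamma <- NA_real_; grid$sse <- NA_real_
  grid$rmse <- NA_real_; grid$rae_int <- NA_real_
  w_eq <- rep(1 / ensemble$n_tbf, ensemble$n_tbf)
  for (i in seq_len(nrow(grid))) {
    p <- base_params
    p$t0 <- grid$t0[i]; p$tau_c <- grid$tau_c[i]
    if (is.null(p$gamma)) p$x <- 1 else p$gamma <- 1
    unit <- forward_model(ensemble, w_eq, p, reference, exp_signal$q,
                          exp_signal$t, probe, bin_width, stack)
    m <- integrated_signal(unit, q_window[1], q_window[2])
    mm <- sum(m^2)
    if (mm < 1e-300)
      stop("flat equal-weight model: excitation fraction unidentifiable",
           call. = FALSE)
    g <- sum(m * y) / mm
    g <- min(max(g, 0), 1)
    r <- g * m - y
    grid$gamma[i] <- g
    grid$sse[i] <- sum(r^2)
    grid$rmse[i] <- sqrt(mean(r^2))
    grid$rae_int[i] <- if (sum(abs(y)) > 0) sum(abs(r)) / sum(abs(y)) else
      NA_real_
  }
  ord <- order(grid$sse)
  grid <- grid[ord, , drop = FALSE]
  cands <- lapply(seq_len(nrow(grid)), function(i) {
    p <- base_params
    p$t0 <- grid$t0[i]; p$tau_c <- grid$tau_c[i]
    if (is.null(p$gamma)) p$x <- grid$gamma[i] else p$gamma <- grid$gamma[i]
    p
  })
  list(table = grid, candidates = cands)
}

#' Step two: weight optimization with excitation re-optimization
#'
#' Takes the best global-parameter sets from [step1_fit_globals()], runs
#' [optimize_weights()] with the excitation scalar freed, and compares the
#' re-optimized scalar to the step-one value: a large relative drift
#' signals that the step-one parameters may be suboptimal.
#'
#' @inheritParams optimize_weights
#' @param step1 Result of [step1_fit_globals()].
#' @param n_candidates How many top-ranked step-one parameter sets to
#'   refit. Candidates are deduplicated by time zero first (each `t0`
#'   contributes its best-ranked cell), so the refits probe genuinely
#'   different temporal alignments: the step-one ranking rests on the
#'   equal-weight approximation, whose bias is largest in `t0`, and the
#'   full-data fit is the sharper arbiter.
#' @param drift_threshold Relative drift in the excitation scalar above
#'   which the self-consistency verdict fails (default 25%).
#' @return List with `best` (`tbf_fit` of the lowest-F candidate),
#'   `candidates` (per-candidate table: t0, tau_c, gamma_step1,
#'   gamma_step2, drift, F, rae), and `consistent` (logical verdict for
#'   the best candidate).
#' @export
step2_fit_weights <- function(exp_signal, conf, ensemble, reference, step1,
                              cfg = optimization_config(),
                              n_candidates = 1L, drift_threshold = 0.25,
                              probe = "xray", bin_width = NULL,
                              stack = NULL) {
  if (is.null(stack))
    stack <- ensemble_signal_stack(ensemble, exp_signal$q, probe)
  t0s <- vapply(step1$candidates, `[[`, numeric(1), "t0")
  # phase 1: arbitrate the time zero -- one candidate per distinct t0
  phase1 <- which(!duplicated(t0s))[seq_len(min(n_candidates,
                                                sum(!duplicated(t0s))))]
  tab <- data.frame(t0 = numeric(0), tau_c = numeric(0),
                    gamma_step1 = numeric(0), gamma_step2 = numeric(0),
                    drift = numeric(0), F = numeric(0), rae = numeric(0))
  fits <- list()
  refit <- function(i) {
    p <- step1$candidates[[i]]
    g1 <- if (is.null(p$gamma)) p$x else p$gamma
    fit <- optimize_weights(exp_signal, conf, ensemble, p, reference, cfg,
                            free_gamma = TRUE, probe = probe,
                            bin_width = bin_width, stack = stack)
    g2 <- if (is.null(fit$best_params$gamma)) fit$best_params$x else
      fit$best_params$gamma
    fits[[length(fits) + 1L]] <<- fit
    tab <<- rbind(tab, data.frame(t0 = p$t0, tau_c = p$tau_c,
                                  gamma_step1 = g1, gamma_step2 = g2,
                                  drift = abs(g2 - g1) / max(g1, 1e-300),
                                  F = fit$F, rae = fit$report$rae))
  }
  for (i in phase1) refit(i)
  # phase 2: at the winning t0, refit the step-one cells with the other
  # instrument-response widths (their step-one ranking inherits the same
  # equal-weight bias)
  t0_best <- tab$t0[which.min(tab$F)]
  phase2 <- setdiff(which(t0s == t0_best), phase1)
  for (i in phase2) refit(i)
  best_i <- which.min(tab$F)
  best <- fits[[best_i]]
  best$gamma_drift <- tab$drift[best_i]
  consistent <- tab$drift[best_i] <= drift_threshold
  if (!consistent)
    message(sprintf(paste0("step2: excitation scalar drifted %.1f%% from ",
                           "its step-one value; step-one globals may be ",
                           "suboptimal"), 100 * tab$drift[best_i]))
  list(best = best, candidates = tab, consistent = consistent)
}
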