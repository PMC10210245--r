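# Rotationally averaged independent-atom-model (IAM) scattering.
#
# The coherent elastic intensity of a rigid geometry in a gas of freely
# rotating molecules is the Debye double sum
#   I_el(q) = sum_A sum_B f_A(q) f_B(q) sin(q R_AB) / (q R_AB),
# the orientational average of |sum_A f_A(q) exp(i q . R_A)|^2, with the
# A = B self terms entering through the sinc -> 1 limit (required for the
# (sum Z)^2 limit at q -> 0). Geometry-independent inelastic scattering is
# added as the incoherent atomic sum.
#
# Probe prefactors (Thomson / Rutherford cross sections, polarization,
# s^-4) are multiplicative in q only and cancel exactly in the
# percent-difference observable, so they are not applied here.

#' Rotationally averaged elastic scattering (Debye formula)
#'
#' @param geometry List with `symbols` and an `n_atoms x 3` position matrix
#'   (Angstrom), e.g. from [get_geometry()].
#' @param q Momentum-transfer grid (inverse Angstrom).
#' @param probe `"xray"` or `"electron"`.
#' @return Numeric vector of elastic intensities, one per `q`; nonnegative.
#' @export
elastic_debye <- function(geometry, q, probe = "xray") {
  probe <- match.arg(probe, probe_kinds())
  pos <- matrix(geometry$positions, ncol = 3)
  sym <- geometry$symbols
  nat <- length(sym)
  if (nrow(pos) != nat) stop("positions/symbols length mismatch",
                             call. = FALSE)
  # accumulate in a canonical order (sorted species pairs, sorted
  # distances) so the result is bit-identical under atom permutation
  us <- sort(unique(sym))
  fu <- lapply(us, function(s) elastic_form_factor(s, q, probe))
  names(fu) <- us
  out <- numeric(length(q))
  for (s in us) out <- out + sum(sym == s) * fu[[s]]^2
  if (nat > 1L) {
    for (i in seq_along(us)) for (j in i:length(us)) {
      ai <- which(sym == us[i]); aj <- which(sym == us[j])
      if (i == j) {
        if (length(ai) < 2L) next
        idx <- utils::combn(ai, 2L)
        rs <- sqrt(rowSums((pos[idx[1, ], , drop = FALSE] -
                              pos[idx[2, ], , drop = FALSE])^2))
      } else {
        grid <- expand.grid(a = ai, b = aj)
        rs <- sqrt(rowSums((pos[grid$a, , drop = FALSE] -
                              pos[grid$b, , drop = FALSE])^2))
      }
      rs <- sort(rs)
      ff <- 2 * fu[[us[i]]] * fu[[us[j]]]
      for (r in rs) {
        x <- q * r
        sinc <- ifelse(x == 0, 1, sin(x) / x)
        out <- out + ff * sinc
      }
    }
  }
  out
}

# per-atom form-factor matrix, nq x nat, shared species evaluated once
.species_f_matrix <- function(symbols, q, probe) {
  fq <- matrix(NA_real_, length(q), length(symbols))
  for (sym in unique(symbols)) {
    f <- elastic_form_factor(sym, q, probe)
    fq[, symbols == sym] <- f
  }
  fq
}

#' Total IAM signal of one trajectory
#'
#' Per-frame Debye elastic intensity plus the (frame-independent) inelastic
#' sum, on the trajectory's own time grid.
#'
#' @param traj A [trajectory()], or an ensemble member selected via
#'   `ensemble`/`tbf`.
#' @param q Momentum-transfer grid (inverse Angstrom).
#' @param probe `"xray"` or `"electron"`.
#' @param include_inelastic Add the incoherent atomic sum (default `TRUE`).
#' @return A [signal_matrix()] (`|q| x n_frames`, unit `"intensity"`).
#' @export
trajectory_signal <- function(traj, q, probe = "xray",
                              include_inelastic = TRUE) {
  nt <- length(traj$times)
  vals <- matrix(NA_real_, length(q), nt)
  for (k in seq_len(nt))
    vals[, k] <- elastic_debye(list(symbols = traj$symbols,
                                    positions = traj$positions[, , k]),
                               q, probe)
  if (include_inelastic) vals <- vals + inelastic_sum(traj$symbols, q)
  signal_matrix(q, traj$times, vals, unit = "intensity")
}

#' Per-trajectory signal stack of an ensemble
#'
#' Computes each member's IAM signal once; callers (the forward model and
#' the optimizer) reuse the stack so that geometry work is never repeated
#' across weight evaluations.
#'
#' @param ensemble A [build_ensemble()] result.
#' @inheritParams trajectory_signal
#' @return Array `|q| x n_times x n_tbf`.
#' @export
ensemble_signal_stack <- function(ensemble, q, probe = "xray",
                                  include_inelastic = TRUE) {
  stack <- array(NA_real_, dim = c(length(q), length(ensemble$model_times),
                                   ensemble$n_tbf))
  inel <- if (include_inelastic) inelastic_sum(ensemble$symbols, q) else 0
  for (n in seq_len(ensemble$n_tbf)) {
    for (k in seq_along(ensemble$model_times))
      stack[, k, n] <- elastic_debye(list(symbols = ensemble$symbols,
                                          positions = ensemble$positions[, , k, n]),
                                     q, probe)
    stack[, , n] <- stack[, , n] + inel
  }
  stack
}

#' Weighted ensemble signal
#'
#' `I(q, t) = sum_n w_n I_n(q, t)`: the scattering of the weighted model
#' wave function under time-independent weights; linear in the weights.
#'
#' @param ensemble A [build_ensemble()] result.
#' @param weights Nonnegative weights summing to 1 (tolerance `1e-9`).
#' @inheritParams trajectory_signal
#' @param stack Optional precomputed [ensemble_signal_stack()].
#' @return A [signal_matrix()] on `(q, model_times)`.
#' @export
ensemble_signal <- function(ensemble, weights, q, probe = "xray",
                            include_inelastic = TRUE, stack = NULL) {
  weights <- check_weights(weights, ensemble$n_tbf)
  if (is.null(stack))
    stack <- ensemble_signal_stack(ensemble, q, probe, include_inelastic)
  vals <- matrix(0, length(q), length(ensemble$model_times))
  for (n in seq_along(weights))
    if (weights[n] != 0) vals <- vals + weights[n] * stack[, , n]
  signal_matrix(q, ensemble$model_times, vals, unit = "intensity")
}

#' Validate a trajectory weight vector
#'
#' @param weights Numeric vector.
#' @param n_tbf Expected length.
#' @param tol Tolerance on the simplex constraint `sum(w) = 1`.
#' @return The weights, unchanged, invisibly usable.
#' @export
check_weights <- function(weights, n_tbf = length(weights), tol = 1e-9) {
  weights <- as.numeric(weights)
  if (length(weights) != n_tbf)
    stop(sprintf("expected %d weights, got %d", n_tbf, length(weights)),
         call. = FALSE)
  if (any(!is.finite(weights)) || any(weights < -tol))
    stop("weights must be finite and nonnegative", call. = FALSE)
  if (abs(sum(weights) - 1) > tol)
    stop(sprintf("weights must sum to 1 (got %.12g)", sum(weights)),
         call. = FALSE)
  pmax(weights, 0)
}

#' Reference ("laser-off") intensity
#'
#' IAM signal of a reference geometry, or the average over a list of
#' geometries (e.g. a ground-state ensemble drawn from a Wigner
#' distribution).
#'
#' @param reference A geometry (list with `symbols`, `positions`) or a list
#'   of such geometries.
#' @inheritParams trajectory_signal
#' @return Numeric vector `I_off(q)`, strictly positive on valid input.
#' @export
reference_signal <- function(reference, q, probe = "xray",
                             include_inelastic = TRUE) {
  geoms <- if (!is.null(reference$symbols)) list(reference) else reference
  acc <- numeric(length(q))
  for (g in geoms) {
    v <- elastic_debye(g, q, probe)
    if (include_inelastic) v <- v + inelastic_sum(g$symbols, q)
    acc <- acc + v
  }
  acc / length(geoms)
}

#' Orientational-average oracle for the Debye formula
#'
#' Numerically averages `|sum_A f_A(q) exp(i q u . R_A)|^2` over scattering
#' directions `u` distributed on the unit sphere (deterministic Fibonacci
#' lattice, a low-discrepancy sampling whose error decays much faster than
#' plain Monte Carlo). Used as an independent cross-check of
#' [elastic_debye()]; never called by the fitting pipeline.
#'
#' @param geometry As in [elastic_debye()].
#' @param q Scalar or vector momentum transfer.
#' @param probe Probe kind.
#' @param n_orient Number of sphere points.
#' @return Numeric vector of averaged intensities, one per `q`.
#' @export
orientation_average_intensity <- function(geometry, q, probe = "xray",
                                          n_orient = 1e5) {
  pos <- matrix(geometry$positions, ncol = 3)
  sym <- geometry$symbols
  i <- seq_len(n_orient) - 0.5
  golden <- (1 + sqrt(5)) / 2
  z <- 1 - 2 * i / n_orient
  phi <- 2 * pi * i / golden
  r <- sqrt(pmax(1 - z^2, 0))
  u <- cbind(r * cos(phi), r * sin(phi), z)  # n_orient x 3
  proj <- u %*% t(pos)                       # n_orient x nat
  out <- numeric(length(q))
  fq <- .species_f_matrix(sym, q, probe)     # nq x nat
  for (j in seq_along(q)) {
    ph <- q[j] * proj
    re <- cos(ph) %*% fq[j, ]
    im <- sin(ph) %*% fq[j, ]
    out[j] <- mean(re^2 + im^2)
  }
  out
}
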