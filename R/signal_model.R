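# Apparatus mapping: from weighted IAM intensities to the model
# percent-difference signal on the experimental (q, t) grid.
#
# The chain is
#   %dI(q, t) = 100 gamma_eff(q) (I_mod(q, t) / I_off(q) - 1)
#   -> Gaussian instrument-response convolution in t (FWHM tau_c)
#   -> time-zero shift t' = t + t0 and box-average temporal binning.
# The model signal is identically zero before excitation (delta-pulse
# approximation), so the convolution pads the leading edge with zeros; the
# trailing edge holds the last value (the difference signal is
# near-stationary at late delays). Convolution happens on the fine model
# grid before binning — binning first would alias the instrument response.

#' Global experimental parameters
#'
#' @param t0 Time-zero shift (fs): experimental time `t' = t + t0`.
#' @param tau_c FWHM of the Gaussian instrument response (fs), positive.
#' @param gamma Uniform excitation fraction in `[0, 1]`; mutually exclusive
#'   with `gamma_q`.
#' @param gamma_q Optional q-dependent excitation-fraction profile: list
#'   with numeric `q` and `gamma` of equal length (linearly interpolated).
#' @param x Uniform scale applied to `gamma_q` (the quantity optimized when
#'   a profile is used), positive.
#' @return An object of class `global_params`.
#' @export
global_params <- function(t0 = 0, tau_c = 1, gamma = NULL, gamma_q = NULL,
                          x = 1) {
  if (!is.finite(tau_c) || tau_c <= 0)
    stop("tau_c must be a positive FWHM in fs", call. = FALSE)
  if (is.null(gamma) == is.null(gamma_q))
    stop("exactly one of 'gamma' or 'gamma_q' must be given", call. = FALSE)
  if (!is.null(gamma) && (!is.finite(gamma) || gamma < 0 || gamma > 1))
    stop("gamma must lie in [0, 1]", call. = FALSE)
  if (!is.null(gamma_q)) {
    if (is.null(gamma_q$q) || is.null(gamma_q$gamma) ||
        length(gamma_q$q) != length(gamma_q$gamma))
      stop("gamma_q must be a list with equal-length 'q' and 'gamma'",
           call. = FALSE)
    if (!is.finite(x) || x <= 0) stop("x must be positive", call. = FALSE)
  }
  structure(list(t0 = t0, tau_c = tau_c, gamma = gamma, gamma_q = gamma_q,
                 x = x), class = "global_params")
}

#' @export
print.global_params <- function(x, ...) {
  g <- if (!is.null(x$gamma)) sprintf("gamma = %.4g", x$gamma) else
    sprintf("gamma_q profile (%d nodes) scaled by x = %.4g",
            length(x$gamma_q$q), x$x)
  cat(sprintf("<global_params: t0 = %g fs, tau_c = %g fs, %s>\n",
              x$t0, x$tau_c, g))
  invisible(x)
}

#' Effective excitation fraction on a q grid
#'
#' @param params A [global_params()].
#' @param q Momentum-transfer grid.
#' @return Numeric vector `gamma_eff(q)`: the uniform `gamma`, or the
#'   interpolated profile times the scale `x`.
#' @export
gamma_eff <- function(params, q) {
  if (!is.null(params$gamma)) return(rep(params$gamma, length(q)))
  prof <- stats::approx(params$gamma_q$q, params$gamma_q$gamma, xout = q,
                        rule = 2)$y
  params$x * prof
}

#' Model percent-difference signal
#'
#' `%dI_mod(q, t) = 100 gamma_eff(q) (I_mod(q, t) / I_off(q) - 1)`. The
#' excitation fraction scales the difference because only the excited
#' sub-ensemble deviates from the laser-off reference. An opt-in
#' alternative rescales by the ratio of integrated laser-on/off
#' intensities instead of subtracting 1.
#'
#' @param intensity A [signal_matrix()] of model intensities.
#' @param reference Numeric vector `I_off(q)` (strictly positive), e.g.
#'   from [reference_signal()].
#' @param params A [global_params()].
#' @param mode `"difference"` (default) or `"integrated_ratio"`.
#' @return A [signal_matrix()] in percent units.
#' @export
percent_difference_model <- function(intensity, reference, params,
                                     mode = c("difference",
                                              "integrated_ratio")) {
  mode <- match.arg(mode)
  if (length(reference) != length(intensity$q))
    stop("reference length must match the q grid", call. = FALSE)
  if (any(!is.finite(reference)) || any(reference <= 0))
    stop("reference intensity must be strictly positive", call. = FALSE)
  ge <- gamma_eff(params, intensity$q)
  base <- if (mode == "difference") 1 else {
    pracma::trapz(intensity$q, reference) /
      mean(apply(intensity$values, 2, function(col)
        pracma::trapz(intensity$q, col)))
  }
  vals <- 100 * ge * (intensity$values / reference - base)
  signal_matrix(intensity$q, intensity$t, vals, unit = "percent")
}

#' Gaussian instrument-response convolution in time
#'
#' Convolves each q row with a unit-area Gaussian of FWHM `tau_c` on a
#' uniform time grid. The leading edge is zero-padded (no signal before
#' excitation under the delta-pulse approximation); the trailing edge holds
#' the last value.
#'
#' @param signal A [signal_matrix()] on a uniform time grid.
#' @param tau_c Gaussian FWHM (fs).
#' @return A [signal_matrix()] on the same grid.
#' @export
convolve_time <- function(signal, tau_c) {
  if (!is.finite(tau_c) || tau_c <= 0)
    stop("tau_c must be positive", call. = FALSE)
  dt <- .uniform_step(signal$t)
  signal_matrix(signal$q, signal$t,
                .convolve_rows(signal$values, tau_c, dt),
                unit = signal$unit)
}

.uniform_step <- function(t) {
  if (length(t) < 2L)
    stop("time grid must have at least two points", call. = FALSE)
  d <- diff(t)
  if (max(d) - min(d) > 1e-6 * mean(d))
    stop("time grid must be uniform; resample the signal first",
         call. = FALSE)
  mean(d)
}

.gauss_kernel <- function(tau_c, dt) {
  sigma <- tau_c / (2 * sqrt(2 * log(2)))
  m <- max(1L, ceiling(4 * sigma / dt))
  k <- exp(-((-m:m) * dt)^2 / (2 * sigma^2))
  list(k = k / sum(k), m = m)
}

.convolve_rows <- function(values, tau_c, dt) {
  kk <- .gauss_kernel(tau_c, dt)
  m <- kk$m; k <- kk$k
  nq <- nrow(values); nt <- ncol(values)
  ext <- cbind(matrix(0, nq, m), values,
               matrix(values[, nt], nq, m))
  out <- matrix(0, nq, nt)
  for (j in seq_along(k))
    out <- out + k[j] * ext[, j:(j + nt - 1L), drop = FALSE]
  out
}

#' Map a model signal onto the experimental time axis
#'
#' Applies the time-zero relation `t = t' - t0` and box-averages the model
#' samples inside each experimental bin (width `bin_width`, centered on the
#' experimental time stamp). When a bin contains no model sample the model
#' is linearly interpolated at the bin center.
#'
#' @param signal A [signal_matrix()] on the model time axis.
#' @param t0 Time-zero shift (fs).
#' @param exp_times Experimental time stamps `t'` (fs), strictly
#'   increasing.
#' @param bin_width Bin width (fs); defaults to the model grid step.
#' @return A [signal_matrix()] on `(q, exp_times)`.
#' @export
map_to_experiment <- function(signal, t0, exp_times, bin_width = NULL) {
  exp_times <- as.numeric(exp_times)
  if (is.unsorted(exp_times, strictly = TRUE))
    stop("exp_times must be strictly increasing", call. = FALSE)
  tm <- exp_times - t0  # model-axis bin centers
  if (is.null(bin_width)) bin_width <- .uniform_step(signal$t)
  half <- bin_width / 2
  lo <- min(tm) - half; hi <- max(tm) + half
  if (lo < signal$t[1] - 1e-9 || hi > signal$t[length(signal$t)] + 1e-9)
    stop(sprintf(paste0("model signal covers [%g, %g] fs but the shifted ",
                        "experimental bins need [%g, %g] fs"),
                 signal$t[1], signal$t[length(signal$t)], lo, hi),
         call. = FALSE)
  tol <- 1e-9 * max(1, bin_width)
  vals <- matrix(NA_real_, length(signal$q), length(exp_times))
  for (j in seq_along(tm)) {
    sel <- which(signal$t >= tm[j] - half - tol &
                   signal$t <= tm[j] + half + tol)
    vals[, j] <- if (length(sel)) rowMeans(signal$values[, sel,
                                                         drop = FALSE])
    else apply(signal$values, 1, function(row)
      stats::approx(signal$t, row, xout = tm[j])$y)
  }
  signal_matrix(signal$q, exp_times, vals, unit = signal$unit)
}

# Extend a percent-difference signal backwards in time with explicit
# zeros (pre-excitation) so the convolution sees the correct onset, and
# forwards by holding the last value. The model axis must begin at the
# excitation instant (t = 0) for the zero extension to be exact.
.extend_pd_axis <- function(signal, t_lo, t_hi) {
  dt <- .uniform_step(signal$t)
  n_pre <- max(0L, ceiling((signal$t[1] - t_lo) / dt))
  n_post <- max(0L, ceiling((t_hi - signal$t[length(signal$t)]) / dt))
  if (n_pre > 0L && signal$t[1] > 1e-9)
    stop(sprintf(paste0("model times start at %g fs > 0; cannot zero-pad ",
                        "before the excitation instant"), signal$t[1]),
         call. = FALSE)
  if (n_pre == 0L && n_post == 0L) return(signal)
  t_new <- seq(signal$t[1] - n_pre * dt, by = dt,
               length.out = n_pre + length(signal$t) + n_post)
  nq <- nrow(signal$values)
  last <- if (n_post > 0L)
    matrix(signal$values[, ncol(signal$values)], nq, n_post)
  else matrix(0, nq, 0L)
  vals <- cbind(matrix(0, nq, n_pre), signal$values, last)
  signal_matrix(signal$q, t_new, vals, unit = signal$unit)
}

#' Full forward model
#'
#' Composes [ensemble_signal()], [percent_difference_model()],
#' [convolve_time()] and [map_to_experiment()]: from trajectory weights and
#' global parameters to the model percent-difference signal on the
#' experimental grid. Deterministic, and linear in the weights and in the
#' effective excitation fraction.
#'
#' @param ensemble A [build_ensemble()] result with model times starting at
#'   the excitation instant (0 fs).
#' @param weights Trajectory weights on the simplex.
#' @param params A [global_params()].
#' @param reference `I_off(q)` vector (see [reference_signal()]).
#' @param q Momentum-transfer grid (inverse Angstrom).
#' @param exp_times Experimental time stamps (fs).
#' @param probe `"xray"` or `"electron"`.
#' @param bin_width Temporal bin width (fs); default one model step.
#' @param stack Optional precomputed [ensemble_signal_stack()].
#' @return A [signal_matrix()] on `(q, exp_times)`, percent units.
#' @export
forward_model <- function(ensemble, weights, params, reference, q,
                          exp_times, probe = "xray", bin_width = NULL,
                          stack = NULL) {
  imod <- ensemble_signal(ensemble, weights, q, probe, stack = stack)
  pd <- percent_difference_model(imod, reference, params)
  dt <- .uniform_step(pd$t)
  if (is.null(bin_width)) bin_width <- dt
  pd <- .extend_pd_axis(pd, min(exp_times) - params$t0 - bin_width,
                        max(exp_times) - params$t0 + bin_width)
  pd <- convolve_time(pd, params$tau_c)
  map_to_experiment(pd, params$t0, exp_times, bin_width)
}

# Design matrix of the linear(-in-weights) forward model: column n is the
# fully mapped percent-difference signal of trajectory n alone at unit
# excitation scalar, flattened column-major (q fastest). The mapped model
# is then scalar * (D %*% w), where the scalar is gamma (uniform case) or
# the profile scale x (gamma_q case) -- the workhorse of the optimizer.
.forward_design <- function(ensemble, params, reference, q, exp_times,
                            probe = "xray", bin_width = NULL,
                            stack = NULL) {
  if (is.null(stack)) stack <- ensemble_signal_stack(ensemble, q, probe)
  unit_params <- if (is.null(params$gamma_q))
    global_params(t0 = params$t0, tau_c = params$tau_c,
                  gamma_q = list(q = range(q), gamma = c(1, 1)), x = 1)
  else
    global_params(t0 = params$t0, tau_c = params$tau_c,
                  gamma_q = params$gamma_q, x = 1)
  D <- matrix(NA_real_, length(q) * length(exp_times), ensemble$n_tbf)
  for (n in seq_len(ensemble$n_tbf)) {
    imod <- signal_matrix(q, ensemble$model_times, stack[, , n],
                          unit = "intensity")
    pd <- percent_difference_model(imod, reference, unit_params)
    dt <- .uniform_step(pd$t)
    bw <- if (is.null(bin_width)) dt else bin_width
    pd <- .extend_pd_axis(pd, min(exp_times) - params$t0 - bw,
                          max(exp_times) - params$t0 + bw)
    pd <- convolve_time(pd, params$tau_c)
    D[, n] <- as.numeric(map_to_experiment(pd, params$t0, exp_times,
                                           bw)$values)
  }
  D
}
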