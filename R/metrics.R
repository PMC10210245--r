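# Confidence-weighted objective and fit-quality metrics.

#' Confidence matrix
#'
#' Per-point weights in `[0, 1]` matching a signal's shape; entries below
#' the threshold `p_min` are zeroed, excluding those points from the
#' objective.
#'
#' @param values Numeric matrix with entries in `[0, 1]`.
#' @param p_min Confidence threshold in `[0, 1)`.
#' @return An object of class `confidence_matrix`.
#' @export
confidence_matrix <- function(values, p_min = 0) {
  values <- as.matrix(values)
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1))
    stop("confidence entries must lie in [0, 1]", call. = FALSE)
  if (!is.finite(p_min) || p_min < 0 || p_min >= 1)
    stop("p_min must lie in [0, 1)", call. = FALSE)
  values[values < p_min] <- 0
  structure(list(values = unname(values), p_min = p_min),
            class = "confidence_matrix")
}

#' @export
print.confidence_matrix <- function(x, ...) {
  cat(sprintf("<confidence_matrix %d x %d, p_min = %g, %d/%d points active>\n",
              nrow(x$values), ncol(x$values), x$p_min,
              sum(x$values > 0), length(x$values)))
  invisible(x)
}

#' Confidence from experimental standard deviations
#'
#' Surrogate scheme `p_ij` proportional to `1 / sigma_ij`, rescaled so the
#' most trusted point has confidence 1. Non-positive or missing sigmas mark
#' invalid points and get zero confidence. Any externally computed
#' confidence matrix can be supplied to the objective instead.
#'
#' @param sigma Matrix of per-point standard deviations.
#' @param p_min Threshold passed to [confidence_matrix()].
#' @return A [confidence_matrix()].
#' @export
confidence_from_sigma <- function(sigma, p_min = 0) {
  sigma <- as.matrix(sigma)
  valid <- is.finite(sigma) & sigma > 0
  if (!any(valid))
    stop("no valid (positive, finite) standard deviations", call. = FALSE)
  p <- matrix(0, nrow(sigma), ncol(sigma))
  p[valid] <- min(sigma[valid]) / sigma[valid]
  confidence_matrix(p, p_min)
}

#' Confidence-weighted target function
#'
#' `F = sum_ij p_ij (model_ij - exp_ij)^2`; points with zero confidence
#' contribute nothing.
#'
#' @param model,exp [signal_matrix()] objects (or bare matrices) on the
#'   same grid.
#' @param conf A [confidence_matrix()] (or matrix); defaults to all ones.
#' @return Scalar `F >= 0`. Warns when every point is masked.
#' @export
target_function <- function(model, exp, conf = NULL) {
  mv <- if (inherits(model, "signal_matrix")) model$values else
    as.matrix(model)
  ev <- if (inherits(exp, "signal_matrix")) exp$values else as.matrix(exp)
  if (!identical(dim(mv), dim(ev)))
    stop("model and experiment shapes differ", call. = FALSE)
  pv <- if (is.null(conf)) matrix(1, nrow(mv), ncol(mv)) else
    if (inherits(conf, "confidence_matrix")) conf$values else
      as.matrix(conf)
  if (!identical(dim(pv), dim(mv)))
    stop("confidence matrix shape differs from the signal", call. = FALSE)
  if (all(pv == 0))
    warning("all confidence entries are zero: degenerate objective",
            call. = FALSE)
  sum(pv * (mv - ev)^2)
}

#' Net integrated percent-difference signal
#'
#' Trapezoidal integral of the signal over a q window (typically the band
#' of highest confidence), giving one time series used by the first step of
#' the two-step optimization. Window endpoints off the grid are included by
#' linear interpolation.
#'
#' @param signal A [signal_matrix()].
#' @param q_lo,q_hi Integration bounds (inverse Angstrom), inside the grid.
#' @return Numeric vector, one value per time point.
#' @export
integrated_signal <- function(signal, q_lo, q_hi) {
  q <- signal$q
  if (q_lo >= q_hi) stop("empty q window", call. = FALSE)
  if (q_lo < q[1] - 1e-9 || q_hi > q[length(q)] + 1e-9)
    stop(sprintf("q window [%g, %g] outside grid [%g, %g]",
                 q_lo, q_hi, q[1], q[length(q)]), call. = FALSE)
  inner <- q > q_lo + 1e-12 & q < q_hi - 1e-12
  nodes <- c(q_lo, q[inner], q_hi)
  vapply(seq_along(signal$t), function(j) {
    col <- signal$values[, j]
    vals <- c(stats::approx(q, col, xout = q_lo, rule = 2)$y,
              col[inner],
              stats::approx(q, col, xout = q_hi, rule = 2)$y)
    pracma::trapz(nodes, vals)
  }, numeric(1))
}

#' Relative absolute error of a fit
#'
#' Summed absolute deviation of the optimized model from experiment,
#' divided by that of the unoptimized (uniform-weight) theoretical signal.
#' Values below 1 mean the optimization improved on the raw theory;
#' independent of the grid size.
#'
#' @param model,theory,exp [signal_matrix()] objects (or matrices) on one
#'   grid: optimized model, unweighted theory, experiment.
#' @return Scalar RAE.
#' @export
rae <- function(model, theory, exp) {
  mv <- .vals(model); tv <- .vals(theory); ev <- .vals(exp)
  if (!identical(dim(mv), dim(ev)) || !identical(dim(tv), dim(ev)))
    stop("all three signals must share one grid", call. = FALSE)
  den <- sum(abs(tv - ev))
  if (den == 0)
    stop("unweighted theory equals experiment: RAE undefined", call. = FALSE)
  sum(abs(mv - ev)) / den
}

.vals <- function(x) if (inherits(x, "signal_matrix")) x$values else
  as.matrix(x)

#' Root mean squared error
#'
#' @param model,exp Signals (or matrices) on one grid.
#' @return Scalar RMSE over the full `N_q x N_t` grid.
#' @export
rmse <- function(model, exp) {
  mv <- .vals(model); ev <- .vals(exp)
  if (!identical(dim(mv), dim(ev)))
    stop("model and experiment shapes differ", call. = FALSE)
  sqrt(mean((mv - ev)^2))
}

#' Variance of a weight vector
#'
#' Mean squared deviation of the `N_TBF` weights from their mean;
#' characterizes how concentrated a particular solution is.
#'
#' @param w Normalized weight vector.
#' @return Scalar variance (population form, divisor `N_TBF`).
#' @export
weight_variance <- function(w) {
  w <- check_weights(w)
  mean((w - mean(w))^2)
}

#' Distance from the best weight set
#'
#' Euclidean distance between two weight vectors; conventionally reported
#' squared (`D_b^2`) when comparing many solutions to the best one.
#'
#' @param w A weight vector.
#' @param w_best The reference (best) weight vector, same length.
#' @return Scalar `D_b >= 0`.
#' @export
distance_to_best <- function(w, w_best) {
  if (length(w) != length(w_best))
    stop("weight vectors must have equal length", call. = FALSE)
  sqrt(sum((w - w_best)^2))
}

#' Fit-quality report
#'
#' @param F Target-function value.
#' @param rae Relative absolute error.
#' @param rmse Root mean squared error.
#' @param var_w Weight variance.
#' @param d_b Distance to the best weights (optional).
#' @return An object of class `fit_report`.
#' @export
fit_report <- function(F, rae = NA_real_, rmse = NA_real_,
                       var_w = NA_real_, d_b = NA_real_) {
  stopifnot(F >= 0)
  structure(list(F = F, rae = rae, rmse = rmse, var_w = var_w, d_b = d_b),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("<fit_report: F = %.6g, RAE = %.4g, RMSE = %.4g, Var_w = %.4g%s>\n",
              x$F, x$rae, x$rmse, x$var_w,
              if (is.na(x$d_b)) "" else sprintf(", D_b = %.4g", x$d_b)))
  invisible(x)
}
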