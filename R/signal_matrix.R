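# Signals on a (q, t) grid: the container shared by experimental,
# theoretical and model percent-difference signals.

#' Signal on a (q, t) grid
#'
#' @param q Strictly increasing momentum-transfer grid (inverse Angstrom).
#' @param t Strictly increasing time grid (fs).
#' @param values Numeric matrix, `length(q)` rows by `length(t)` columns.
#' @param unit Free-form unit tag, e.g. `"percent"` or `"intensity"`.
#' @return An object of class `signal_matrix` with fields `q`, `t`,
#'   `values`, `unit`.
#' @export
signal_matrix <- function(q, t, values, unit = "intensity") {
  q <- as.numeric(q); t <- as.numeric(t)
  values <- as.matrix(values)
  if (length(q) < 1L || any(!is.finite(q)) || is.unsorted(q, strictly = TRUE))
    stop("q grid must be finite and strictly increasing", call. = FALSE)
  if (length(t) < 1L || any(!is.finite(t)) || is.unsorted(t, strictly = TRUE))
    stop("t grid must be finite and strictly increasing", call. = FALSE)
  if (nrow(values) != length(q) || ncol(values) != length(t))
    stop(sprintf("values must be %d x %d (|q| x |t|), got %d x %d",
                 length(q), length(t), nrow(values), ncol(values)),
         call. = FALSE)
  if (any(!is.finite(values)))
    stop("signal values must all be finite", call. = FALSE)
  structure(list(q = q, t = t, values = unname(values), unit = unit),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("<signal_matrix %d q x %d t [%s]>\n", length(x$q),
              length(x$t), x$unit))
  cat(sprintf("  q: %.4g .. %.4g 1/Angstrom; t: %.4g .. %.4g fs\n",
              min(x$q), max(x$q), min(x$t), max(x$t)))
  cat(sprintf("  values: %.4g .. %.4g\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.signal_matrix <- function(x) dim(x$values)

.check_same_grid <- function(a, b, what = "signal") {
  if (length(a$q) != length(b$q) || length(a$t) != length(b$t) ||
      max(abs(a$q - b$q)) > 1e-9 || max(abs(a$t - b$t)) > 1e-9)
    stop(sprintf("%s grids do not match", what), call. = FALSE)
  invisible(TRUE)
}

#' Read a signal matrix from delimited text
#'
#' Format: first row holds the time grid (fs), first column the q grid
#' (inverse Angstrom), the body the signal values. An optional companion
#' file of per-point standard deviations must share the exact shape.
#'
#' @param path Path to the signal file.
#' @param sigma_path Optional path to the standard-deviation file.
#' @param unit Unit tag attached to the result.
#' @return A `signal_matrix`; when `sigma_path` is given, the result carries
#'   the matrix of standard deviations in attribute-free field `sigma`.
#' @export
read_signal_matrix <- function(path, sigma_path = NULL, unit = "percent") {
  m <- .read_grid_file(path)
  sig <- signal_matrix(m$q, m$t, m$values, unit = unit)
  if (!is.null(sigma_path)) {
    s <- .read_grid_file(sigma_path)
    if (!identical(dim(s$values), dim(sig$values)))
      stop(sprintf("sigma file shape %d x %d does not match signal %d x %d",
                   nrow(s$values), ncol(s$values), nrow(sig$values),
                   ncol(sig$values)), call. = FALSE)
    sig$sigma <- s$values
  }
  sig
}

.read_grid_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  split1 <- strsplit(lines, "\t", fixed = TRUE)
  t <- as.numeric(split1[[1]][-1])
  body <- split1[-1]
  q <- vapply(body, function(r) as.numeric(r[1]), numeric(1))
  vals <- t(vapply(body, function(r) as.numeric(r[-1]),
                   numeric(length(t))))
  vals <- matrix(vals, nrow = length(q))
  if (anyNA(t) || anyNA(q) || anyNA(vals))
    stop(sprintf("non-numeric entries in %s", path), call. = FALSE)
  if (is.unsorted(t, strictly = TRUE))
    stop("time axis must be strictly increasing", call. = FALSE)
  if (is.unsorted(q, strictly = TRUE))
    stop("q axis must be strictly increasing", call. = FALSE)
  list(q = q, t = t, values = vals)
}

#' Write a signal matrix as delimited text
#'
#' Inverse of [read_signal_matrix()]; values are written with 17 significant
#' digits so a read/write round trip is exact in double precision.
#'
#' @param x A `signal_matrix` (or a bare numeric matrix together with `q`
#'   and `t`).
#' @param path Output path.
#' @param q,t Grids, only needed when `x` is a bare matrix.
#' @return `path`, invisibly.
#' @export
write_signal_matrix <- function(x, path, q = NULL, t = NULL) {
  if (inherits(x, "signal_matrix")) {
    q <- x$q; t <- x$t; v <- x$values
  } else {
    v <- as.matrix(x)
  }
  fmt <- function(z) sprintf("%.17g", z)
  header <- paste(c("q_by_t", fmt(t)), collapse = "\t")
  rows <- vapply(seq_along(q), function(i)
    paste(c(fmt(q[i]), fmt(v[i, ])), collapse = "\t"), character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}
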