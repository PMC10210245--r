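# Reading, validating and time-aligning trajectory ensembles.
#
# Trajectories arrive as multi-frame XYZ files (atom-count line, comment
# line carrying "t = <fs>", then element + Cartesian coordinates in
# Angstrom). All trajectories of an ensemble are resampled onto one model
# time grid by per-coordinate linear interpolation; propagator steps are on
# the fs scale, where the interpolation error is negligible compared to the
# scattering signal changes.

#' Construct a trajectory
#'
#' @param id Trajectory identifier.
#' @param times Strictly increasing time stamps (fs).
#' @param symbols Element symbols, one per atom.
#' @param positions Numeric array `n_atoms x 3 x n_frames` (Angstrom).
#' @param label Non-empty class tag, e.g. `"bound"`, `"open"`, `"triplet"`.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(id, times, symbols, positions, label) {
  times <- as.numeric(times)
  if (length(times) < 1L || is.unsorted(times, strictly = TRUE))
    stop("trajectory times must be strictly increasing", call. = FALSE)
  if (!is.character(label) || !nzchar(label))
    stop("trajectory label must be a non-empty string", call. = FALSE)
  positions <- array(as.numeric(positions),
                     dim = c(length(symbols), 3L, length(times)))
  if (any(!is.finite(positions)))
    stop("trajectory positions must be finite", call. = FALSE)
  for (sym in unique(symbols)) atomic_species(sym)  # validates support
  structure(list(id = as.character(id), times = times,
                 symbols = as.character(symbols), positions = positions,
                 label = label),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory '%s' [%s]: %d atoms (%s), %d frames, %g .. %g fs>\n",
              x$id, x$label, length(x$symbols),
              paste(x$symbols, collapse = ""), length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Read a multi-frame XYZ trajectory
#'
#' Each frame is `n_atoms`, a comment line containing a time stamp of the
#' form `t = <value>` (fs), then one `symbol x y z` line per atom.
#'
#' @param path Path to the XYZ file.
#' @param label Class tag to attach (`"bound"`, `"open"`, ...).
#' @param id Trajectory id; defaults to the file name without extension.
#' @return A [trajectory()].
#' @export
read_trajectory_xyz <- function(path, label, id = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  i <- 1L; frame <- 0L
  times <- numeric(0); frames <- list(); symbols <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    frame <- frame + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L)
      stop(sprintf("frame %d of %s: bad atom-count line '%s'",
                   frame, path, lines[i]), call. = FALSE)
    if (i + 1L + nat > length(lines))
      stop(sprintf("frame %d of %s: truncated frame", frame, path),
           call. = FALSE)
    tm <- regmatches(lines[i + 1L],
                     regexec("t\\s*=\\s*([-+0-9.eE]+)", lines[i + 1L]))[[1]]
    if (length(tm) < 2L)
      stop(sprintf("frame %d of %s: no 't = <fs>' time stamp in comment line",
                   frame, path), call. = FALSE)
    atom_lines <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(atom_lines), "\\s+")
    if (any(vapply(toks, length, integer(1)) < 4L))
      stop(sprintf("frame %d of %s: malformed atom line", frame, path),
           call. = FALSE)
    sym <- vapply(toks, `[`, character(1), 1L)
    xyz <- t(vapply(toks, function(z) as.numeric(z[2:4]), numeric(3)))
    if (anyNA(xyz))
      stop(sprintf("frame %d of %s: non-numeric coordinates", frame, path),
           call. = FALSE)
    if (is.null(symbols)) {
      symbols <- sym
    } else if (length(sym) != length(symbols) || any(sym != symbols)) {
      stop(sprintf("frame %d of %s: atom list differs from frame 1",
                   frame, path), call. = FALSE)
    }
    times <- c(times, as.numeric(tm[2]))
    frames[[frame]] <- xyz
    i <- i + 2L + nat
  }
  if (frame == 0L) stop(sprintf("no frames in %s", path), call. = FALSE)
  ord <- order(times)
  pos <- array(NA_real_, dim = c(length(symbols), 3L, frame))
  for (k in seq_len(frame)) pos[, , k] <- frames[[ord[k]]]
  trajectory(id, times[ord], symbols, pos, label)
}

#' Write a trajectory as multi-frame XYZ
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_xyz <- function(traj, path) {
  out <- character(0)
  nat <- length(traj$symbols)
  for (k in seq_along(traj$times)) {
    out <- c(out, as.character(nat),
             sprintf("t = %.17g fs", traj$times[k]),
             sprintf("%-2s %.12f %.12f %.12f", traj$symbols,
                     traj$positions[, 1, k], traj$positions[, 2, k],
                     traj$positions[, 3, k]))
  }
  writeLines(out, path)
  invisible(path)
}

#' Assemble a time-aligned trajectory ensemble
#'
#' Every trajectory is resampled onto `model_times` by linear interpolation
#' of each Cartesian coordinate. Trajectories that end before the last
#' model time are handled by the edge policy: `"hold"` (default) freezes
#' the last frame — dissociative trajectories have reached their
#' asymptote — while `"strict"` raises a coverage error.
#'
#' @param trajectories List of [trajectory()] objects sharing one ordered
#'   species list.
#' @param model_times Strictly increasing common time grid (fs).
#' @param edge `"hold"` or `"strict"`.
#' @return An object of class `trajectory_ensemble` with fields
#'   `positions` (array `n_atoms x 3 x n_times x n_tbf`), `symbols`, `ids`,
#'   `labels`, `model_times`, `n_tbf`.
#' @export
build_ensemble <- function(trajectories, model_times,
                           edge = c("hold", "strict")) {
  edge <- match.arg(edge)
  model_times <- as.numeric(model_times)
  if (is.unsorted(model_times, strictly = TRUE))
    stop("model_times must be strictly increasing", call. = FALSE)
  if (length(trajectories) < 1L)
    stop("at least one trajectory is required", call. = FALSE)
  symbols <- trajectories[[1]]$symbols
  for (tr in trajectories) {
    if (length(tr$symbols) != length(symbols) || any(tr$symbols != symbols))
      stop(sprintf(paste0("trajectory '%s': species list (%s) differs from ",
                          "'%s' (%s); no reordering is attempted"),
                   tr$id, paste(tr$symbols, collapse = ""),
                   trajectories[[1]]$id, paste(symbols, collapse = "")),
           call. = FALSE)
  }
  n_tbf <- length(trajectories)
  nat <- length(symbols)
  held <- character(0)
  pos <- array(NA_real_,
               dim = c(nat, 3L, length(model_times), n_tbf))
  for (n in seq_len(n_tbf)) {
    tr <- trajectories[[n]]
    if (model_times[1] < tr$times[1] - 1e-9)
      stop(sprintf("trajectory '%s' starts at %g fs, after model start %g fs",
                   tr$id, tr$times[1], model_times[1]), call. = FALSE)
    if (model_times[length(model_times)] > tr$times[length(tr$times)] + 1e-9) {
      if (edge == "strict")
        stop(sprintf(paste0("trajectory '%s' ends at %g fs, before model end ",
                            "%g fs (edge policy 'strict')"), tr$id,
                     tr$times[length(tr$times)],
                     model_times[length(model_times)]), call. = FALSE)
      held <- c(held, tr$id)
    }
    same_grid <- length(tr$times) == length(model_times) &&
      max(abs(tr$times - model_times)) <= 1e-12
    for (a in seq_len(nat)) for (d in 1:3) {
      pos[a, d, , n] <- if (same_grid) tr$positions[a, d, ] else
        stats::approx(tr$times, tr$positions[a, d, ], xout = model_times,
                      rule = 2)$y
    }
  }
  if (length(held))
    message(sprintf("build_ensemble: hold-last-frame applied to %d trajectories (%s)",
                    length(held), paste(held, collapse = ", ")))
  structure(list(positions = pos, symbols = symbols,
                 ids = vapply(trajectories, `[[`, character(1), "id"),
                 labels = vapply(trajectories, `[[`, character(1), "label"),
                 model_times = model_times, n_tbf = n_tbf),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("<trajectory_ensemble: %d TBFs, %d atoms (%s), %d model times %g .. %g fs>\n",
              x$n_tbf, length(x$symbols), paste(x$symbols, collapse = ""),
              length(x$model_times), min(x$model_times), max(x$model_times)))
  tab <- table(x$labels)
  cat("  labels:", paste(sprintf("%s = %d", names(tab), tab),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Read a trajectory manifest
#'
#' Tab-delimited text with a header line `trajectory_id  path  label`;
#' relative paths are resolved against the manifest directory.
#'
#' @param path Manifest path.
#' @return List of [trajectory()] objects.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("trajectory_id", "path", "label")
  if (!all(need %in% names(df)))
    stop(sprintf("manifest must have columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  base <- dirname(path)
  lapply(seq_len(nrow(df)), function(i) {
    p <- df$path[i]
    if (!file.exists(p)) p <- file.path(base, df$path[i])
    read_trajectory_xyz(p, label = df$label[i], id = df$trajectory_id[i])
  })
}

#' Extract a single geometry
#'
#' @param ensemble_or_traj A `trajectory_ensemble` or `trajectory`.
#' @param frame Frame index on the object's time grid.
#' @param tbf Trajectory index (ensembles only).
#' @return List with `symbols` and an `n_atoms x 3` position matrix.
#' @export
get_geometry <- function(ensemble_or_traj, frame = 1L, tbf = 1L) {
  x <- ensemble_or_traj
  p <- if (inherits(x, "trajectory_ensemble"))
    x$positions[, , frame, tbf] else x$positions[, , frame]
  list(symbols = x$symbols, positions = matrix(p, ncol = 3))
}
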