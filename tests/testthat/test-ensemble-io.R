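# Trajectory and signal I/O: parsing, validation, time alignment.

test_that("multi-frame XYZ files round-trip through read and write", {
  path <- withr::local_tempfile(fileext = ".xyz")
  frames <- list(rbind(c(0, 0, 0), c(0, 0, -1.55), c(0, 0, 1.55)),
                 rbind(c(0, 0, 0.01), c(0, 0, -1.6), c(0, 0, 1.6)))
  write_xyz_text(path, c("C", "S", "S"), frames, c(0, 0.5))
  tr <- read_trajectory_xyz(path, label = "bound")
  expect_equal(tr$times, c(0, 0.5))
  expect_equal(dim(tr$positions), c(3L, 3L, 2L))
  expect_equal(tr$positions[, , 2], frames[[2]], tolerance = 1e-12)
  zs <- vapply(tr$symbols, function(s) atomic_species(s)$Z, integer(1))
  expect_equal(unname(zs), c(6L, 16L, 16L))

  out <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory_xyz(tr, out)
  tr2 <- read_trajectory_xyz(out, label = "bound")
  expect_equal(tr2$times, tr$times)
  expect_equal(tr2$positions, tr$positions, tolerance = 1e-10)
})

test_that("malformed XYZ input is rejected with the frame index", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "t = 0 fs",
               "C 0 0 0", "S 0 0 -1.5", "S 0 0 1.5",
               "2", "t = 10 fs",
               "C 0 0 0", "S 0 0 -1.5"), path)
  expect_error(read_trajectory_xyz(path, label = "x"), "frame 2")
  writeLines(c("2", "no timestamp here", "C 0 0 0", "S 0 0 1"), path)
  expect_error(read_trajectory_xyz(path, label = "x"), "time stamp")
})

test_that("build_ensemble interpolates linearly onto the model grid", {
  pos <- array(0, dim = c(2, 3, 3))
  pos[1, 3, ] <- c(0, 1, 4)       # nonlinear course to expose interpolation
  pos[2, 1, ] <- c(1, 1, 1)
  tr <- trajectory("a", c(0, 10, 20), c("C", "S"), pos, "bound")
  ens <- build_ensemble(list(tr), c(0, 5, 10, 15, 20))
  expect_equal(ens$positions[1, 3, , 1], c(0, 0.5, 1, 2.5, 4))
  # identity on the trajectory's own grid is bit-exact
  ens2 <- build_ensemble(list(tr), c(0, 10, 20))
  expect_identical(ens2$positions[, , , 1], pos)
})

test_that("interpolated positions are bounded by the bracketing frames", {
  set.seed(3)
  pos <- array(stats::rnorm(3 * 3 * 6), dim = c(3, 3, 6))
  tr <- trajectory("r", seq(0, 100, by = 20), c("C", "O", "H"), pos, "x")
  fine <- build_ensemble(list(tr), seq(0, 100, by = 5))
  for (k in seq_len(5)) {
    seg <- fine$positions[, , (4 * (k - 1) + 1):(4 * k + 1), 1]
    lo <- pmin(pos[, , k], pos[, , k + 1]); hi <- pmax(pos[, , k], pos[, , k + 1])
    expect_true(all(seg >= array(lo, dim(seg)) - 1e-12))
    expect_true(all(seg <= array(hi, dim(seg)) + 1e-12))
  }
})

test_that("species mismatches and short trajectories honour the edge policy", {
  p1 <- array(0, dim = c(2, 3, 2)); p2 <- p1
  t1 <- trajectory("a", c(0, 10), c("C", "S"), p1, "x")
  t2 <- trajectory("b", c(0, 10), c("S", "C"), p2, "x")
  expect_error(build_ensemble(list(t1, t2), c(0, 10)), "species list")
  short <- trajectory("s", c(0, 5), c("C", "S"), p1, "x")
  expect_error(build_ensemble(list(short), c(0, 5, 10), edge = "strict"),
               "ends at")
  expect_message(ens <- build_ensemble(list(short), c(0, 5, 10),
                                       edge = "hold"), "hold-last")
  expect_equal(ens$positions[, , 3, 1], ens$positions[, , 2, 1])
})

test_that("signal matrices round-trip exactly and reject bad axes", {
  q <- c(0.5, 1.37, 2.9); t <- c(-10, 0, 25.5, 100)
  vals <- matrix(stats::rnorm(12), 3, 4)
  sig <- signal_matrix(q, t, vals)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signal_matrix(sig, path)
  back <- read_signal_matrix(path)
  expect_identical(back$q, q)
  expect_identical(back$t, t)
  expect_identical(back$values, vals)

  expect_error(signal_matrix(c(1, 1, 2), t, matrix(0, 3, 4)),
               "strictly increasing")
  expect_error(signal_matrix(q, t, matrix(0, 4, 4)), "values must be")
  # duplicated q row in a file
  lines <- readLines(path)
  writeLines(c(lines, lines[2]), path)
  expect_error(read_signal_matrix(path), "strictly increasing")
})

test_that("sigma companion files must match the signal shape", {
  q <- 1:3; t <- 1:4
  sig <- signal_matrix(q, t, matrix(1, 3, 4))
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_signal_matrix(sig, p1)
  write_signal_matrix(signal_matrix(q, t[-4], matrix(1, 3, 3)), p2)
  expect_error(read_signal_matrix(p1, p2), "shape")
  write_signal_matrix(signal_matrix(q, t, matrix(0.5, 3, 4)), p2)
  ok <- read_signal_matrix(p1, p2)
  expect_equal(ok$sigma, matrix(0.5, 3, 4))
})

test_that("manifests resolve relative paths and attach labels", {
  dir <- withr::local_tempdir()
  frames <- list(rbind(c(0, 0, 0), c(0, 0, 1.5)))
  write_xyz_text(file.path(dir, "t1.xyz"), c("C", "S"), frames, 0)
  write_xyz_text(file.path(dir, "t2.xyz"), c("C", "S"), frames, 0)
  writeLines(c("trajectory_id\tpath\tlabel",
               "tr1\tt1.xyz\tbound", "tr2\tt2.xyz\tdissociative"),
             file.path(dir, "manifest.tsv"))
  trajs <- read_manifest(file.path(dir, "manifest.tsv"))
  expect_length(trajs, 2L)
  expect_equal(vapply(trajs, `[[`, character(1), "label"),
               c("bound", "dissociative"))
})
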