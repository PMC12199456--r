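# Trajectory pipeline: XYZ I/O, internal-coordinate features, PCA reduction,
# per-frame clustering, channel assembly, and the branching-ensemble
# generator.

test_that("multi-frame XYZ files round-trip through write and read", {
  set.seed(4)
  coords <- array(rnorm(2 * 5 * 3, sd = 2), c(2, 5, 3))
  paths <- replicate(3, tempfile(fileext = ".xyz"))
  for (p in paths) write_xyz_trajectory(coords, c("C", "C", "H", "H", "O"), p)
  ens <- read_xyz_trajectories(paths, dt = 0.5)
  expect_equal(dim(ens$coords), c(3L, 2L, 5L, 3L))
  expect_equal(ens$coords[2, , , ], coords, tolerance = 1e-6)
  expect_equal(ens$elements, c("C", "C", "H", "H", "O"))
  expect_equal(ens$times, c(0, 0.5))
  unlink(paths)
})

test_that("malformed and inconsistent XYZ input is reported with context", {
  bad <- tempfile(fileext = ".xyz")
  writeLines(c("2", "frame 1", "C 0 0 0", "C 1 oops 0"), bad)
  expect_error(read_xyz_trajectories(bad), "line 4")
  ok <- tempfile(fileext = ".xyz")
  writeLines(c("1", "f", "C 0 0 0"), ok)
  other <- tempfile(fileext = ".xyz")
  writeLines(c("2", "f", "C 0 0 0", "C 1 1 1"), other)
  expect_error(read_xyz_trajectories(c(ok, other)), "atom counts")
  unlink(c(bad, ok, other))
})

# analytic four-atom geometry with prescribed pair distances
square_coords <- function(w = 2, l = 1.5) {
  rbind(c(-w / 2,  l / 2, 0), c(w / 2,  l / 2, 0),
        c(w / 2, -l / 2, 0), c(-w / 2, -l / 2, 0))
}

test_that("distance features follow their defining formulas", {
  g <- square_coords(w = 2, l = 1.5)
  coords <- array(0, c(1, 2, 4, 3))
  coords[1, 1, , ] <- g
  coords[1, 2, , ] <- g
  ens <- structure(list(coords = coords, elements = rep("C", 4),
                        times = c(0, 1)), class = "donkey_ensemble")
  ft <- compute_features(ens)
  expect_equal(ft$values[1, 1, 1], 2)            # wing separation = R12
  expect_equal(ft$values[1, 1, 2], 0)            # symmetric: R13 = R24
  expect_equal(ft$values[1, 1, 3], 1.5)          # wing length = R14
  expect_true(all(abs(ft$values[1, , 4:6]) < 1e-12))  # static: zero rates
})

test_that("features are invariant under rigid motion, so rates vanish for it", {
  set.seed(6)
  g <- square_coords()
  n_frames <- 6L
  coords <- array(0, c(1, n_frames, 4, 3))
  th <- seq(0, 1, length.out = n_frames)
  for (f in seq_len(n_frames)) {
    R <- rbind(c(cos(th[f]), -sin(th[f]), 0),
               c(sin(th[f]),  cos(th[f]), 0),
               c(0, 0, 1))
    coords[1, f, , ] <- g %*% t(R) +
      matrix(c(3 * th[f], -th[f], 2 * th[f]), 4, 3, byrow = TRUE)
  }
  ens <- structure(list(coords = coords, elements = rep("C", 4),
                        times = seq_len(n_frames) - 1),
                   class = "donkey_ensemble")
  ft <- compute_features(ens)
  expect_lt(max(abs(sweep(ft$values[1, , 1:3, drop = FALSE], 3,
                          ft$values[1, 1, 1:3]))), 1e-10)
  expect_lt(max(abs(ft$values[1, , 4:6])), 1e-10)
})

test_that("PCA reduction keeps exactly the above-threshold components", {
  set.seed(14)
  # data on an exact 2-D plane embedded in 6-D
  basis <- qr.Q(qr(matrix(rnorm(36), 6)))[, 1:2]
  scores <- matrix(rnorm(200), ncol = 2L) %*% diag(c(3, 1))
  flat <- scores %*% t(basis)
  red <- reduce_features(flat)
  expect_equal(ncol(red), 2L)
  # isotropic 6-D data keeps all six (each ratio near 1/6)
  iso <- matrix(rnorm(6 * 400), ncol = 6L)
  expect_equal(ncol(reduce_features(iso)), 6L)
  # retained explained variance obeys the threshold bound
  evr <- attr(reduce_features(iso), "evr")
  expect_gte(sum(evr), 1 - (6 - length(evr)) * 0.01)
  # zero variance: single zero column with a warning
  expect_warning(z <- reduce_features(matrix(1, 10, 6)), "zero-variance")
  expect_equal(dim(z), c(10L, 1L))
  expect_true(all(z == 0))
})

test_that("an ensemble of identical trajectories forms one cluster per frame", {
  b <- make_branching_ensemble(n_traj = 12L, n_frames = 11L, dt = 1,
                               branch_times = c(100, 200), noise_sd = 0,
                               seed = 1)
  ft <- compute_features(b$ensemble)
  fr <- suppressMessages(suppressWarnings(cluster_frames(ft, frame_interval = 5)))
  expect_equal(names(fr), c("t=0", "t=5", "t=10"))
  for (r in fr) expect_equal(r$n_clusters, 1L)
})

test_that("the branching fixture is recovered exactly at zero noise", {
  b <- make_branching_ensemble(n_traj = 16L, noise_sd = 0, seed = 2)
  # trajectories coincide with their templates in feature space
  ft <- compute_features(b$ensemble)
  for (i in c(1, 9, 16)) {
    tpl <- b$templates[[b$truth_channels[i]]]
    expect_equal(ft$values[i, , 1:3], unname(as.matrix(tpl)),
                 tolerance = 1e-7, ignore_attr = TRUE)
  }
  fr <- suppressMessages(suppressWarnings(cluster_frames(ft, frame_interval = 5)))
  ch <- assemble_channels(fr, c(20, 35))
  expect_equal(length(unique(ch$channel)), 4L)
  expect_equal(v_measure(b$truth_channels, ch$channel)$v_measure, 1)
})

test_that("channel recovery survives moderate noise and splits time-shifted paths", {
  b <- make_branching_ensemble(n_traj = 24L, noise_sd = 0.03, seed = 5)
  ft <- compute_features(b$ensemble)
  fr <- suppressMessages(suppressWarnings(cluster_frames(ft, frame_interval = 5)))
  ch <- assemble_channels(fr, c(20, 35))
  # recovery = fraction of trajectories whose channel traces back to a
  # single generating path (a pure split channel still recovers its
  # trajectories)
  tab <- table(b$truth_channels, ch$channel)
  expect_gte(sum(apply(tab, 2, max)) / sum(tab), 0.95)
  # two spatially identical paths, one delayed past the checkpoint,
  # land in different channels
  times <- 0:40
  ramp <- function(t0) 0.5 * (1 + tanh((times - t0) / 3))
  mk <- function(t0) cbind(2.5 - 0.8 * ramp(t0), 0.4 * ramp(t0),
                           rep(1.5, 41))
  b2 <- make_branching_ensemble(n_traj = 10L, n_frames = 41L, dt = 1,
                                path_templates = list(mk(10), mk(30)),
                                noise_sd = 0.01, seed = 3)
  ft2 <- compute_features(b2$ensemble)
  fr2 <- suppressMessages(suppressWarnings(
    cluster_frames(ft2, frame_interval = 5)))
  # checkpoints inside the delay window, where one path has moved and the
  # other has not
  ch2 <- assemble_channels(fr2, c(10, 20))
  expect_equal(v_measure(b2$truth_channels, ch2$channel)$v_measure, 1)
  expect_error(assemble_channels(fr2, c(21)), "checkpoint")
})

test_that("branching ensembles are reproducible and evenly split", {
  a <- make_branching_ensemble(n_traj = 10L, seed = 4)
  b <- make_branching_ensemble(n_traj = 10L, seed = 4)
  expect_identical(a$ensemble$coords, b$ensemble$coords)
  expect_equal(as.integer(table(a$truth_channels)), c(3L, 3L, 2L, 2L))
  expect_error(make_branching_ensemble(path_templates = list(matrix(1, 3, 3)),
                                       n_frames = 41L), "n_frames")
})
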