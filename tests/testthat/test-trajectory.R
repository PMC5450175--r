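test_that("contact matrices use a strict Euclidean cut-off", {
  two <- function(sep) rbind(c(0, 0, 0), c(sep, 0, 0))
  expect_equal(contact_matrix(two(5), d = 13)[1, 2], 1)
  expect_equal(contact_matrix(two(20), d = 13)[1, 2], 0)
  # exact equality counts as no contact
  expect_equal(contact_matrix(two(13), d = 13)[1, 2], 0)

  # atoms on a line at 0, 6, 12, 18 with d = 7: only consecutive pairs touch
  line <- cbind(c(0, 6, 12, 18), 0, 0)
  B <- contact_matrix(line, d = 7)
  expect_equal(B, rbind(c(0, 1, 0, 0), c(1, 0, 1, 0),
                        c(0, 1, 0, 1), c(0, 0, 1, 0)))
  expect_true(isSymmetric(B))
  expect_true(all(diag(B) == 0))
  expect_error(contact_matrix(rbind(c(0, 0, NA), c(1, 1, 1)), 5), "finite")
  expect_error(contact_matrix(line, d = -1), "positive")
})

test_that("edge sets grow monotonically with the cut-off", {
  set.seed(40)
  coords <- matrix(runif(30, 0, 20), 10, 3)
  prev <- NULL
  for (d in c(5, 8, 11, 14)) {
    B <- contact_matrix(coords, d)
    if (!is.null(prev)) expect_true(all(B >= prev))
    prev <- B
  }
})

test_that("contact probability is the time average of per-frame contacts", {
  # one pair: in contact in 3 of 4 frames
  seps <- c(5, 5, 20, 5)
  coords <- array(0, c(4, 2, 3))
  coords[, 2, 1] <- seps
  traj <- as_trajectory(coords)
  P <- contact_probability(traj, d = 13)
  expect_equal(P[1, 2], 0.75)

  # oracle on a random trajectory: recompute per frame and average
  set.seed(41)
  traj2 <- generate_synthetic_trajectory(8, 20, seed = 41)
  P2 <- contact_probability(traj2, 13)
  manual <- Reduce(`+`, lapply(1:20, function(t) {
    contact_matrix(traj2, 13, frame = t)
  })) / 20
  expect_equal(unname(P2), manual)
  expect_true(all(P2 >= 0 & P2 <= 1))
  expect_true(isSymmetric(P2))
})

test_that("RMSF measures fluctuation about the time-averaged position", {
  # static atom
  static <- as_trajectory(array(rep(c(1, 2, 3), each = 4), c(4, 1, 3)))
  expect_equal(unname(rmsf(static)), 0)

  # atom alternating between (0,0,0) and (2,0,0): mean (1,0,0), deviation 1
  alt <- array(0, c(4, 1, 3))
  alt[c(2, 4), 1, 1] <- 2
  expect_equal(unname(rmsf(as_trajectory(alt))), 1)

  traj <- generate_synthetic_trajectory(6, 30, seed = 2)
  expect_equal(unname(delta_rmsf(traj, traj)), rep(0, 6))

  # a constant offset applied to every frame leaves RMSF unchanged
  shifted <- traj
  shifted$coords <- traj$coords + 100
  expect_equal(rmsf(shifted), rmsf(traj))
})

test_that("multi-model PDB files are reduced to one atom per residue", {
  coords <- list(rbind(c(0, 0, 0), c(6, 0, 0), c(12, 0, 0)),
                 rbind(c(0, 0, 1), c(6, 0, 1), c(12, 0, 1)))
  f <- tempfile(fileext = ".pdb")
  writeLines(pdb_lines(coords), f)
  traj <- read_trajectory(f, atom = "C3'")
  expect_equal(traj$n_frames, 2L)
  expect_equal(traj$n_atoms, 3L)
  expect_equal(traj$coords[1, , ], coords[[1]])
  expect_equal(traj$coords[2, , ], coords[[2]])
  expect_equal(traj$labels, c("G1", "G2", "G3"))

  # selecting the backbone P instead picks the other atom record
  trajP <- read_trajectory(f, atom = "P")
  expect_equal(trajP$coords[1, , ], coords[[1]])
})

test_that("PDB models missing the selected atom are rejected by residue", {
  coords <- list(rbind(c(0, 0, 0), c(6, 0, 0), c(12, 0, 0)),
                 rbind(c(0, 0, 1), c(6, 0, 1), c(12, 0, 1)))
  f <- tempfile(fileext = ".pdb")
  writeLines(pdb_lines(coords, drop_c3 = cbind(2, 2)), f)
  expect_error(read_trajectory(f, atom = "C3'"), "residue A:2 .* in model 2")
})

test_that("PDB coordinates agree with bio3d's reader", {
  coords <- list(rbind(c(1.5, -2.25, 3), c(7.125, 0, -1)),
                 rbind(c(1.5, -2.25, 4), c(7.125, 1, -1)))
  f <- tempfile(fileext = ".pdb")
  writeLines(pdb_lines(coords), f)
  traj <- read_trajectory(f, atom = "C3'")
  ref <- bio3d::read.pdb(f, multi = TRUE)
  sel <- bio3d::atom.select(ref, elety = "C3'")
  ref_xyz <- matrix(ref$xyz[, sel$xyz], nrow = 2, byrow = FALSE)
  for (m in 1:2) {
    expect_equal(matrix(ref_xyz[m, ], ncol = 3, byrow = TRUE),
                 traj$coords[m, , ], tolerance = 1e-6)
  }
})

test_that("XYZ tables round-trip a synthetic trajectory", {
  traj <- generate_synthetic_trajectory(10, 50, seed = 4)
  f <- tempfile(fileext = ".xyz")
  write_xyz_trajectory(traj, f)
  back <- read_trajectory(f, format = "xyz")
  expect_equal(back$coords, traj$coords, tolerance = 1e-12)
  expect_equal(back$labels, traj$labels)

  # frames with inconsistent atom sets are rejected
  bad <- tempfile()
  writeLines(c("1 A 0 0 0", "1 B 1 0 0", "2 A 0 0 0"), bad)
  expect_error(read_trajectory(bad, format = "xyz"), "inconsistent atoms")
})

test_that("trajectories convert to dynamic contact graphs", {
  # one frame, two atoms 5 apart, d = 13: a single snapshot with one edge
  one <- as_trajectory(rbind(c(0, 0, 0), c(5, 0, 0)))
  g1 <- trajectory_to_dynamic_graph(one, 13)
  expect_equal(g1$tau, 1L)
  expect_equal(g1$initial, cbind(u = 1L, v = 2L))

  # a pair oscillating across the cut-off alternates add/remove batches
  seps <- c(5, 20, 5, 20, 5)
  coords <- array(0, c(5, 2, 3))
  coords[, 2, 1] <- seps
  g2 <- trajectory_to_dynamic_graph(as_trajectory(coords), 13)
  expect_equal(batch_statistics(g2)$delta, rep(1L, 4))
  expect_equal(nrow(g2$batches[[1]]$removals), 1L)
  expect_equal(nrow(g2$batches[[2]]$additions), 1L)

  # per-frame contact oracle on a synthetic run
  traj <- generate_synthetic_trajectory(12, 15, seed = 6)
  g3 <- trajectory_to_dynamic_graph(traj, 13)
  expect_equal(g3$n_vertices, 12L)
  snaps <- replay_snapshots(g3)
  for (t in c(1, 7, 15)) {
    B <- contact_matrix(traj, 13, frame = t)
    expected <- which(upper.tri(B) & B == 1, arr.ind = TRUE)
    expected <- expected[order(expected[, 1], expected[, 2]), , drop = FALSE]
    expect_equal(unname(snaps[[t]]), unname(expected))
  }
})

test_that("the synthetic generator is seeded and physically shaped", {
  t1 <- generate_synthetic_trajectory(20, 10, seed = 11)
  t2 <- generate_synthetic_trajectory(20, 10, seed = 11)
  expect_identical(t1$coords, t2$coords)

  # consecutive beads stay near one backbone step apart (6 A base fold,
  # blurred by the 1.5 A per-coordinate fluctuations and the short average)
  base_mean <- apply(t1$coords, c(2, 3), mean)
  gaps <- sqrt(rowSums((base_mean[-1, ] - base_mean[-20, ])^2))
  expect_true(all(gaps > 2 & gaps < 12))
})
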