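test_that("superposition recovers rigid transforms and is symmetric", {
  set.seed(101)
  x <- matrix(rnorm(45), 15, 3)
  expect_lt(kabsch_superpose(x, x)$rmsd, 1e-10)
  for (i in 1:25) {
    rt <- random_rigid()
    y <- apply_rigid(x, rt)
    f <- kabsch_superpose(y, x)
    expect_lt(f$rmsd, 1e-8)
    expect_equal(det(f$rotation), 1, tolerance = 1e-9)
  }
  x2 <- x + matrix(rnorm(45, sd = 0.5), 15, 3)
  expect_equal(kabsch_superpose(x, x2)$rmsd, kabsch_superpose(x2, x)$rmsd,
               tolerance = 1e-9)
})

test_that("superposition rejects degenerate inputs", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line + 1), "degenerate")
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)),
               "at least 3")
})

test_that("fitted RMSD matches an independent rotation-search oracle", {
  ref <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(0, 0, 3))
  mob <- ref
  mob[4, ] <- mob[4, ] + c(0, 2, 0)   # one point displaced by 2 A
  ours <- kabsch_superpose(mob, ref)$rmsd
  oracle <- oracle_min_rmsd(mob, ref)
  expect_equal(ours, oracle, tolerance = 1e-3)
  # and a noisy pair
  set.seed(7)
  mob2 <- ref + matrix(rnorm(12, sd = 0.4), 4, 3)
  expect_equal(kabsch_superpose(mob2, ref)$rmsd, oracle_min_rmsd(mob2, ref),
               tolerance = 1e-3)
})

test_that("fitted RMSD agrees with the bio3d reference implementation", {
  skip_if_not_installed("bio3d")
  set.seed(13)
  x <- matrix(rnorm(30), 10, 3)
  y <- x + matrix(rnorm(30, sd = 0.7), 10, 3)
  ref <- bio3d::rmsd(as.vector(t(x)), as.vector(t(y)), fit = TRUE)
  expect_equal(kabsch_superpose(y, x)$rmsd, ref, tolerance = 1e-3)
})

test_that("RMSD series is zero for static frames and translated references", {
  sched <- contact_schedule(2, 2, 0)
  traj <- make_dimer_trajectory(sched, n_frames = 5, seed = 3)
  rs <- rmsd_series(traj, "A")
  expect_s3_class(rs, "rmsd_series")
  expect_equal(nrow(rs), 5L)
  expect_true(all(rs$rmsd_A < 1e-10))
  # frame 3 replaced by a translated copy of frame 1: still zero there
  frames <- lapply(seq_len(5), function(k) get_frame(traj, k))
  frames[[3]] <- md_frame(frames[[3]]$atoms,
                          frames[[1]]$xyz + matrix(c(5, -2, 8), 1, 3)[rep(1, nrow(frames[[1]]$xyz)), ],
                          time = frames[[3]]$time)
  t2 <- as_trajectory(frames)
  rs2 <- rmsd_series(t2, "A", reference_frame = 1)
  expect_lt(rs2$rmsd_A[3], 1e-8)
  expect_error(rmsd_series(traj, "A", reference_frame = 9), "index error")
})

test_that("per-frame RMSD equals direct superposition of that frame", {
  sched <- contact_schedule(c(2, 5), c(2, 5), c(50, 100))
  traj <- make_dimer_trajectory(sched, n_frames = 4, noise_sd = 0.3, seed = 21)
  rs <- rmsd_series(traj, "B")
  idx <- atom_select(traj, "B", atom_names = "CA")
  for (k in 1:4) {
    direct <- kabsch_superpose(matrix(traj$xyz[idx, , k], ncol = 3),
                               matrix(traj$xyz[idx, , 1], ncol = 3))$rmsd
    expect_equal(rs$rmsd_A[k], direct, tolerance = 1e-12)
  }
})

test_that("static trajectories have exactly zero RMSF", {
  h <- make_ideal_helix(12)
  traj <- as_trajectory(rep(list(h), 10))
  p <- rmsf_profile(traj, "A")
  expect_identical(unique(p$rmsf_A), 0)
})

test_that("an antiphase two-residue oscillator has RMSF d, others zero", {
  d <- 0.5
  traj <- make_oscillator_trajectory(n_res = 10, d = d, n_frames = 8)
  p <- rmsf_profile(traj, "A")
  moving <- p$residue %in% c(1, 10)
  expect_equal(p$rmsf_A[moving], c(d, d), tolerance = 1e-8)
  expect_lt(max(p$rmsf_A[!moving]), 1e-8)
})

test_that("RMSF is invariant to global rigid motion and frame order", {
  sched <- contact_schedule(c(2, 4), c(2, 4), c(25, 75))
  traj <- make_dimer_trajectory(sched, n_frames = 8, noise_sd = 0.2, seed = 5)
  p0 <- rmsf_profile(traj, "B")
  set.seed(99)
  rt <- random_rigid()
  p1 <- rmsf_profile(transform_trajectory(traj, rt), "B")
  expect_equal(p1$rmsf_A, p0$rmsf_A, tolerance = 1e-6)
  # reorder frames
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  frames <- lapply(perm, function(k) {
    f <- get_frame(traj, k); f$time <- NULL
    f
  })
  frames <- lapply(seq_along(perm), function(i)
    md_frame(get_frame(traj, perm[i])$atoms,
             get_frame(traj, perm[i])$xyz, time = (i - 1) * 10))
  p2 <- rmsf_profile(as_trajectory(frames), "B")
  expect_equal(p2$rmsf_A, p0$rmsf_A, tolerance = 1e-6)
})

test_that("RMSF windows restrict the frames used", {
  d <- 0.4
  traj <- make_oscillator_trajectory(n_res = 8, d = d, n_frames = 8)
  expect_error(rmsf_profile(traj, "A", window = analysis_window(0, 5)),
               "window error")
  p <- rmsf_profile(traj, "A", window = analysis_window(0, 30))
  expect_equal(p$rmsf_A[p$residue == 1], d, tolerance = 1e-8)
})
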