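test_that("multi-model PDB round trip preserves topology and coordinates", {
  sched <- contact_schedule(c(2, 4), c(2, 4), c(50, 100))
  traj <- make_dimer_trajectory(sched, n_frames = 3, noise_sd = 0.2, seed = 11)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(traj, path)
  back <- read_pdb(path)
  expect_equal(n_frames(back), 3L)
  expect_identical(back$atoms$name, traj$atoms$name)
  expect_identical(back$atoms$chain, traj$atoms$chain)
  expect_identical(back$atoms$resid, traj$atoms$resid)
  expect_identical(back$atoms$resname, traj$atoms$resname)
  expect_lt(max(abs(back$xyz - traj$xyz)), 1e-3 + 1e-9)
})

test_that("single-model files parse as one frame and report chains", {
  h <- make_ideal_helix(10)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(h, path)
  traj <- read_pdb(path)
  expect_equal(n_frames(traj), 1L)
  expect_equal(unique(traj$atoms$chain), "A")
  expect_equal(length(unique(traj$atoms$resid)), 10L)
})

test_that("models with inconsistent topology are rejected", {
  h <- make_ideal_helix(6)
  path <- withr::local_tempfile(fileext = ".pdb")
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(h, tmp)
  body <- grep("^ATOM", readLines(tmp), value = TRUE)
  # model 2 lacks the last residue's atoms
  short <- body[seq_len(length(body) - 5L)]
  writeLines(c("MODEL        1", body, "ENDMDL",
               "MODEL        2", short, "ENDMDL", "END"), path)
  expect_error(read_pdb(path), "topology")
})

test_that("malformed ATOM lines and insertion codes are reported by line", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  CA  ALA A   1      bad"), path)
  expect_error(read_pdb(path), "malformed ATOM line at line 1")
  writeLines(c(
    "ATOM      1  CA  ALA A   1A     1.000   2.000   3.000  1.00  0.00"),
    path)
  expect_error(read_pdb(path), "insertion codes")
})

test_that("HETATM records are skipped with a count", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00",
    "ATOM      2  CA  ALA A   2       4.000   2.000   3.000  1.00  0.00",
    "HETATM    3  O   HOH A 101       9.000   9.000   9.000  1.00  0.00"),
    path)
  expect_message(traj <- read_pdb(path), "skipped 1 HETATM")
  expect_equal(nrow(traj$atoms), 2L)
})

test_that("selection is residue-ordered, idempotent and validated", {
  sched <- contact_schedule(3, 3, 100)
  traj <- make_dimer_trajectory(sched, n_frames = 2, seed = 1)
  i1 <- atom_select(traj, "A", 2, 6, "CA")
  i2 <- atom_select(traj, "A", 2, 6, "CA")
  expect_identical(i1, i2)
  expect_equal(attr(i1, "resid"), 2:6)
  expect_equal(length(i1), 5L)
  fr <- get_frame(traj, 1)
  m <- select_coords(fr, "A", 2, 6, "CA")
  expect_equal(dim(m), c(5L, 3L))
  expect_error(atom_select(traj, "Z"), "no chain")
  expect_error(atom_select(traj, "A", 50, 60), "selection error")
  expect_error(atom_select(traj, "A", 1, 5, "OMG"), "absent in residue")
})

test_that("a domain-1-sized region selects one entry per residue", {
  # sparse synthetic chain spanning the enzyme's domain-1 numbering
  n <- 300L
  atoms <- data.frame(serial = seq_len(n), name = "CA", elem = "C",
                      resname = "GLY", chain = "A", resid = seq_len(n))
  fr <- md_frame(atoms, cbind(seq_len(n), 0, (-1)^seq_len(n)))
  sch <- ide_regions("A")
  d1 <- sch[sch$region == "D1", ]
  m <- select_coords(fr, d1$chain, d1$first, d1$last, "CA")
  expect_equal(nrow(m), 285L - 43L + 1L)
  expect_equal(nrow(m), 243L)
})

test_that("trajectory invariants are enforced", {
  h <- make_ideal_helix(6)
  expect_error(as_trajectory(list()), "at least one frame")
  t2 <- as_trajectory(list(h, h))
  expect_equal(t2$times, c(0, 10))
  g <- make_ideal_helix(7)
  expect_error(as_trajectory(list(h, g)), "topology")
  expect_error(md_frame(h$atoms, h$xyz * NA), "finite")
  expect_error(analysis_window(5, 5), "window error")
  expect_error(analysis_window(-1, 5), "window error")
  w <- analysis_window(0, 10)
  expect_equal(window_frames(t2, w), 1:2)
  expect_error(window_frames(t2, analysis_window(100, 200)), "window error")
})

test_that("region schemes reject bad ranges and duplicate names", {
  expect_error(region_scheme(c("a", "a"), "A", c(1, 2), c(3, 4)), "unique")
  expect_error(region_scheme("a", "A", 5, 2), "first")
  sch <- abeta_regions("B")
  expect_equal(sch$last[sch$region == "Nterm"], 16L)
  expect_equal(sch$first[sch$region == "Cterm"], 17L)
})
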