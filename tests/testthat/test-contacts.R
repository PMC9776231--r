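test_that("scheduled occupancies are recovered exactly", {
  sched <- contact_schedule(c(2, 4, 6), c(2, 4, 6), c(85, 0, 100))
  traj <- make_dimer_trajectory(sched, n_frames = 100, noise_sd = 0, seed = 8)
  occ <- hydrophobic_occurrence_map(traj, list(chain = "A"),
                                    list(chain = "B"))
  val <- function(ra, rb) occ$occurrence_pct[occ$resid_a == ra &
                                               occ$resid_b == rb]
  expect_identical(val(2, 2), 85)
  expect_identical(val(4, 4), 0)
  expect_identical(val(6, 6), 100)
  # occurrence values are exact frame counts
  expect_true(all(occ$occurrence_pct * attr(occ, "n_frames") / 100 ==
                    round(occ$occurrence_pct * attr(occ, "n_frames") / 100)))
})

test_that("a 17-in-20-frame pair reports 85 percent", {
  sched <- contact_schedule(3, 3, 85)
  traj <- make_dimer_trajectory(sched, n_frames = 20, seed = 2)
  occ <- hydrophobic_occurrence_map(traj, list(chain = "A"),
                                    list(chain = "B"))
  expect_identical(occ$occurrence_pct[occ$resid_a == 3 & occ$resid_b == 3], 85)
  expect_identical(occ$n_contact_frames[occ$resid_a == 3 & occ$resid_b == 3],
                   17L)
})

test_that("the hydrophobic cutoff is inclusive at 10 A", {
  for (d in c(9.99, 10, 10.01)) {
    sched <- contact_schedule(2, 2, 100, contact_distance = d,
                              apart_distance = 20)
    traj <- make_dimer_trajectory(sched, n_frames = 4, seed = 1)
    occ <- hydrophobic_occurrence_map(traj, list(chain = "A"),
                                      list(chain = "B"))
    got <- occ$occurrence_pct[occ$resid_a == 2 & occ$resid_b == 2]
    expect_identical(got, if (d <= 10) 100 else 0)
  }
})

test_that("occurrence maps are symmetric under group exchange", {
  sched <- contact_schedule(c(2, 5), c(3, 6), c(40, 90))
  traj <- make_dimer_trajectory(sched, n_frames = 10, seed = 4)
  ab <- hydrophobic_occurrence_map(traj, list(chain = "A"),
                                   list(chain = "B"))
  ba <- hydrophobic_occurrence_map(traj, list(chain = "B"),
                                   list(chain = "A"))
  key_ab <- paste(ab$resid_a, ab$resid_b)
  key_ba <- paste(ba$resid_b, ba$resid_a)
  expect_setequal(key_ab, key_ba)
  expect_equal(ab$occurrence_pct[order(key_ab)],
               ba$occurrence_pct[order(key_ba)])
})

test_that("groups without hydrophobic residues warn and return empty maps", {
  traj <- make_salt_bridge_trajectory(2, contact_frames = 1)
  expect_warning(
    occ <- hydrophobic_occurrence_map(traj, list(chain = "A"),
                                      list(chain = "B")),
    "no hydrophobic")
  expect_equal(nrow(occ), 0L)
})

test_that("facing fractions follow the side-chain orientations", {
  toward <- make_dimer_trajectory(contact_schedule(2, 2, 100),
                                  n_frames = 4, seed = 1)
  expect_equal(facing_fraction(toward, "A", 2, "B", 2), 1.0)
  away <- make_dimer_trajectory(contact_schedule(2, 2, 100, facing = FALSE),
                                n_frames = 4, seed = 1)
  expect_equal(facing_fraction(away, "A", 2, "B", 2), 0.0)
})

test_that("alternating toward/away frames give facing fraction one half", {
  on <- make_dimer_trajectory(contact_schedule(2, 2, 100), n_frames = 2,
                              seed = 1)
  off <- make_dimer_trajectory(contact_schedule(2, 2, 100, facing = FALSE),
                               n_frames = 2, seed = 1)
  frames <- list(get_frame(on, 1), get_frame(off, 1),
                 get_frame(on, 2), get_frame(off, 2))
  frames <- lapply(seq_along(frames), function(i)
    md_frame(frames[[i]]$atoms, frames[[i]]$xyz, time = (i - 1) * 10))
  mix <- as_trajectory(frames)
  expect_equal(facing_fraction(mix, "A", 2, "B", 2), 0.5)
})

test_that("salt bridges count only opposite charges within 4 A", {
  traj <- make_salt_bridge_trajectory(4, contact_frames = 1:3,
                                      contact_distance = 3.5)
  occ <- electrostatic_occurrence_map(traj, list(chain = "A"),
                                      list(chain = "B"))
  expect_equal(nrow(occ), 1L)
  expect_identical(occ$occurrence_pct, 75)
  # boundary: inclusive at 4.00, exclusive just beyond
  for (d in c(3.99, 4, 4.01)) {
    tr <- make_salt_bridge_trajectory(2, contact_frames = 1:2,
                                      contact_distance = d)
    o <- electrostatic_occurrence_map(tr, list(chain = "A"),
                                      list(chain = "B"))
    expect_identical(o$occurrence_pct, if (d <= 4) 100 else 0)
  }
})

test_that("like-charged pairs are excluded from electrostatic maps", {
  base <- make_salt_bridge_trajectory(2, contact_frames = 1:2,
                                      contact_distance = 3)
  atoms <- base$atoms
  atoms$resname[atoms$chain == "B"] <- "ARG"  # carboxylate atoms renamed away
  atoms$name[atoms$chain == "B" & atoms$name == "OE1"] <- "NE"
  atoms$name[atoms$chain == "B" & atoms$name == "OE2"] <- "NH1"
  atoms$elem[atoms$name %in% c("NE", "NH1")] <- "N"
  frames <- lapply(seq_len(n_frames(base)), function(k)
    md_frame(atoms, base$xyz[, , k], time = base$times[k]))
  lys_arg <- as_trajectory(frames)
  occ <- electrostatic_occurrence_map(lys_arg, list(chain = "A"),
                                      list(chain = "B"))
  expect_equal(nrow(occ), 0L)
})

test_that("hydrogen-bond occurrence uses the donor-H distance, inclusively", {
  # NZ-OE1 = d places HZ1 exactly d - 1 from OE1
  for (d in c(3.39, 3.41)) {
    tr <- make_salt_bridge_trajectory(2, contact_frames = 1:2,
                                      contact_distance = d)
    occ <- hbond_occurrence_map(tr, list(chain = "A"), list(chain = "B"))
    expect_identical(occ$occurrence_pct,
                     if (d - 1 <= 2.4) 100 else 0)
  }
})

test_that("structures without hydrogens are rejected for H-bond analysis", {
  tr <- make_salt_bridge_trajectory(2, contact_frames = 1:2,
                                    with_hydrogens = FALSE)
  expect_error(hbond_occurrence_map(tr, list(chain = "A"),
                                    list(chain = "B")),
               "no hydrogen atoms")
})

test_that("region contact levels follow the four-rule rubric", {
  n_frames <- 20
  mk <- function(occs, facings) {
    df <- data.frame(resid_a = seq_along(occs), resid_b = seq_along(occs),
                     occ = occs)
    list(occ = as_occurrence_map(df, n_frames), facing = facings)
  }
  sa <- region_scheme("RA", "A", 1, 10)
  sb <- region_scheme("RB", "B", 1, 10)
  lvl <- function(x) classify_region_contacts(x$occ, x$facing, sa, sb)$level
  # three facing pairs at 90% -> strong
  expect_identical(lvl(mk(c(90, 90, 90), c(1, 1, 1))), "strong")
  # one facing pair at 60% -> weak
  expect_identical(lvl(mk(60, 1)), "weak")
  # nothing within cutoff -> none
  expect_identical(lvl(mk(c(0, 0), c(1, 1))), "none")
  # boundary: exactly 2 interactions at exactly 85% -> strong
  expect_identical(lvl(mk(c(85, 85), c(1, 1))), "strong")
  # facing below half disqualifies (rule 1)
  expect_identical(lvl(mk(c(90, 90), c(0.4, 0.4))), "none")
})

test_that("classification agrees with an independent rubric enumeration", {
  set.seed(202)
  n_cases <- 1000
  sa <- region_scheme(c("R1", "R2"), "A", c(1, 6), c(5, 10))
  sb <- region_scheme(c("S1", "S2"), "B", c(1, 6), c(5, 10))
  for (case in seq_len(n_cases)) {
    n_pairs <- sample(1:8, 1)
    df <- data.frame(
      resid_a = sample(1:10, n_pairs, replace = TRUE),
      resid_b = sample(1:10, n_pairs, replace = TRUE),
      occ = sample(c(0, 5, 50, 84, 85, 86, 100), n_pairs, replace = TRUE))
    df <- df[!duplicated(df[c("resid_a", "resid_b")]), , drop = FALSE]
    facing <- sample(c(0, 0.25, 0.5, 0.75, 1), nrow(df), replace = TRUE)
    occ <- as_occurrence_map(df, 100)
    got <- classify_region_contacts(occ, facing, sa, sb)
    ref <- oracle_rubric(data.frame(
      ra = ifelse(df$resid_a <= 5, "R1", "R2"),
      rb = ifelse(df$resid_b <= 5, "S1", "S2"),
      occ = df$occ, facing = facing))
    for (r in seq_len(nrow(got))) {
      hit <- ref$ra == got$region_a[r] & ref$rb == got$region_b[r]
      want <- if (any(hit)) ref$level[hit] else "none"
      expect_identical(got$level[r], want)
    }
  }
})

test_that("raising the strong threshold never upgrades a contact", {
  set.seed(77)
  sa <- region_scheme("RA", "A", 1, 10)
  sb <- region_scheme("RB", "B", 1, 10)
  rank <- c(none = 0, weak = 1, strong = 2)
  for (i in 1:50) {
    n <- sample(1:6, 1)
    df <- data.frame(resid_a = seq_len(n), resid_b = seq_len(n),
                     occ = sample(0:100, n, replace = TRUE))
    facing <- runif(n)
    occ <- as_occurrence_map(df, 100)
    lv_low <- classify_region_contacts(occ, facing, sa, sb,
                                       interaction_criteria(
                                         strong_occurrence_threshold = 70))
    lv_high <- classify_region_contacts(occ, facing, sa, sb,
                                        interaction_criteria(
                                          strong_occurrence_threshold = 95))
    expect_lte(rank[lv_high$level], rank[lv_low$level])
  }
})

test_that("criteria constructors validate their fields", {
  expect_error(interaction_criteria(hydrophobic_ca_cutoff = -1), "positive")
  expect_error(interaction_criteria(strong_occurrence_threshold = 0), "0")
  crit <- interaction_criteria()
  expect_equal(crit$hydrophobic_ca_cutoff, 10)
  expect_equal(crit$electrostatic_cutoff, 4)
  expect_equal(crit$hbond_cutoff, 2.4)
  expect_equal(crit$strong_occurrence_threshold, 85)
  expect_equal(crit$min_interactions, 2L)
})
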