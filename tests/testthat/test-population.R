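kt298 <- postmd::KB_KCAL * 298

test_that("exact populations integrate the Boltzmann measure", {
  # equal energies: populations follow conformation counts
  es <- conformer_energy_set(list(A = rep(1.5, 100), B = rep(1.5, 300)))
  expect_equal(unname(exact_populations(es)), c(0.25, 0.75))
  # two single-conformation conformers split 0.9 / 0.1 at dE = kT ln 9
  es2 <- conformer_energy_set(list(low = 0, high = kt298 * log(9)))
  expect_equal(unname(exact_populations(es2)), c(0.9, 0.1), tolerance = 1e-12)
  # single conformer
  expect_equal(unname(exact_populations(conformer_energy_set(list(X = 1:5)))),
               1)
  # shifting every energy by a constant changes nothing
  es3 <- conformer_energy_set(lapply(unclass(es2), function(e) e + 1234))
  expect_equal(exact_populations(es3), exact_populations(es2),
               tolerance = 1e-12)
})

test_that("the MC walk reproduces the uniform limit within batch errors", {
  es <- conformer_energy_set(
    setNames(rep(list(rep(2, 500)), 7), paste0("C", 1:7)))
  est <- mc_populations(es, population_config(steps = 1e6, seed = 42))
  expect_equal(sum(est$probability), 1, tolerance = 1e-12)
  expect_equal(sum(est$visits), est$n_total)
  z <- abs(est$probability - 1 / 7) / est$stderr
  expect_true(all(z < 3))
})

test_that("a two-state system recovers the closed-form split", {
  es <- conformer_energy_set(list(low = 0, high = kt298 * log(9)))
  est <- mc_populations(es, population_config(steps = 2e5, seed = 5))
  expect_lt(abs(est$probability[1] - 0.9), 3 * est$stderr[1])
  expect_lt(abs(est$probability[2] - 0.1), 3 * est$stderr[2])
  dg <- relative_free_energies(est)
  expect_equal(unname(dg["high"]), kt298 * log(9),
               tolerance = 5 * kt298 * est$stderr[2] / est$probability[2])
})

test_that("the walk is deterministic given its seed", {
  es <- make_conformer_energies(default_energy_spec(seed = 3))
  a <- mc_populations(es, population_config(steps = 5e4, seed = 12))
  b <- mc_populations(es, population_config(steps = 5e4, seed = 12))
  expect_identical(a$visits, b$visits)
  c_ <- mc_populations(es, population_config(steps = 5e4, seed = 13))
  expect_false(identical(a$visits, c_$visits))
})

test_that("energy offsets leave MC visits unchanged for the same seed", {
  es <- make_conformer_energies(energy_model_spec(mean = c(0, 1, 2),
                                                  count = 50, seed = 6))
  shifted <- conformer_energy_set(lapply(unclass(es), function(e) e + 500))
  a <- mc_populations(es, population_config(steps = 5e4, seed = 2))
  b <- mc_populations(shifted, population_config(steps = 5e4, seed = 2))
  expect_identical(a$visits, b$visits)
})

test_that("lower mean energy wins in two-conformer systems", {
  es <- make_conformer_energies(energy_model_spec(mean = c(0, 1.2),
                                                  spread = c(0.5, 0.5),
                                                  count = 200, seed = 9))
  ex <- exact_populations(es)
  expect_gt(ex[1], ex[2])
  est <- mc_populations(es, population_config(steps = 2e5, seed = 4))
  expect_gt(est$probability[1], est$probability[2])
})

test_that("single-conformer input short-circuits to probability one", {
  es <- conformer_energy_set(list(only = c(1, 2, 3)))
  expect_message(est <- mc_populations(es), "single conformer")
  expect_equal(est$probability, 1)
})

test_that("free energies reference the most populated conformer", {
  expect_equal(unname(relative_free_energies(c(a = 0.25, b = 0.25,
                                               c = 0.25, d = 0.25))),
               rep(0, 4), ignore_attr = TRUE)
  dg <- relative_free_energies(c(major = 10 / 11, minor = 1 / 11),
                               temperature = 298)
  expect_equal(unname(dg["minor"]), kt298 * log(10), tolerance = 1e-12)
  expect_equal(unname(dg["major"]), 0)
  # permutation equivariance
  p <- c(x = 0.5, y = 0.3, z = 0.2)
  expect_equal(relative_free_energies(p)[c("z", "x", "y")],
               relative_free_energies(p[c("z", "x", "y")]),
               ignore_attr = TRUE)
  # zero populations flagged, not fatal
  dg0 <- relative_free_energies(c(a = 1, b = 0))
  expect_true(is.infinite(dg0["b"]))
  expect_true(attr(dg0, "unbounded")["b"])
})

test_that("energy tables round-trip through the text format", {
  es <- make_conformer_energies(energy_model_spec(mean = c(0, 2),
                                                  count = 10, seed = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_energy_table(es, path)
  back <- read_energy_table(path)
  expect_equal(sort(names(back)), sort(names(es)))
  expect_equal(back$C1, es$C1, tolerance = 1e-12)
  expect_error(conformer_energy_set(list(A = c(1, NA))), "non-finite")
  expect_error(conformer_energy_set(list()), "at least one")
})
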