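test_that("minimization config enforces its invariants and protocol defaults", {
  cfg <- minimization_config()
  expect_equal(cfg$max_steps, 1500L)
  expect_equal(cfg$fmax, 1.0)
  expect_equal(cfg$cutoff, 1.4)
  expect_error(minimization_config(max_steps = 0), "max_steps")
  expect_error(minimization_config(fmax = -1))
  expect_error(minimization_config(cutoff = 0))
})

test_that("a single harmonic bond relaxes to its minimum", {
  topo <- bond_only_topology(b0 = 0.15, kb = 1000)
  res <- steepest_descent(rbind(c(0, 0, 0), c(0.16, 0, 0)), topo)
  expect_true(res$converged)
  sep <- sqrt(sum((res$positions[1, ] - res$positions[2, ])^2))
  expect_equal(sep, 0.15, tolerance = 1e-3)
  expect_lte(res$final_fmax, 1.0)
  expect_true(all(diff(res$energy_trace) <= 0))
})

test_that("a seeded perturbed tripeptide converges under the default protocol", {
  st <- make_peptide("ASA", perturb = 0.005, seed = 42)
  topo <- build_topology(st)
  res <- steepest_descent(positions_of(st), topo)
  expect_true(res$converged)
  expect_lte(res$final_fmax, 1.0)
  expect_lte(res$steps_used, 1500L)
  expect_true(all(diff(res$energy_trace) <= 0))
})

test_that("a non-converging system runs exactly 1500 steps and still yields a structure", {
  st <- make_peptide("AKSA", perturb = 0.005, seed = 11)
  mod <- apply_all(st, list("A:2:carbonylation", "A:3:phosphorylation"))$structure
  topo <- build_topology(mod)
  res <- steepest_descent(positions_of(mod), topo)
  expect_false(res$converged)
  expect_false(res$stalled)
  expect_equal(res$steps_used, 1500L)
  expect_true(all(is.finite(res$positions)))
  expect_true(all(diff(res$energy_trace) <= 0))
})

test_that("minimization is deterministic", {
  st <- make_peptide("ASA", perturb = 0.005, seed = 7)
  topo <- build_topology(st)
  r1 <- steepest_descent(positions_of(st), topo)
  r2 <- steepest_descent(positions_of(st), topo)
  expect_identical(r1$energy_trace, r2$energy_trace)
  expect_identical(r1$positions, r2$positions)
})

test_that("gradient norm decreases to the threshold on a pure quadratic system", {
  topo <- bond_only_topology(b0 = 0.12, kb = 5000)
  res <- steepest_descent(rbind(c(0, 0, 0), c(0.2, 0, 0)), topo)
  expect_true(res$converged)
  expect_lt(res$final_energy, 0.5 * 5000 * 0.08^2)
})

test_that("step underflow is flagged as a stall, distinct from the step cap", {
  topo <- bond_only_topology(b0 = 0.15, kb = 1e14)
  cfg <- minimization_config(fmax = 1e-8)
  res <- steepest_descent(rbind(c(0, 0, 0), c(0.1500001, 0, 0)), topo, cfg)
  expect_true(res$stalled)
  expect_false(res$converged)
  expect_lt(res$steps_used, cfg$max_steps)
})

test_that("non-finite starting energy is an input error", {
  topo <- bond_only_topology()
  x <- rbind(c(0, 0, 0), c(NaN, 0, 0))
  expect_error(steepest_descent(x, topo), "non-finite")
})

test_that("eligibility pre-check lists every reason found", {
  reg <- default_registry()
  clean <- make_peptide("ASA")
  rep1 <- check_minimizable(clean, reg)
  expect_true(rep1$eligible)
  expect_length(rep1$reasons, 0L)

  lig <- peptide_with_ligand()
  rep2 <- check_minimizable(lig, reg)
  expect_false(rep2$eligible)
  expect_match(rep2$reasons, "ligand", all = FALSE)

  missing <- clean
  missing$atoms <- missing$atoms[missing$atoms$name != "CA" |
                                 missing$atoms$res_seq != 2L, ]
  rep3 <- check_minimizable(missing, reg)
  expect_false(rep3$eligible)
  expect_match(rep3$reasons, "missing atoms", all = FALSE)

  # two independent problems -> two reasons
  both <- lig
  both$atoms <- both$atoms[both$atoms$name != "CA" |
                           both$atoms$res_seq != 2L, ]
  rep4 <- check_minimizable(both, reg)
  expect_length(rep4$reasons, 2L)

  extra <- clean
  row <- extra$atoms[1, ]; row$name <- "XQ"
  extra$atoms <- rbind(extra$atoms[1, ], row, extra$atoms[-1, ])
  rep5 <- check_minimizable(extra, reg)
  expect_false(rep5$eligible)
  expect_match(rep5$reasons, "formatting", all = FALSE)
})

test_that("generated fixtures always pass the eligibility check", {
  for (s in c("A", "GSG", "AKSA", "QWER"))
    expect_true(check_minimizable(make_peptide(s))$eligible, label = s)
})

test_that("the settings echo records the protocol constants", {
  txt <- settings_echo(minimization_config(), "45a3")
  expect_match(txt, "nsteps\\s+= 1500", all = FALSE)
  expect_match(txt, "emtol\\s+= 1", all = FALSE)
  expect_match(txt, "rvdw\\s+= 1.4", all = FALSE)
  expect_match(txt, "45a3", all = FALSE)
})
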