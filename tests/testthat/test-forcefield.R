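test_that("topology for a single residue is index-valid with consistent exclusions", {
  st <- make_peptide("A")
  topo <- build_topology(st)
  n <- nrow(topo$atoms)
  expect_true(all(unlist(topo$bonds[, c("i", "j")]) %in% seq_len(n)))
  expect_true(all(unlist(topo$angles[, c("i", "j", "k")]) %in% seq_len(n)))
  expect_false(any(topo$bonds$i == topo$bonds$j))
  expect_true(all(topo$atoms$mass > 0))
})

test_that("exclusions equal the brute-force graph-distance <= 2 enumeration", {
  st <- make_peptide("ASA")
  topo <- build_topology(st)
  n <- nrow(topo$atoms)
  # independent oracle: adjacency matrix powers
  adj <- matrix(FALSE, n, n)
  for (b in seq_len(nrow(topo$bonds)))
    adj[topo$bonds$i[b], topo$bonds$j[b]] <- adj[topo$bonds$j[b], topo$bonds$i[b]] <- TRUE
  two <- (adj %*% adj) > 0
  want <- character()
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (adj[i, j] || two[i, j]) want <- c(want, paste(i, j))
  got <- paste(topo$exclusions$i, topo$exclusions$j)
  expect_setequal(got, want)
  # and the nonbonded pair list is exactly the complement
  expect_equal(nrow(topo$pairs), choose(n, 2) - length(want))
})

test_that("structures with unparameterized content are rejected", {
  expect_error(build_topology(peptide_with_ligand()), "unknown residue")
  st <- make_peptide("ASA")
  st$atoms$res_name[st$atoms$res_seq == 2L] <- "ZZZ"
  expect_error(build_topology(st), "unknown residue")
  st2 <- make_peptide("ASA")
  st2$atoms <- st2$atoms[st2$atoms$name != "CA" | st2$atoms$res_seq != 2L, ]
  expect_error(build_topology(st2), "missing atom")
})

test_that("harmonic bond energy and force match the closed form", {
  topo <- bond_only_topology(b0 = 0.15, kb = 1000)
  x <- rbind(c(0, 0, 0), c(0.16, 0, 0))
  ef <- energy_forces(x, topo)
  expect_equal(ef$total, 0.05, tolerance = 1e-12)
  expect_equal(ef$bond, 0.05, tolerance = 1e-12)
  fmag <- sqrt(rowSums(ef$forces^2))
  expect_equal(fmag, c(10, 10), tolerance = 1e-10)
  expect_equal(ef$forces[1, ], -ef$forces[2, ], tolerance = 1e-12)
  # pulling direction: atom 1 is pulled toward atom 2
  expect_gt(ef$forces[1, 1], 0)
  expect_error(energy_forces(rbind(c(0, 0, 0), c(1e-9, 0, 0)), topo),
               "singularity")
})

test_that("nonbonded interactions vanish exactly beyond the cutoff", {
  topo <- pair_only_topology(sigma = 0.3, epsilon = 1, qq = 0.25)
  near <- energy_forces(rbind(c(0, 0, 0), c(1.39, 0, 0)), topo)
  far <- energy_forces(rbind(c(0, 0, 0), c(1.41, 0, 0)), topo)
  expect_gt(abs(near$coulomb), 0)
  expect_identical(far$lj, 0)
  expect_identical(far$coulomb, 0)
  expect_identical(max(abs(far$forces)), 0)
  # a non-default cutoff moves the boundary
  far2 <- energy_forces(rbind(c(0, 0, 0), c(1.41, 0, 0)), topo, cutoff = 2)
  expect_gt(abs(far2$coulomb), 0)
})

test_that("analytic forces match central finite differences on 50 seeded configurations", {
  st <- make_peptide("AA")
  topo <- build_topology(st)
  x0 <- positions_of(st)
  set.seed(1234)
  h <- 1e-6
  worst <- 0
  for (cfg in 1:50) {
    x <- x0 + matrix(runif(length(x0), -0.004, 0.004), ncol = 3)
    ef <- energy_forces(x, topo)
    g <- matrix(0, nrow(x), 3)
    for (i in seq_len(nrow(x))) for (d in 1:3) {
      xa <- x; xa[i, d] <- xa[i, d] + h
      xb <- x; xb[i, d] <- xb[i, d] - h
      g[i, d] <- (energy_forces(xa, topo)$total -
                  energy_forces(xb, topo)$total) / (2 * h)
    }
    worst <- max(worst, max(abs(-g - ef$forces)) / max(abs(ef$forces)))
    expect_lt(max(abs(colSums(ef$forces))), 1e-8)  # net force ~ 0
  }
  expect_lt(worst, 1e-4)
})

test_that("energy is translation invariant and the decomposition sums to the total", {
  st <- make_peptide("ASA")
  topo <- build_topology(st)
  x <- positions_of(st)
  e1 <- energy_forces(x, topo)
  e2 <- energy_forces(x + matrix(rep(c(1.3, -0.7, 2.1), each = nrow(x)),
                                 ncol = 3), topo)
  expect_equal(e1$total, e2$total, tolerance = 1e-10)
  expect_equal(e1$total,
               e1$bond + e1$angle + e1$dihedral + e1$improper + e1$lj +
                 e1$coulomb, tolerance = 1e-10)
})

test_that("modified residues get complete topologies", {
  st <- apply_all(make_peptide("ASA"), list("A:2:phosphorylation"))$structure
  topo <- build_topology(st)
  expect_equal(nrow(topo$atoms), nrow(st$atoms))
  sep_rows <- which(topo$atoms$res_name == "SEP")
  expect_true("P" %in% topo$atoms$name[sep_rows])
  # the phosphate P is bonded to OG and three terminal oxygens
  p_idx <- sep_rows[topo$atoms$name[sep_rows] == "P"]
  p_bonds <- sum(topo$bonds$i == p_idx | topo$bonds$j == p_idx)
  expect_equal(p_bonds, 4L)
})
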