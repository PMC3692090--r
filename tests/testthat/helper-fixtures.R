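# Fixtures are built in code: hand-written PDB snippets for the parser and
# tiny custom topologies with closed-form energies for the force field.

pdb_line <- function(record, serial, name, res_name, chain, res_seq,
                     x, y, z, altloc = " ", icode = " ", element = "") {
  nm <- if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name)
  sprintf("%-6s%5d %s%s%3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, altloc, res_name, chain, res_seq, icode,
          x, y, z, 1, 0, element)
}

# minimal two-atom ALA fixture (coordinates in angstroms on file)
tiny_pdb <- function() {
  c(pdb_line("ATOM", 1, "N", "ALA", "A", 1, 0, 0, 0, element = "N"),
    pdb_line("ATOM", 2, "CA", "ALA", "A", 1, 1.47, 0, 0, element = "C"),
    "END")
}

# a small protein + ligand fixture: tripeptide plus a two-atom HETATM block
peptide_with_ligand <- function() {
  st <- make_peptide("ASA")
  st <- renumber_structure(st)
  lig <- st$atoms[1:2, ]
  lig$record <- "HETATM"
  lig$res_name <- "LIG"
  lig$chain_id <- "B"
  lig$res_seq <- 101L
  lig$name <- c("C1", "C2")
  lig$x <- lig$x + 2; lig$y <- lig$y + 2
  st$het <- lig
  renumber_structure(st)
}

# custom topology: a single harmonic bond, no nonbonded terms
bond_only_topology <- function(b0 = 0.15, kb = 1000) {
  structure(list(
    atoms = data.frame(name = c("A1", "A2"), type = "CH2", charge = 0,
                       mass = 14, res_id = 1L, res_name = "XXX",
                       res_seq = 1L, chain_id = "A"),
    bonds = data.frame(i = 1L, j = 2L, b0 = b0, kb = kb),
    angles = data.frame(i = integer(), j = integer(), k = integer(),
                        theta0 = numeric(), kt = numeric()),
    dihedrals = data.frame(i = integer(), j = integer(), k = integer(),
                           l = integer(), phis = numeric(), n = integer(),
                           kp = numeric()),
    impropers = data.frame(i = integer(), j = integer(), k = integer(),
                           l = integer(), xi0 = numeric(), kxi = numeric()),
    pairs = data.frame(i = integer(), j = integer(), sigma = numeric(),
                       epsilon = numeric(), qq = numeric(),
                       is14 = logical()),
    exclusions = data.frame(i = 1L, j = 2L),
    flavour = "54a7", epsilon_r = 1,
    type_table = data.frame(type = "CH2", mass = 14.027, sigma = 0.4,
                            epsilon = 0.4)),
    class = "ptm_topology")
}

# custom topology: one nonbonded pair only (for cutoff / closed-form checks)
pair_only_topology <- function(sigma = 0.3, epsilon = 1, qq = 0.25) {
  t <- bond_only_topology()
  t$bonds <- t$bonds[0, ]
  t$exclusions <- t$exclusions[0, ]
  t$pairs <- data.frame(i = 1L, j = 2L, sigma = sigma, epsilon = epsilon,
                        qq = qq, is14 = FALSE)
  t
}

# a registry file set for toy catalogues, written to a temp dir
write_toy_registry <- function(rows, dir = tempfile("reg")) {
  dir.create(dir)
  rx <- file.path(dir, "reactions.tsv")
  writeLines(c("# toy", rows), rx)
  rx
}

positions_of <- function(st) as.matrix(st$atoms[, c("x", "y", "z")])

random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
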