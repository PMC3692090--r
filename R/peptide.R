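#' Synthetic peptide fixtures
#'
#' Builds united-atom peptides with ideal template geometry by sequential
#' internal-coordinate placement, so every pipeline stage is testable
#' without downloading a structure.  An optional seeded uniform coordinate
#' perturbation emulates the imperfect geometry of experimental models.
#'
#' @name fixtures
NULL

.AA1 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
          E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL")

.CONFORMATIONS <- list(extended = c(phi = -120, psi = 120),
                       helix = c(phi = -57, psi = -47))

.type_element <- function(type) {
  first <- substr(type, 1, 1)
  ifelse(type == "H", "H", ifelse(first %in% c("C", "N", "O", "S", "P"), first, "X"))
}

#' Build a synthetic peptide structure
#'
#' @param sequence either a 1-letter string (e.g. `"ASA"`) or a character
#'   vector of 3-letter residue names.
#' @param conformation backbone dihedral preset: "extended"
#'   (phi/psi = -120/+120, the default: clash-free) or "helix" (-57/-47).
#' @param perturb uniform noise amplitude in nm applied to every coordinate
#'   (each displaced by U(-perturb, +perturb)); 0 disables.
#' @param seed integer seed for the perturbation; required when
#'   `perturb > 0` so fixtures are reproducible.
#' @param chain_id chain identifier for the built peptide.
#' @param registry a `ptm_registry` supplying the residue building blocks.
#' @return a `ptm_structure` (one model, one chain, C-terminal OXT added).
#' @examples
#' st <- make_peptide("ASA")
#' structure_residues(st)
#' @export
make_peptide <- function(sequence, conformation = "extended", perturb = 0,
                         seed = NULL, chain_id = "A",
                         registry = default_registry()) {
  if (length(sequence) == 1L && !sequence %in% names(registry$blocks)) {
    letters1 <- strsplit(sequence, "")[[1L]]
    bad <- setdiff(letters1, names(.AA1))
    if (length(bad)) stop(sprintf("unsupported residue letter(s): %s",
                                  paste(bad, collapse = ", ")))
    sequence <- unname(.AA1[letters1])
  }
  if (length(sequence) == 0L) stop("empty sequence")
  miss <- setdiff(sequence, names(registry$blocks))
  if (length(miss)) stop(sprintf("unsupported residue(s): %s",
                                 paste(unique(miss), collapse = ", ")))
  if (perturb < 0) stop("perturbation amplitude must be >= 0")
  if (perturb > 0 && is.null(seed)) stop("a seed is required when perturb > 0")
  conf <- .CONFORMATIONS[[conformation]]
  if (is.null(conf)) stop(sprintf("unknown conformation preset '%s'", conformation))

  rows <- list()
  prev <- NULL  # positions of previous residue backbone: list(N=, CA=, C=)
  for (ri in seq_along(sequence)) {
    blk <- registry$blocks[[sequence[ri]]]
    pos <- list()
    if (ri == 1L) {
      pos$N <- c(0, 0, 0)
      pos$CA <- c(0.147, 0, 0)
      th <- .deg2rad(111)
      pos$C <- pos$CA + 0.153 * c(-cos(th), sin(th), 0)
    } else {
      pos$N <- place_atom(prev$N, prev$CA, prev$C, r = 0.133, theta = 116,
                          phi = conf["psi"])
      pos$CA <- place_atom(prev$CA, prev$C, pos$N, r = 0.147, theta = 121.7,
                           phi = 180)
      pos$C <- place_atom(prev$C, pos$N, pos$CA, r = 0.153, theta = 111,
                          phi = conf["phi"])
    }
    # "-C" in a build record is the previous residue's carbonyl carbon
    # (amide-plane reference); falls back to the own C for residue 1
    pos[["-C"]] <- if (ri > 1L) prev$C else pos$C
    ic <- blk$ic
    if (!is.null(ic)) for (i in seq_len(nrow(ic))) {
      refs <- lapply(c(ic$ref_dihedral[i], ic$ref_angle[i], ic$ref_bond[i]),
                     function(nm) pos[[nm]])
      # the N-terminal amine H has no peptide plane to be trans to: place it
      # staggered (gauche) instead of amide-trans
      phi_i <- if (ri == 1L && ic$ref_dihedral[i] == "-C") 120 else ic$phi[i]
      pos[[ic$name[i]]] <- place_atom(refs[[1]], refs[[2]], refs[[3]],
                                      r = ic$r[i], theta = ic$theta[i],
                                      phi = phi_i)
    }
    if (ri == length(sequence))
      pos$OXT <- place_atom(pos$O, pos$CA, pos$C, r = 0.123, theta = 117,
                            phi = 180)
    atom_names <- c(blk$atoms$name, if (ri == length(sequence)) "OXT")
    types <- c(blk$atoms$type, if (ri == length(sequence)) "O")
    xyz <- do.call(rbind, pos[atom_names])
    rows[[ri]] <- data.frame(
      record = "ATOM", serial = 0L, name = atom_names, alt_loc = "",
      res_name = sequence[ri], chain_id = chain_id, res_seq = ri, i_code = "",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occupancy = 1, b_factor = 0,
      element = .type_element(types), stringsAsFactors = FALSE)
    prev <- pos[c("N", "CA", "C")]
  }
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL

  if (perturb > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()), add = TRUE)
    set.seed(seed)
    n <- nrow(atoms)
    atoms$x <- atoms$x + stats::runif(n, -perturb, perturb)
    atoms$y <- atoms$y + stats::runif(n, -perturb, perturb)
    atoms$z <- atoms$z + stats::runif(n, -perturb, perturb)
  }

  st <- structure(list(atoms = atoms, het = .empty_atom_df(),
                       header_lines = character(), extra_models = list(),
                       multi_model = FALSE, n_models = 1L,
                       warnings = character(),
                       known_residues = union(.CANONICAL_AA,
                                              unique(registry$reactions$product_code))),
                  class = "ptm_structure")
  renumber_structure(st)
}
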