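#' GROMACS file export
#'
#' Writers for the GROMACS structure (.gro) and topology (.top) formats:
#' fixed-column .gro records in nanometres with a zero box line (in-vacuo
#' semantics, velocities omitted), and a standalone modern-dialect .top with
#' explicit atom, bonded and exclusion sections.  Atom ordering matches the
#' PDB output ordering exactly.
#'
#' @name export_gromacs
NULL

#' Write a structure in .gro format
#'
#' @param st a `ptm_structure` (model 1 is written).
#' @param title title line.
#' @param path optional output file.
#' @return character vector of lines.
#' @export
write_gro <- function(st, title = "ptmod structure", path = NULL) {
  atoms <- st$atoms
  if (nrow(atoms) == 0L) stop("structure has no atoms")
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop("non-finite coordinates")
  idx <- .residue_index(atoms)
  lines <- c(title, sprintf("%5d", nrow(atoms)))
  for (i in seq_len(nrow(atoms))) {
    lines <- c(lines, sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                              idx[i] %% 100000L, atoms$res_name[i],
                              atoms$name[i], i %% 100000L,
                              atoms$x[i], atoms$y[i], atoms$z[i]))
  }
  lines <- c(lines, sprintf("%10.5f%10.5f%10.5f", 0, 0, 0))
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}

#' Read a .gro file (round-trip support)
#'
#' @param text lines, a single string, or a file path.
#' @return data frame with res_seq, res_name, name, serial, x, y, z (nm).
#' @export
read_gro <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  n <- as.integer(trimws(text[2L]))
  rows <- lapply(text[2L + seq_len(n)], function(ln) data.frame(
    res_seq = as.integer(substr(ln, 1, 5)),
    res_name = trimws(substr(ln, 6, 10)),
    name = trimws(substr(ln, 11, 15)),
    serial = as.integer(substr(ln, 16, 20)),
    x = as.numeric(substr(ln, 21, 28)),
    y = as.numeric(substr(ln, 29, 36)),
    z = as.numeric(substr(ln, 37, 44))))
  do.call(rbind, rows)
}

#' Write a topology in .top format
#'
#' Standalone modern-dialect topology: \[defaults\], \[atomtypes\],
#' \[moleculetype\], \[atoms\], \[bonds\], \[pairs\], \[angles\],
#' \[dihedrals\], \[exclusions\], \[system\], \[molecules\].  The header
#' comment records the force-field flavour and tool version.  Bonded indices
#' are validated against the atom section before writing.
#'
#' @param topology a `ptm_topology`.
#' @param flavour force-field flavour for the header (defaults to the
#'   topology's own).
#' @param title system title.
#' @param path optional output file.
#' @return character vector of lines.
#' @export
write_top <- function(topology, flavour = topology$flavour,
                      title = "ptmod system", path = NULL) {
  at <- topology$atoms
  n <- nrow(at)
  if (n == 0L) stop("empty topology")
  idx_ok <- function(v) all(v >= 1L & v <= n)
  if (!idx_ok(unlist(topology$bonds[c("i", "j")])) ||
      !idx_ok(unlist(topology$angles[c("i", "j", "k")])) ||
      !idx_ok(unlist(topology$dihedrals[c("i", "j", "k", "l")])))
    stop("topology indices out of range")
  ver <- as.character(utils::packageVersion("ptmod"))
  types <- unique(at$type)
  lines <- c(
    sprintf("; generated by ptmod %s; force-field flavour: %s", ver, flavour),
    "; simplified united-atom parameter set (documented placeholders)",
    "",
    "[ defaults ]",
    "; nbfunc comb-rule gen-pairs fudgeLJ fudgeQQ",
    "  1      2         no        1.0     1.0",
    "",
    "[ atomtypes ]",
    "; name mass charge ptype sigma epsilon")
  atd <- topology$type_table
  for (tp in types) {
    r <- atd[atd$type == tp, ]
    lines <- c(lines, sprintf("  %-5s %9.4f 0.000 A %9.5f %9.5f",
                              tp, r$mass, r$sigma, r$epsilon))
  }
  lines <- c(lines, "",
             "[ moleculetype ]",
             "; name nrexcl",
             "  protein 2",
             "",
             "[ atoms ]",
             "; nr type resnr residue atom cgnr charge mass")
  for (i in seq_len(n))
    lines <- c(lines, sprintf("%6d %-5s %5d %-5s %-5s %5d %9.4f %9.4f",
                              i, at$type[i], at$res_id[i], at$res_name[i],
                              at$name[i], i, at$charge[i], at$mass[i]))
  lines <- c(lines, "", "[ bonds ]", "; ai aj funct b0 kb")
  bd <- topology$bonds
  for (i in seq_len(nrow(bd)))
    lines <- c(lines, sprintf("%6d %6d 1 %9.5f %12.1f", bd$i[i], bd$j[i],
                              bd$b0[i], bd$kb[i]))
  lines <- c(lines, "", "[ pairs ]",
             "; none: 1-4 pairs interact at full nonbonded strength")
  lines <- c(lines, "", "[ angles ]", "; ai aj ak funct theta0 ktheta")
  an <- topology$angles
  for (i in seq_len(nrow(an)))
    lines <- c(lines, sprintf("%6d %6d %6d 1 %9.3f %9.1f", an$i[i], an$j[i],
                              an$k[i], an$theta0[i], an$kt[i]))
  lines <- c(lines, "", "[ dihedrals ]", "; ai aj ak al funct phis kphi n")
  dh <- topology$dihedrals
  for (i in seq_len(nrow(dh)))
    lines <- c(lines, sprintf("%6d %6d %6d %6d 1 %9.3f %9.3f %d", dh$i[i],
                              dh$j[i], dh$k[i], dh$l[i], dh$phis[i],
                              dh$kp[i], dh$n[i]))
  im <- topology$impropers
  if (!is.null(im) && nrow(im)) {
    lines <- c(lines, "", "[ dihedrals ]", "; impropers: ai aj ak al funct xi0 kxi")
    for (i in seq_len(nrow(im)))
      lines <- c(lines, sprintf("%6d %6d %6d %6d 2 %9.3f %9.3f", im$i[i],
                                im$j[i], im$k[i], im$l[i], im$xi0[i], im$kxi[i]))
  }
  lines <- c(lines, "", "[ exclusions ]")
  ex <- topology$exclusions
  if (nrow(ex)) {
    sp <- split(ex$j, ex$i)
    for (i in names(sp))
      lines <- c(lines, paste(c(i, sort(sp[[i]])), collapse = " "))
  }
  lines <- c(lines, "",
             "[ system ]", title, "",
             "[ molecules ]", "protein 1")
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}
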