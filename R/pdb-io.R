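#' PDB reading and writing
#'
#' The parser follows the handling rules of the modification workflow: only
#' coordinate records (ATOM/HETATM) and model/chain bookkeeping are
#' interpreted; every other statement is retained verbatim as pass-through
#' header text.  Multi-model (NMR) files are parsed in full but model 1 is
#' marked as the modification target and a notification flag is set.
#' Residues whose names fall outside the 20 canonical amino acids and the
#' registry's product codes are flagged non-canonical; they are shown as "!"
#' in sequence output and cannot be modified.
#'
#' Internally all coordinates are stored in nanometres; PDB files are in
#' angstroms, converted only at the I/O boundary.
#'
#' @name pdb_io
NULL

.CANONICAL_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                   "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                   "THR", "TRP", "TYR", "VAL")

.empty_atom_df <- function() {
  data.frame(record = character(), serial = integer(), name = character(),
             alt_loc = character(), res_name = character(),
             chain_id = character(), res_seq = integer(), i_code = character(),
             x = numeric(), y = numeric(), z = numeric(),
             occupancy = numeric(), b_factor = numeric(),
             element = character(), stringsAsFactors = FALSE)
}

.substr_trim <- function(line, from, to) {
  n <- nchar(line)
  if (from > n) return("")
  trimws(substr(line, from, min(to, n)))
}

.parse_coord_line <- function(line, lineno) {
  num <- function(from, to, what, required = TRUE) {
    s <- .substr_trim(line, from, to)
    if (s == "") {
      if (required) stop(sprintf("PDB parse error at line %d: missing %s", lineno, what))
      return(NA_real_)
    }
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) stop(sprintf("PDB parse error at line %d: unparseable %s ('%s')",
                               lineno, what, s))
    v
  }
  name <- .substr_trim(line, 13, 16)
  res_name <- .substr_trim(line, 18, 20)
  if (name == "") stop(sprintf("PDB parse error at line %d: blank atom name", lineno))
  if (res_name == "") stop(sprintf("PDB parse error at line %d: blank residue name", lineno))
  chain <- substr(paste0(line, " "), 22, 22)
  list(record = ifelse(startsWith(line, "ATOM"), "ATOM", "HETATM"),
       serial = as.integer(num(7, 11, "serial")),
       name = name,
       alt_loc = .substr_trim(line, 17, 17),
       res_name = res_name,
       chain_id = ifelse(chain == "", " ", chain),
       res_seq = as.integer(num(23, 26, "residue number")),
       i_code = .substr_trim(line, 27, 27),
       x = num(31, 38, "x coordinate") / 10,
       y = num(39, 46, "y coordinate") / 10,
       z = num(47, 54, "z coordinate") / 10,
       occupancy = {o <- num(55, 60, "occupancy", required = FALSE); ifelse(is.na(o), 1, o)},
       b_factor = {b <- num(61, 66, "B factor", required = FALSE); ifelse(is.na(b), 0, b)},
       element = .substr_trim(line, 77, 78))
}

#' Parse PDB file text into a structure object
#'
#' @param text character: either a single string of PDB content, a character
#'   vector of lines, or a file path (a single-element string naming an
#'   existing file is read from disk).
#' @param known_residues character vector of residue names considered
#'   modifiable; defaults to the 20 canonical amino acids plus all product
#'   codes of the packaged registry.  Anything else is flagged non-canonical.
#' @return an object of class `ptm_structure`: list with `atoms` (model-1
#'   ATOM records, data frame), `het` (model-1 HETATM records), `header_lines`
#'   (verbatim pass-through text), `extra_models` (ATOM data frames of models
#'   2..n), `multi_model` (flag), `n_models`, `warnings`.
#' @export
parse_pdb <- function(text, known_residues = NULL) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  if (length(text) == 0L) stop("empty PDB input")
  if (is.null(known_residues))
    known_residues <- union(.CANONICAL_AA, registry_product_codes())

  is_atom <- startsWith(text, "ATOM")
  is_het <- startsWith(text, "HETATM")
  is_model <- startsWith(text, "MODEL")
  is_endmdl <- startsWith(text, "ENDMDL")
  is_coord <- is_atom | is_het
  if (!any(is_coord)) stop("empty structure: no ATOM or HETATM records found")

  # MODEL/ENDMDL nesting check
  depth <- 0L
  model_no <- 0L
  model_of_line <- integer(length(text))
  for (i in seq_along(text)) {
    if (is_model[i]) {
      if (depth != 0L) stop("PDB format error: nested MODEL records")
      depth <- 1L
      model_no <- model_no + 1L
    } else if (is_endmdl[i]) {
      if (depth != 1L) stop("PDB format error: ENDMDL without matching MODEL")
      depth <- 0L
    }
    model_of_line[i] <- max(model_no, 1L)
  }
  if (depth != 0L) stop("PDB format error: MODEL without matching ENDMDL")
  n_models <- max(model_no, 1L)

  first_coord <- which(is_coord)[1L]
  header_lines <- text[seq_len(first_coord - 1L)]
  header_lines <- header_lines[!is_model[seq_len(first_coord - 1L)]]

  warnings <- character()
  parse_block <- function(idx) {
    if (length(idx) == 0L) return(.empty_atom_df())
    recs <- lapply(idx, function(i) .parse_coord_line(text[i], i))
    do.call(rbind, lapply(recs, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  }

  atoms <- parse_block(which(is_atom & model_of_line == 1L))
  het <- parse_block(which(is_het & model_of_line == 1L))

  # alternate locations: keep blank or 'A', drop the rest
  drop_alt <- function(df) {
    if (nrow(df) == 0L) return(df)
    bad <- !(df$alt_loc %in% c("", "A"))
    if (any(bad)) {
      warnings <<- c(warnings, sprintf(
        "dropped %d alternate-location record(s) (alt_loc not blank or 'A')", sum(bad)))
      df <- df[!bad, , drop = FALSE]
    }
    df$alt_loc <- ""
    rownames(df) <- NULL
    df
  }
  atoms <- drop_alt(atoms)
  het <- drop_alt(het)
  if (nrow(atoms) + nrow(het) == 0L) stop("empty structure: no usable coordinate records")

  extra_models <- list()
  if (n_models > 1L) {
    warnings <- c(warnings, sprintf(
      "multi-model input (%d models): only model 1 is modified and written", n_models))
    for (m in 2L:n_models)
      extra_models[[m - 1L]] <- drop_alt(parse_block(which(is_atom & model_of_line == m)))
  }

  st <- structure(list(atoms = atoms, het = het, header_lines = header_lines,
                       extra_models = extra_models, multi_model = n_models > 1L,
                       n_models = n_models, warnings = warnings,
                       known_residues = known_residues),
                  class = "ptm_structure")
  .check_residue_identity(st)
  st
}

# residue identity (chain, res_seq, i_code) must be unique within model 1:
# the same key must not reappear after a different residue interrupts it.
.check_residue_identity <- function(st) {
  if (nrow(st$atoms) == 0L) return(invisible(st))
  key <- paste(st$atoms$chain_id, st$atoms$res_seq, st$atoms$i_code, sep = "|")
  runs <- rle(key)$values
  if (anyDuplicated(runs))
    stop("invalid structure: residue identity (chain, number, insertion code) recurs non-contiguously")
  invisible(st)
}

# Residue index over model-1 ATOM records: integer block id per residue,
# in file order.
.residue_index <- function(atoms) {
  if (nrow(atoms) == 0L) return(integer())
  key <- paste(atoms$chain_id, atoms$res_seq, atoms$i_code, sep = "|")
  r <- rle(key)
  rep(seq_along(r$lengths), r$lengths)
}

#' Residue-level summary of a structure
#'
#' @param st a `ptm_structure`.
#' @return data frame with one row per model-1 residue: chain_id, res_seq,
#'   i_code, res_name, n_atoms, canonical (flag).
#' @export
structure_residues <- function(st) {
  idx <- .residue_index(st$atoms)
  if (length(idx) == 0L)
    return(data.frame(chain_id = character(), res_seq = integer(),
                      i_code = character(), res_name = character(),
                      n_atoms = integer(), canonical = logical()))
  first <- !duplicated(idx)
  out <- st$atoms[first, c("chain_id", "res_seq", "i_code", "res_name")]
  out$n_atoms <- as.integer(tabulate(idx))
  out$canonical <- out$res_name %in% st$known_residues
  rownames(out) <- NULL
  out
}

.fmt_atom_name <- function(name, element) {
  # Standard PDB alignment: 1-letter elements start in column 14 unless the
  # name is 4 characters long.
  if (nchar(name) >= 4L) return(substr(name, 1, 4))
  if (nchar(element) == 2L) sprintf("%-4s", name) else sprintf(" %-3s", name)
}

.fmt_coord_line <- function(rec) {
  if (rec$serial > 99999L)
    stop("serial overflow: more than 99999 atom records cannot be written in fixed-column PDB")
  if (nchar(rec$name) > 4L)
    stop(sprintf("atom name '%s' exceeds the 4-character PDB column", rec$name))
  if (!all(is.finite(c(rec$x, rec$y, rec$z))))
    stop("non-finite coordinates cannot be written")
  sprintf("%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec$record, rec$serial, .fmt_atom_name(rec$name, rec$element),
          substr(paste0(rec$alt_loc, " "), 1, 1), rec$res_name, rec$chain_id,
          rec$res_seq, substr(paste0(rec$i_code, " "), 1, 1),
          rec$x * 10, rec$y * 10, rec$z * 10, rec$occupancy, rec$b_factor,
          rec$element)
}

#' Write a structure as PDB text
#'
#' Model 1 only is written (multi-model inputs produce a single-model file).
#' Records are renumbered 1..N over ATOM then HETATM, with TER records per
#' chain consuming serials.  Coordinates are written in angstroms to three
#' decimals.
#'
#' @param st a `ptm_structure`.
#' @param copy_header if TRUE, pass-through header lines are reproduced
#'   verbatim before the coordinate section.
#' @param path optional file path; when given the text is also written there.
#' @return character vector of lines, invisibly when `path` is given.
#' @export
write_pdb <- function(st, copy_header = FALSE, path = NULL) {
  st <- renumber_structure(st)
  out <- character()
  if (copy_header && length(st$header_lines) > 0L) out <- st$header_lines
  emit_model <- st$multi_model
  if (emit_model) out <- c(out, sprintf("MODEL     %4d", 1L))
  atoms <- st$atoms
  idx <- .residue_index(atoms)
  ter_serial_used <- 0L
  if (nrow(atoms) > 0L) {
    chains <- rle(atoms$chain_id)
    pos <- 0L
    for (ci in seq_along(chains$lengths)) {
      rows <- seq(pos + 1L, pos + chains$lengths[ci])
      pos <- pos + chains$lengths[ci]
      for (i in rows) out <- c(out, .fmt_coord_line(atoms[i, ]))
      last <- atoms[rows[length(rows)], ]
      out <- c(out, sprintf("TER   %5d      %3s %1s%4d%1s",
                            last$serial + 1L, last$res_name, last$chain_id,
                            last$res_seq, substr(paste0(last$i_code, " "), 1, 1)))
    }
  }
  if (nrow(st$het) > 0L)
    for (i in seq_len(nrow(st$het))) out <- c(out, .fmt_coord_line(st$het[i, ]))
  if (emit_model) out <- c(out, "ENDMDL")
  out <- c(out, "END")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Fetch a PDB entry by 4-character ID
#'
#' Never called implicitly: networking is off by default and must be enabled
#' explicitly.  The text is returned for [parse_pdb()].
#'
#' @param pdb_id 4-character PDB code, e.g. "1N5U".
#' @param offline if TRUE (the default) no network access is attempted and a
#'   fetch error is raised.
#' @param base_url download endpoint.
#' @return character vector of PDB lines.
#' @export
fetch_pdb <- function(pdb_id, offline = TRUE,
                      base_url = "https://files.rcsb.org/download") {
  if (!is.character(pdb_id) || length(pdb_id) != 1L ||
      !grepl("^[0-9][A-Za-z0-9]{3}$", pdb_id))
    stop(sprintf("invalid PDB id '%s': expected a digit followed by 3 alphanumerics",
                 as.character(pdb_id)[1]))
  if (offline)
    stop(sprintf("fetch error: offline mode is active; pass offline = FALSE (or --fetch) to download '%s'",
                 pdb_id))
  url <- sprintf("%s/%s.pdb", base_url, toupper(pdb_id))
  txt <- tryCatch(readLines(url, warn = FALSE),
                  error = function(e) stop(sprintf(
                    "fetch error: could not download '%s' (%s)", pdb_id, conditionMessage(e))))
  txt
}

#' @export
print.ptm_structure <- function(x, ...) {
  res <- structure_residues(x)
  cat(sprintf("ptm_structure: %d atom(s), %d residue(s), %d chain(s), %d HETATM record(s)%s\n",
              nrow(x$atoms), nrow(res), length(unique(res$chain_id)), nrow(x$het),
              if (x$multi_model) sprintf(", %d models (model 1 active)", x$n_models) else ""))
  invisible(x)
}
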