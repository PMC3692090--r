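#' Modification engine
#'
#' Applies modification plans to a structure: deletes, renames and places
#' atoms, renames the residue to its product code, renumbers serials and
#' renders the three-letter sequence.  Application is transactional: any
#' failure leaves the input untouched and produces no partial output.
#'
#' @name engine
NULL

#' Parse a selection string
#'
#' Selection syntax is `CHAIN:RESSEQ[ICODE]:REACTION_ID`, e.g.
#' `"A:58:phosphorylation"` or `"A:100A:acetylation"`.  A blank chain id may
#' be written as `_`.
#'
#' @param spec selection string.
#' @return list with `chain_id`, `res_seq`, `i_code`, `reaction_id`.
#' @export
parse_selection <- function(spec) {
  parts <- strsplit(spec, ":", fixed = TRUE)[[1L]]
  if (length(parts) != 3L || !nzchar(parts[3]))
    stop(sprintf("invalid selection '%s': expected CHAIN:RESSEQ[ICODE]:REACTION_ID", spec))
  m <- regmatches(parts[2], regexec("^(-?[0-9]+)([A-Za-z]?)$", parts[2]))[[1L]]
  if (length(m) == 0L)
    stop(sprintf("invalid selection '%s': residue field '%s' is not RESSEQ[ICODE]",
                 spec, parts[2]))
  chain <- parts[1]
  if (chain %in% c("", "_")) chain <- " "
  if (nchar(chain) != 1L)
    stop(sprintf("invalid selection '%s': chain id must be a single character", spec))
  list(chain_id = chain, res_seq = as.integer(m[2]), i_code = m[3],
       reaction_id = parts[3])
}

.find_residue_rows <- function(st, site) {
  idx <- .residue_index(st$atoms)
  hit <- which(st$atoms$chain_id == site$chain_id &
               st$atoms$res_seq == site$res_seq &
               st$atoms$i_code == site$i_code)
  if (length(hit) == 0L)
    stop(sprintf("selection error: no residue %s:%d%s in model 1",
                 site$chain_id, site$res_seq, site$i_code))
  hit
}

.is_chain_start <- function(st, rows) {
  first <- rows[1L]
  first == 1L || st$atoms$chain_id[first - 1L] != st$atoms$chain_id[first]
}

#' Apply one modification plan to a structure
#'
#' Deletions are removed, renames applied, and additions placed by
#' internal-coordinate geometry in plan order (later additions may reference
#' earlier placed atoms).  The residue is renamed to the plan's product code
#' and stays in the ATOM section; all untouched atoms keep their coordinates
#' bit-identically.
#'
#' @param st a `ptm_structure`.
#' @param site a selection (list from [parse_selection()], or a selection
#'   string).
#' @param plan a `ptm_plan` from [lookup_reaction()].
#' @return the modified `ptm_structure` (serials not yet renumbered; see
#'   [apply_all()]).
#' @export
apply_modification <- function(st, site, plan) {
  if (is.character(site)) site <- parse_selection(site)
  rows <- .find_residue_rows(st, site)
  res <- st$atoms[rows, , drop = FALSE]
  res_name <- res$res_name[1L]
  parent <- .tpl_parent_residue(plan$target)
  if (!res_name %in% st$known_residues)
    stop(sprintf("residue %s %s:%d%s is non-canonical and cannot be modified",
                 res_name, site$chain_id, site$res_seq, site$i_code))
  if (!identical(res_name, parent))
    stop(sprintf("plan targets %s but residue %s:%d%s is %s",
                 parent, site$chain_id, site$res_seq, site$i_code, res_name))
  if (isTRUE(plan$nter) && !.is_chain_start(st, rows))
    stop(sprintf("reaction '%s' modifies the N-terminus but residue %s:%d%s does not start its chain",
                 plan$reaction_id, site$chain_id, site$res_seq, site$i_code))

  for (nm in plan$deletions) {
    j <- match(nm, res$name)
    if (is.na(j))
      stop(sprintf("structural incompleteness: atom %s missing from residue %s %s:%d%s",
                   nm, res_name, site$chain_id, site$res_seq, site$i_code))
    res <- res[-j, , drop = FALSE]
  }
  if (!is.null(plan$renames)) for (i in seq_len(nrow(plan$renames))) {
    j <- match(plan$renames$old[i], res$name)
    if (is.na(j))
      stop(sprintf("structural incompleteness: atom %s missing from residue %s %s:%d%s",
                   plan$renames$old[i], res_name, site$chain_id, site$res_seq, site$i_code))
    res$name[j] <- plan$renames$new[i]
  }
  if (!is.null(plan$additions)) for (i in seq_len(nrow(plan$additions))) {
    ad <- plan$additions[i, ]
    get_pos <- function(nm) {
      j <- match(nm, res$name)
      if (is.na(j))
        stop(sprintf("structural incompleteness: reference atom %s missing from residue %s %s:%d%s",
                     nm, res_name, site$chain_id, site$res_seq, site$i_code))
      c(res$x[j], res$y[j], res$z[j])
    }
    d <- place_atom(get_pos(ad$ref_dihedral), get_pos(ad$ref_angle),
                    get_pos(ad$ref_bond), r = ad$r, theta = ad$theta,
                    phi = ad$phi)
    new_row <- res[1L, , drop = FALSE]
    new_row$serial <- 0L
    new_row$name <- ad$name
    new_row$alt_loc <- ""
    new_row$x <- d[1]; new_row$y <- d[2]; new_row$z <- d[3]
    new_row$occupancy <- 1; new_row$b_factor <- 0
    new_row$element <- .type_element(ad$type)
    res <- rbind(res, new_row)
  }
  res$res_name <- plan$product_code
  res$record <- "ATOM"

  before <- if (rows[1L] > 1L) st$atoms[seq_len(rows[1L] - 1L), , drop = FALSE]
            else st$atoms[0L, ]
  after <- if (rows[length(rows)] < nrow(st$atoms))
             st$atoms[seq(rows[length(rows)] + 1L, nrow(st$atoms)), , drop = FALSE]
           else st$atoms[0L, ]
  st$atoms <- rbind(before, res, after)
  rownames(st$atoms) <- NULL
  st
}

#' Apply a list of selections and produce the modification log
#'
#' Selections are applied in input order, transactionally: a duplicate site
#' or any single failure aborts with an error before any output, leaving the
#' input structure untouched.  Serials are renumbered once at the end.
#'
#' @param st a `ptm_structure`.
#' @param selections list of selection strings or parsed selections.
#' @param registry a `ptm_registry`.
#' @return list with `structure` (modified, renumbered) and `log`
#'   (a `ptm_log`: one entry per selection, in application order, plus
#'   warnings carried over from parsing).
#' @export
apply_all <- function(st, selections, registry = default_registry()) {
  selections <- lapply(selections, function(s)
    if (is.character(s)) parse_selection(s) else s)
  if (length(selections)) {
    key <- vapply(selections, function(s)
      paste(s$chain_id, s$res_seq, s$i_code), "")
    if (anyDuplicated(key))
      stop(sprintf("duplicate selection: site %s given more than once",
                   key[duplicated(key)][1]))
  }
  entries <- list()
  out <- st
  for (s in selections) {
    rows <- .find_residue_rows(out, s)
    res_name <- out$atoms$res_name[rows[1L]]
    plan <- lookup_reaction(res_name, s$reaction_id, registry)
    n_before <- nrow(out$atoms)
    out <- apply_modification(out, s, plan)
    entries[[length(entries) + 1L]] <- data.frame(
      chain_id = s$chain_id, res_seq = s$res_seq, i_code = s$i_code,
      residue = res_name, reaction_id = s$reaction_id,
      product_code = plan$product_code,
      atoms_deleted = length(plan$deletions),
      atoms_renamed = if (is.null(plan$renames)) 0L else nrow(plan$renames),
      atoms_added = if (is.null(plan$additions)) 0L else nrow(plan$additions),
      atoms_after = nrow(out$atoms), stringsAsFactors = FALSE)
    stopifnot(nrow(out$atoms) ==
                n_before - length(plan$deletions) +
                (if (is.null(plan$additions)) 0L else nrow(plan$additions)))
  }
  out <- renumber_structure(out)
  log <- structure(list(entries = if (length(entries)) do.call(rbind, entries)
                                  else NULL,
                        warnings = st$warnings),
                   class = "ptm_log")
  list(structure = out, log = log)
}

#' Renumber atom serials 1..N
#'
#' ATOM records are numbered first in model order; each chain's TER record
#' consumes one serial; HETATM records continue the sequence.  Idempotent.
#'
#' @param st a `ptm_structure`.
#' @return the structure with serials reassigned.
#' @export
renumber_structure <- function(st) {
  counter <- 0L
  if (nrow(st$atoms) > 0L) {
    chains <- rle(st$atoms$chain_id)
    pos <- 0L
    serial <- integer(nrow(st$atoms))
    for (ci in seq_along(chains$lengths)) {
      n <- chains$lengths[ci]
      serial[pos + seq_len(n)] <- counter + seq_len(n)
      counter <- counter + n + 1L  # TER consumes one serial
      pos <- pos + n
    }
    st$atoms$serial <- serial
  }
  if (nrow(st$het) > 0L) {
    st$het$serial <- counter + seq_len(nrow(st$het))
  }
  st
}

#' Render the three-letter sequence of a structure
#'
#' One 3-letter token per residue, chains on separate lines; modified
#' residues are shown by their product codes, non-canonical unmodifiable
#' residues as `!`.
#'
#' @param st a `ptm_structure`.
#' @return character vector, one line per chain ("A: ALA SEP ALA").
#' @export
render_sequence <- function(st) {
  res <- structure_residues(st)
  if (nrow(res) == 0L) return(character())
  toks <- ifelse(res$canonical, res$res_name, "!")
  unname(vapply(split(seq_len(nrow(res)),
                      factor(res$chain_id, unique(res$chain_id))),
                function(i) paste0(res$chain_id[i[1]], ": ",
                                   paste(toks[i], collapse = " ")),
                ""))
}

#' @export
print.ptm_log <- function(x, ...) {
  n <- if (is.null(x$entries)) 0L else nrow(x$entries)
  cat(sprintf("ptm_log: %d modification(s), %d warning(s)\n", n, length(x$warnings)))
  if (n) print(x$entries)
  invisible(x)
}
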