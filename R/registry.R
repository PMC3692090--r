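#' PTM reaction registry
#'
#' The registry houses the reaction catalogue (one row per reaction/target
#' pair, several reactions may share one product: many-to-one), the
#' executable modification templates, the residue building blocks and the
#' force-field parameter tables.  All invariants are validated at load time:
#' every executable template resolves, every edit step names an existing
#' atom, additions are topologically ordered, and every executable plan
#' applied to its parent building block reproduces the product building
#' block exactly (names, types, charges).
#'
#' @name registry
NULL

.ptm_cache <- new.env(parent = emptyenv())

.extdata <- function(file) {
  p <- system.file("extdata", file, package = "ptmod")
  if (p == "") p <- file.path("inst", "extdata", file)  # pre-install fallback
  if (!file.exists(p)) stop(sprintf("packaged data file '%s' not found", file))
  p
}

.read_data_lines <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  x[nzchar(x)]
}

.tokens <- function(line) strsplit(line, "[ \t]+")[[1L]]

# ---- force-field parameter tables -----------------------------------------

.parse_params <- function(path) {
  lines <- .read_data_lines(path)
  section <- NA_character_
  at <- list(); bt <- list(); an <- list(); dt <- list()
  imp <- list(sp2_types = character(), xi0 = 0, kxi = 0)
  p14 <- list(sigma_scale = 1, eps_scale = 1)
  eps_r <- 1
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      section <- gsub("[][ ]", "", ln)
      next
    }
    tk <- .tokens(ln)
    if (identical(section, "atomtypes")) {
      at[[length(at) + 1L]] <- data.frame(type = tk[1], mass = as.numeric(tk[2]),
                                          sigma = as.numeric(tk[3]),
                                          epsilon = as.numeric(tk[4]))
    } else if (identical(section, "bondtypes")) {
      cls <- tk[1] == "class"
      if (cls) tk <- tk[-1]
      bt[[length(bt) + 1L]] <- data.frame(ti = tk[1], tj = tk[2],
                                          b0 = as.numeric(tk[3]),
                                          kb = as.numeric(tk[4]), class = cls)
    } else if (identical(section, "angletypes")) {
      an[[length(an) + 1L]] <- data.frame(ti = tk[1], tj = tk[2], tk = tk[3],
                                          theta0 = as.numeric(tk[4]),
                                          kt = as.numeric(tk[5]))
    } else if (identical(section, "dihedraltypes")) {
      dt[[length(dt) + 1L]] <- data.frame(ti = tk[1], tj = tk[2],
                                          phis = as.numeric(tk[3]),
                                          n = as.integer(tk[4]),
                                          kp = as.numeric(tk[5]))
    } else if (identical(section, "impropertypes")) {
      nt <- length(tk)
      imp <- list(sp2_types = tk[2:(nt - 2L)],
                  xi0 = as.numeric(tk[nt - 1L]), kxi = as.numeric(tk[nt]))
    } else if (identical(section, "pairs14")) {
      p14 <- list(sigma_scale = as.numeric(tk[2]), eps_scale = as.numeric(tk[3]))
    } else if (identical(section, "coulomb")) {
      eps_r <- as.numeric(tk[2])
    }
  }
  list(atomtypes = do.call(rbind, at), bondtypes = do.call(rbind, bt),
       angletypes = do.call(rbind, an), dihedraltypes = do.call(rbind, dt),
       impropertypes = imp, pairs14 = p14, epsilon_r = eps_r)
}

.type_mass <- function(params, types) {
  i <- match(types, params$atomtypes$type)
  if (anyNA(i)) stop(sprintf("unknown atom type(s): %s",
                             paste(unique(types[is.na(i)]), collapse = ", ")))
  params$atomtypes$mass[i]
}

# ---- residue building blocks ----------------------------------------------

.parse_residue_blocks <- function(path, params) {
  lines <- .read_data_lines(path)
  blocks <- list()
  cur <- NULL
  flush <- function() {
    if (is.null(cur)) return()
    blocks[[cur$name]] <<- list(
      name = cur$name,
      atoms = do.call(rbind, cur$atoms),
      ic = if (length(cur$ic)) do.call(rbind, cur$ic) else NULL,
      bonds = do.call(rbind, cur$bonds))
  }
  for (ln in lines) {
    tk <- .tokens(ln)
    if (tk[1] == "[residue") {
      flush()
      cur <- list(name = gsub("]", "", tk[2]), atoms = list(), ic = list(),
                  bonds = list())
    } else if (tk[1] == "atom") {
      cur$atoms[[length(cur$atoms) + 1L]] <- data.frame(
        name = tk[2], type = tk[3], charge = as.numeric(tk[4]),
        mass = .type_mass(params, tk[3]))
    } else if (tk[1] == "ic") {
      cur$ic[[length(cur$ic) + 1L]] <- data.frame(
        name = tk[2], ref_bond = tk[3], ref_angle = tk[4], ref_dihedral = tk[5],
        r = as.numeric(tk[6]), theta = as.numeric(tk[7]), phi = as.numeric(tk[8]))
    } else if (tk[1] == "bond") {
      cur$bonds[[length(cur$bonds) + 1L]] <- data.frame(a = tk[2], b = tk[3])
    }
  }
  flush()
  blocks
}

# ---- modification templates -----------------------------------------------

.parse_templates <- function(path, params) {
  lines <- .read_data_lines(path)
  templates <- list()
  cur <- NULL
  flush <- function() {
    if (is.null(cur)) return()
    cur$renames <<- if (length(cur$renames)) do.call(rbind, cur$renames) else NULL
    cur$sets <<- if (length(cur$sets)) do.call(rbind, cur$sets) else NULL
    cur$additions <<- if (length(cur$additions)) do.call(rbind, cur$additions) else NULL
    templates[[cur$id]] <<- cur
  }
  for (ln in lines) {
    tk <- .tokens(ln)
    if (tk[1] == "[template") {
      flush()
      cur <- list(id = gsub("]", "", tk[2]), target = NA_character_,
                  product = NA_character_, deletions = character(),
                  renames = list(), sets = list(), additions = list())
    } else if (tk[1] == "target") {
      cur$target <- tk[2]
    } else if (tk[1] == "product") {
      cur$product <- tk[2]
    } else if (tk[1] == "delete") {
      cur$deletions <- c(cur$deletions, tk[2])
    } else if (tk[1] == "rename") {
      cur$renames[[length(cur$renames) + 1L]] <- data.frame(old = tk[2], new = tk[3])
    } else if (tk[1] == "set") {
      cur$sets[[length(cur$sets) + 1L]] <- data.frame(
        name = tk[2], type = tk[3], charge = as.numeric(tk[4]))
    } else if (tk[1] == "add") {
      cur$additions[[length(cur$additions) + 1L]] <- data.frame(
        name = tk[2], type = tk[3], charge = as.numeric(tk[4]),
        mass = .type_mass(params, tk[3]),
        ref_bond = tk[5], ref_angle = tk[6], ref_dihedral = tk[7],
        r = as.numeric(tk[8]), theta = as.numeric(tk[9]),
        phi = as.numeric(tk[10]))
    }
  }
  flush()
  templates
}

# Apply a template's atom edits to a building block, returning the product
# building block.  Used both for load-time validation and for deriving the
# blocks of modified residues (so they too get topologies).
.apply_template_to_block <- function(block, tpl) {
  atoms <- block$atoms
  bonds <- block$bonds
  fail <- function(fmt, ...) stop(sprintf(
    "template '%s': %s", tpl$id, sprintf(fmt, ...)))
  for (nm in tpl$deletions) {
    if (!nm %in% atoms$name) fail("deletion names unknown atom '%s'", nm)
    atoms <- atoms[atoms$name != nm, , drop = FALSE]
    bonds <- bonds[bonds$a != nm & bonds$b != nm, , drop = FALSE]
  }
  if (!is.null(tpl$renames)) for (i in seq_len(nrow(tpl$renames))) {
    old <- tpl$renames$old[i]; new <- tpl$renames$new[i]
    if (!old %in% atoms$name) fail("rename names unknown atom '%s'", old)
    if (new %in% atoms$name) fail("rename target '%s' already exists", new)
    atoms$name[atoms$name == old] <- new
    bonds$a[bonds$a == old] <- new
    bonds$b[bonds$b == old] <- new
  }
  if (!is.null(tpl$sets)) for (i in seq_len(nrow(tpl$sets))) {
    nm <- tpl$sets$name[i]
    j <- match(nm, atoms$name)
    if (is.na(j)) fail("set names unknown atom '%s'", nm)
    atoms$type[j] <- tpl$sets$type[i]
    atoms$charge[j] <- tpl$sets$charge[i]
  }
  if (!is.null(tpl$additions)) for (i in seq_len(nrow(tpl$additions))) {
    ad <- tpl$additions[i, ]
    if (ad$name %in% atoms$name) fail("added atom '%s' already exists", ad$name)
    refs <- c(ad$ref_bond, ad$ref_angle, ad$ref_dihedral)
    miss <- setdiff(refs, atoms$name)
    if (length(miss)) fail("addition '%s' references missing atom(s) %s",
                           ad$name, paste(miss, collapse = ", "))
    atoms <- rbind(atoms, data.frame(name = ad$name, type = ad$type,
                                     charge = ad$charge, mass = ad$mass))
    bonds <- rbind(bonds, data.frame(a = ad$ref_bond, b = ad$name))
  }
  list(name = tpl$product, atoms = atoms, ic = NULL, bonds = bonds)
}

.tpl_parent_residue <- function(target) sub("^NTER:", "", target)

# masses fixed up when templates set a type
.sync_masses <- function(block, params) {
  block$atoms$mass <- .type_mass(params, block$atoms$type)
  block
}

#' Load the PTM reaction registry
#'
#' With no arguments the packaged catalogue, templates, building blocks and
#' parameter table are loaded (and cached for the session).
#'
#' @param reactions_file,templates_file,residues_file,params_file paths to
#'   plain-text registry tables; default to the packaged files.
#' @return a `ptm_registry` object: list with `reactions` (data frame),
#'   `templates`, `blocks` (canonical + derived product building blocks),
#'   `params`, and `counts` (n_reactions, n_products, n_targets).
#' @export
load_registry <- function(reactions_file = .extdata("reactions.tsv"),
                          templates_file = .extdata("mod_templates.txt"),
                          residues_file = .extdata("residues.txt"),
                          params_file = .extdata("ffparams.txt")) {
  params <- .parse_params(params_file)
  blocks <- .parse_residue_blocks(residues_file, params)
  templates <- .parse_templates(templates_file, params)

  rx_lines <- .read_data_lines(reactions_file)
  rx <- do.call(rbind, lapply(rx_lines, function(ln) {
    tk <- strsplit(ln, "\t")[[1L]]
    if (length(tk) < 6L) stop(sprintf("registry load error: malformed row '%s'", ln))
    data.frame(reaction_id = tk[1], target = tk[2], product_code = tk[3],
               template_id = tk[4], code_origin = tk[5], description = tk[6])
  }))
  rx$executable <- rx$template_id != "-"

  key <- paste(rx$reaction_id, rx$target)
  if (anyDuplicated(key))
    stop(sprintf("registry load error: duplicate reaction entry %s",
                 key[duplicated(key)][1]))
  bad <- nchar(rx$product_code) != 3L
  if (any(bad))
    stop(sprintf("registry load error: product code '%s' is not 3 characters",
                 rx$product_code[bad][1]))
  miss <- setdiff(rx$template_id[rx$executable], names(templates))
  if (length(miss))
    stop(sprintf("registry load error: executable entry references missing template '%s'",
                 miss[1]))

  # derive product building blocks, iterating so chained templates whose
  # parent is itself a product (e.g. successive methylations) resolve
  exec <- rx[rx$executable, , drop = FALSE]
  pending <- seq_len(nrow(exec))
  while (length(pending)) {
    progressed <- FALSE
    for (i in pending) {
      tpl <- templates[[exec$template_id[i]]]
      if (!identical(tpl$target, exec$target[i]) ||
          !identical(tpl$product, exec$product_code[i]))
        stop(sprintf("registry load error: template '%s' target/product disagree with catalogue row",
                     tpl$id))
      parent <- .tpl_parent_residue(tpl$target)
      if (!parent %in% names(blocks)) next
      derived <- .sync_masses(.apply_template_to_block(blocks[[parent]], tpl), params)
      if (anyDuplicated(derived$atoms$name))
        stop(sprintf("registry load error: template '%s' yields duplicate atom names", tpl$id))
      code <- tpl$product
      if (code %in% names(blocks)) {
        have <- blocks[[code]]$atoms
        got <- derived$atoms
        o1 <- have[order(have$name), c("name", "type", "charge")]
        o2 <- got[order(got$name), c("name", "type", "charge")]
        rownames(o1) <- rownames(o2) <- NULL
        if (!isTRUE(all.equal(o1, o2, tolerance = 1e-12)))
          stop(sprintf("registry load error: routes to product '%s' disagree on its atoms", code))
      } else {
        blocks[[code]] <- derived
      }
      pending <- setdiff(pending, i)
      progressed <- TRUE
    }
    if (!progressed)
      stop(sprintf("registry load error: template target(s) %s have no building block",
                   paste(unique(exec$target[pending]), collapse = ", ")))
  }

  counts <- c(n_reactions = nrow(rx),
              n_products = length(unique(rx$product_code)),
              n_targets = length(unique(.tpl_parent_residue(rx$target))))
  structure(list(reactions = rx, templates = templates, blocks = blocks,
                 params = params, counts = counts),
            class = "ptm_registry")
}

#' Default (packaged) registry, loaded once per session
#' @return the cached `ptm_registry` for the packaged tables.
#' @export
default_registry <- function() {
  if (is.null(.ptm_cache$registry)) .ptm_cache$registry <- load_registry()
  .ptm_cache$registry
}

#' Product codes known to the packaged registry
#' @return character vector of 3-letter product codes.
#' @export
registry_product_codes <- function() {
  unique(default_registry()$reactions$product_code)
}

#' Resolve a (residue, reaction) pair to a modification plan
#'
#' @param residue 3-letter residue name the reaction is applied to (for a
#'   terminal modification, the residue carrying the terminus).
#' @param reaction_id reaction name, e.g. "phosphorylation".
#' @param registry a `ptm_registry`; the packaged one by default.
#' @return a `ptm_plan`: the ordered atom-edit plan (deletions, renames,
#'   sets, internal-coordinate additions), the product code and the product
#'   residue's per-atom parameters.
#' @export
lookup_reaction <- function(residue, reaction_id, registry = default_registry()) {
  rx <- registry$reactions
  rows <- rx[rx$reaction_id == reaction_id, , drop = FALSE]
  if (nrow(rows) == 0L) {
    near <- unique(agrep(reaction_id, unique(rx$reaction_id), value = TRUE,
                         max.distance = 0.3))
    stop(sprintf("unknown reaction '%s'%s", reaction_id,
                 if (length(near)) paste0("; did you mean: ",
                                          paste(near, collapse = ", "), "?") else ""))
  }
  hit <- rows[rows$target %in% c(residue, paste0("NTER:", residue)), , drop = FALSE]
  if (nrow(hit) == 0L)
    stop(sprintf("target mismatch: reaction '%s' is not defined for residue %s (targets: %s)",
                 reaction_id, residue, paste(rows$target, collapse = ", ")))
  hit <- hit[1L, ]
  if (!hit$executable)
    stop(sprintf("reaction '%s' on %s is a names-layer catalogue entry without a geometric template (not executable)",
                 reaction_id, residue))
  tpl <- registry$templates[[hit$template_id]]
  product_block <- registry$blocks[[hit$product_code]]
  structure(list(reaction_id = hit$reaction_id, target = hit$target,
                 nter = startsWith(hit$target, "NTER:"),
                 product_code = hit$product_code,
                 deletions = tpl$deletions, renames = tpl$renames,
                 sets = tpl$sets, additions = tpl$additions,
                 atom_params = product_block$atoms,
                 template_id = hit$template_id),
            class = "ptm_plan")
}

#' List catalogue entries for a residue (or the whole catalogue)
#'
#' @param residue 3-letter residue name, or "all".
#' @param registry a `ptm_registry`.
#' @return data frame of catalogue rows, ordered by reaction_id then target.
#' @export
list_reactions <- function(residue = "all", registry = default_registry()) {
  rx <- registry$reactions
  if (!identical(residue, "all")) {
    known <- unique(c(names(registry$blocks),
                      .tpl_parent_residue(rx$target), rx$product_code))
    if (!residue %in% known)
      stop(sprintf("unknown residue name '%s'", residue))
    rx <- rx[.tpl_parent_residue(rx$target) == residue, , drop = FALSE]
  }
  rx <- rx[order(rx$reaction_id, rx$target), , drop = FALSE]
  rownames(rx) <- NULL
  rx
}

#' @export
print.ptm_registry <- function(x, ...) {
  cat(sprintf("ptm_registry: %d reaction entries, %d distinct products, %d target residues (%d executable)\n",
              x$counts["n_reactions"], x$counts["n_products"], x$counts["n_targets"],
              sum(x$reactions$executable)))
  invisible(x)
}

#' @export
print.ptm_plan <- function(x, ...) {
  cat(sprintf("ptm_plan '%s' on %s -> %s: %d deletion(s), %d rename(s), %d addition(s)\n",
              x$reaction_id, x$target, x$product_code, length(x$deletions),
              if (is.null(x$renames)) 0L else nrow(x$renames),
              if (is.null(x$additions)) 0L else nrow(x$additions)))
  invisible(x)
}
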