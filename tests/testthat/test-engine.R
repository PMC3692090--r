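reg <- default_registry()

# a peptide carrying every modifiable canonical residue used by the
# executable layer
host_for <- function(target) {
  parent <- sub("^NTER:", "", target)
  one <- names(which(ptmod:::.AA1 == parent))
  if (startsWith(target, "NTER:")) paste0(one, "GA") else paste0("G", one, "A")
}

test_that("selection strings parse, including insertion codes and blank chains", {
  s <- parse_selection("A:58:phosphorylation")
  expect_equal(s[c("chain_id", "res_seq", "i_code")],
               list(chain_id = "A", res_seq = 58L, i_code = ""))
  s2 <- parse_selection("B:100A:acetylation")
  expect_equal(s2$i_code, "A")
  s3 <- parse_selection("_:-5:oxidation")
  expect_equal(s3$chain_id, " ")
  expect_equal(s3$res_seq, -5L)
  expect_error(parse_selection("A:12"), "invalid selection")
  expect_error(parse_selection("A:x2:phos"), "RESSEQ")
  expect_error(parse_selection("AB:2:phos"), "single character")
})

test_that("atom-count identity holds for every executable plan", {
  exec <- reg$reactions[reg$reactions$executable, ]
  for (i in seq_len(nrow(exec))) {
    target <- exec$target[i]
    parent <- sub("^NTER:", "", target)
    if (!parent %in% ptmod:::.CANONICAL_AA) next  # chained plans tested below
    st <- make_peptide(host_for(target))
    site_seq <- if (startsWith(target, "NTER:")) 1L else 2L
    sel <- sprintf("A:%d:%s", site_seq, exec$reaction_id[i])
    plan <- lookup_reaction(parent, exec$reaction_id[i])
    out <- apply_all(st, list(sel))$structure
    d <- length(plan$deletions)
    k <- if (is.null(plan$additions)) 0L else nrow(plan$additions)
    expect_equal(nrow(out$atoms), nrow(st$atoms) - d + k,
                 label = sprintf("%s on %s", exec$reaction_id[i], target))
    expect_true(all(out$atoms$record == "ATOM"))
  }
})

test_that("modification edits only the selected residue and keeps others bit-identical", {
  st <- make_peptide("AKSA")
  out <- apply_all(st, list("A:3:phosphorylation"))$structure
  strip <- function(df) { rownames(df) <- NULL; df }
  expect_identical(
    strip(out$atoms[out$atoms$res_seq != 3L, c("name", "res_name", "x", "y", "z")]),
    strip(st$atoms[st$atoms$res_seq != 3L, c("name", "res_name", "x", "y", "z")]))
  expect_equal(unique(out$atoms$res_name[out$atoms$res_seq == 3L]), "SEP")
})

test_that("added atoms satisfy their template internal coordinates to 1e-6", {
  st <- make_peptide("ASA")
  plan <- lookup_reaction("SER", "phosphorylation")
  out <- apply_modification(st, "A:2:phosphorylation", plan)
  res <- out$atoms[out$atoms$res_seq == 2L, ]
  pos <- function(nm) unlist(res[match(nm, res$name), c("x", "y", "z")],
                             use.names = FALSE)
  for (i in seq_len(nrow(plan$additions))) {
    ad <- plan$additions[i, ]
    m <- measure_internal(pos(ad$ref_dihedral), pos(ad$ref_angle),
                          pos(ad$ref_bond), pos(ad$name))
    expect_equal(unname(m["r"]), ad$r, tolerance = 1e-6)
    expect_equal(unname(m["theta"]), ad$theta, tolerance = 1e-6)
    expect_equal(unname(m["phi"]), ad$phi, tolerance = 1e-6)
  }
})

test_that("failures are transactional and specific", {
  st <- make_peptide("ASA")
  # duplicate site
  expect_error(apply_all(st, list("A:2:phosphorylation", "A:2:oxidation")),
               "duplicate selection")
  # residue not found
  expect_error(apply_all(st, list("A:9:phosphorylation")), "no residue")
  # wrong target residue
  expect_error(apply_all(st, list("A:1:phosphorylation")), "target mismatch")
  # missing atom in the structure
  st2 <- st
  st2$atoms <- st2$atoms[st2$atoms$name != "HG" | st2$atoms$res_seq != 2L, ]
  expect_error(apply_all(st2, list("A:2:phosphorylation")),
               "incompleteness.*HG|atom HG")
  # non-canonical residue cannot be modified
  st3 <- st
  st3$atoms$res_name[st3$atoms$res_seq == 2L] <- "XYZ"
  err <- tryCatch(apply_all(st3, list("A:2:phosphorylation")),
                  error = conditionMessage)
  expect_match(err, "cannot be modified|non-canonical|target mismatch")
  # on any failure the input object is untouched (copy semantics)
  expect_identical(st$atoms, make_peptide("ASA")$atoms)
})

test_that("empty selection list is the identity", {
  st <- make_peptide("ASA")
  res <- apply_all(st, list())
  expect_identical(res$structure$atoms, renumber_structure(st)$atoms)
  expect_null(res$log$entries)
})

test_that("two modifications log two entries in application order", {
  st <- make_peptide("AKSA")
  res <- apply_all(st, list("A:2:carbonylation", "A:3:phosphorylation"))
  expect_equal(nrow(res$log$entries), 2L)
  expect_equal(res$log$entries$reaction_id,
               c("carbonylation", "phosphorylation"))
  expect_equal(res$log$entries$product_code, c("KCA", "SEP"))
})

test_that("renumbering is gapless, idempotent, and puts HETATM last", {
  st <- peptide_with_ligand()
  st$atoms$serial <- st$atoms$serial + 17L  # introduce gaps
  r1 <- renumber_structure(st)
  expect_equal(r1$atoms$serial, seq_len(nrow(r1$atoms)))
  expect_identical(renumber_structure(r1)$atoms$serial, r1$atoms$serial)
  expect_true(min(r1$het$serial) > max(r1$atoms$serial))
})

test_that("render_sequence shows product codes and ! for unknowns", {
  st <- make_peptide("ASA")
  expect_equal(render_sequence(st), "A: ALA SER ALA")
  out <- apply_all(st, list("A:2:phosphorylation"))$structure
  expect_equal(render_sequence(out), "A: ALA SEP ALA")
  st$atoms$res_name[st$atoms$res_seq == 2L] <- "ZZZ"
  expect_equal(render_sequence(st), "A: ALA ! ALA")
})

test_that("registry-defined reverse restores the canonical residue", {
  st <- make_peptide("ANA")
  fwd <- apply_all(st, list("A:2:deamidation"))$structure
  expect_equal(unique(fwd$atoms$res_name[fwd$atoms$res_seq == 2L]), "ASP")
  back <- apply_all(fwd, list("A:2:amidation"))$structure
  orig <- st$atoms[st$atoms$res_seq == 2L, "name"]
  rest <- back$atoms[back$atoms$res_seq == 2L, "name"]
  expect_setequal(rest, orig)
  expect_equal(unique(back$atoms$res_name[back$atoms$res_seq == 2L]), "ASN")
})

test_that("chained methylations accumulate on a re-modified lysine", {
  st <- make_peptide("AKA")
  s1 <- apply_all(st, list("A:2:methylation"))$structure
  expect_equal(unique(s1$atoms$res_name[s1$atoms$res_seq == 2L]), "MLZ")
  s2 <- apply_all(s1, list("A:2:methylation"))$structure
  expect_equal(unique(s2$atoms$res_name[s2$atoms$res_seq == 2L]), "MLY")
  s3 <- apply_all(s2, list("A:2:methylation"))$structure
  expect_equal(unique(s3$atoms$res_name[s3$atoms$res_seq == 2L]), "M3L")
  direct <- apply_all(st, list("A:2:trimethylation"))$structure
  expect_setequal(s3$atoms$name[s3$atoms$res_seq == 2L],
                  direct$atoms$name[direct$atoms$res_seq == 2L])
})

test_that("N-terminal acetylation requires a chain-start residue", {
  st <- make_peptide("AGA")
  out <- apply_all(st, list("A:1:acetylation"))$structure
  expect_equal(unique(out$atoms$res_name[out$atoms$res_seq == 1L]), "AYA")
  st2 <- make_peptide("GAA")
  expect_error(apply_all(st2, list("A:2:acetylation")), "N-terminus")
})
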