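Package: ptmod
Title: Introduce Post-Translational Modifications into Protein Structures
Version: 0.1.0
Authors@R: person("ptmod", "developers", role = c("aut", "cre"),
    email = "ptmod@example.org")
Description: Edits protein 3D structures (PDB files) to carry
    post-translational modifications (PTMs) selected from a packaged
    reaction catalogue: atoms are deleted, renamed and added at
    geometrically realistic positions via internal-coordinate placement,
    residues are renamed to three-letter product codes and atom serials
    are renumbered.  A united-atom molecular-mechanics layer provides an
    eligibility pre-check, steepest-descent energy minimization in vacuo
    (1500 steps, 1.0 kJ/mol/nm force threshold, 1.4 nm cutoff) and
    GROMACS-format structure (.gro) and topology (.top) exports, plus a
    command-line front end mirroring the modify/minimize workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    optparse,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
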