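# ptmod

Introduce post-translational modifications (PTMs) into protein 3D
structures, then energy-minimize and export simulation-ready files.

Proteins are chemically altered after synthesis — phosphorylation,
acetylation, methylation, carbonylation and dozens of other reactions —
and these modifications reshape structure, dynamics and interactions.
Preparing a *modified* structure for molecular-mechanics work is fiddly:
atoms must be deleted, renamed and added at chemically sensible positions,
the residue renamed to its modified three-letter code, and every atom
serial renumbered, before a topology can be built at all.  `ptmod`
automates that workflow for structural bioinformaticians and simulation
scientists:

1. **Parse** a PDB file (only ATOM records are interpreted; everything
   else is pass-through; NMR multi-model files target model 1).
2. **Select** sites as `CHAIN:RESSEQ[ICODE]:REACTION` triples and apply
   plans from a packaged reaction catalogue (two layers: a names-layer
   catalogue and an executable layer with geometric templates covering
   phosphorylation S/T/Y, acetylation K and the N-terminus, mono/di/tri
   methylation K, methylation R, hydroxylation P, carboxylation E,
   nitration Y, carbonylation K/R/P/T, deamidation N/Q, amidation D/E and
   oxidation M/C, including chained reactions for re-uploaded products).
3. **Place** new atoms from internal coordinates (r, θ, φ) in a
   right-handed frame built from the anchoring bond, the angle reference
   and the dihedral reference:
   `|D−C| = r`, `∠(B,C,D) = θ`, `dihedral(A,B,C,D) = φ`.
4. **Check eligibility** and run steepest-descent minimization *in vacuo*
   with the protocol constants: ≤ 1500 steps, convergence at max per-atom
   force 1.0 kJ/mol/nm, 1.4 nm nonbonded cutoff.  The energy model is a
   simplified united-atom force field (harmonic bonds/angles, cosine
   dihedrals, sp2 impropers, LJ 12-6 + screened Coulomb); forces are the
   exact negative gradient (verified against finite differences).
5. **Export** the modified PDB (modified residues as ATOM records, HETATM
   renumbered after the protein), the three-letter sequence, GROMACS
   `.gro`/`.top` files and a run log.

A synthetic-peptide generator (`make_peptide`) builds united-atom
fixtures with ideal geometry and seeded perturbations, so the entire
pipeline is testable offline.

## Worked example

Carbonylate a lysine and phosphorylate a serine on a perturbed synthetic
tetrapeptide, minimize, and write all artifacts — the library analogue of
the modify-two-residues-then-minimize workflow:

```r
library(ptmod)
write_pdb(make_peptide("AKSA", perturb = 0.005, seed = 11), path = "peptide.pdb")
out <- ptm_run(input = "peptide.pdb",
               selections = c("A:2:carbonylation", "A:3:phosphorylation"),
               out_prefix = "job")
```

`job.seq.txt` (three-letter sequence, product codes in place):

```
A: ALA KCA SEP ALA
```

`job.log` (two modification entries, in application order, then the
minimization trace summary):

```
modifications applied: 2
  1. A:2 LYS -> KCA via carbonylation (-4 atoms, +1 atoms, 0 renamed)
  2. A:3 SER -> SEP via phosphorylation (-1 atoms, +4 atoms, 0 renamed)
minimization: step limit reached after 1500 step(s) (cap 1500)
  final energy: -27.3497 kJ/mol
  final max force: 4.472 kJ/mol/nm (threshold 1)
  cutoff: 1.4 nm
  note: the written structure is the last (unminimized-to-threshold) one
```

Carbonylation deletes the lysine ammonium group (NZ + 3 H) and adds an
aldehyde oxygen (allysine, code `KCA`); phosphorylation removes the
hydroxyl hydrogen and adds a phosphate (`SEP`, −2).  This doubly-charged
system does not reach the 1.0 kJ/mol/nm threshold within the 1500-step
cap, so — exactly like the workflow it reproduces — the last structure is
still written, flagged in the log.  A plain tripeptide converges:

```r
st <- make_peptide("ASA", perturb = 0.005, seed = 42)
steepest_descent(positions <- as.matrix(st$atoms[, c("x","y","z")]),
                 build_topology(st))
#> steepest descent: converged after 351 step(s); E = 21.4327 kJ/mol,
#> fmax = 0.9895 kJ/mol/nm
```

The same run from the shell:

```sh
Rscript -e 'ptmod::ptm_cli()' modify --input peptide.pdb \
    --mod A:2:carbonylation --mod A:3:phosphorylation --out-prefix job
Rscript -e 'ptmod::ptm_cli()' list --residue LYS
```

## Scope

The web front end (job queue, visualization, accounts), genuine GROMOS
45A3/54A7 parameters, and production MD are out of scope.  The force
field here is a *documented placeholder*: gradient correctness and
protocol behaviour are the tested contract, not energetic fidelity — see
`vignettes/ptm-patching.Rmd` for the model, its assumptions and its
limits.
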