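---
title: "Patching post-translational modifications into protein structures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patching post-translational modifications into protein structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmod)
```

`ptmod` edits a protein structure so that selected residues carry
post-translational modifications, optionally relaxes the result by
steepest-descent minimization, and writes simulation-ready files.  This
vignette is the package's own account of the science: the models, the
tunable parameters and why they have the values they do, what the
synthetic fixtures do and do not establish, and the design choices made
where the design was genuinely open.

## 1. The modification model

A modification is an ordered atom-edit plan against a *building block* —
the package's united-atom description of a residue (atom names, types,
partial charges, covalent bonds).  A plan consists of:

* **deletions** — atoms the reaction removes (e.g. the serine hydroxyl
  hydrogen before phosphorylation);
* **renames** — atoms that change identity (deamidation turns `ND2` into
  `OD2`);
* **re-typings** — existing atoms whose chemical environment changes
  (the sulfoxide sulfur);
* **additions** — new atoms placed from internal coordinates.

Applying a plan to its parent building block must reproduce the product
building block exactly (names, types, charges); this is checked
exhaustively when the registry loads, including products reachable by
more than one route (direct dimethylation of lysine versus methylation
of monomethyl-lysine).  Products with wwPDB chemical-component codes use
them (`SEP`, `TPO`, `PTR`, `ALY`, `MLZ`, `MLY`, `M3L`, `HYP`, `CGU`,
`NIY`, `CSO`, `AYA`; deamidation products are canonical `ASP`/`GLU`);
codes marked `local` in the catalogue are package inventions.

The catalogue is keyed by the *(reaction, target)* pair, so one reaction
name (e.g. `phosphorylation`) serves several residues and a selection
stays readable (`A:58:phosphorylation`).  Terminal modifications use
pseudo-targets (`NTER:ALA`), and a terminal plan refuses residues that do
not start their chain.  Application is transactional: any failure — a
duplicate site, a missing reference atom, an unknown reaction — aborts
the whole batch with the input untouched.  The server this mirrors did
not state whether it was transactional; atomic failure is our choice,
made so a batch can never leave a half-edited structure.

## 2. Atom placement

A new atom D is positioned from three reference atoms A (dihedral
reference), B (angle reference) and C (bond anchor) and internal
coordinates (r, θ, φ): a right-handed orthonormal frame is erected at C
with its first axis along B→C and its second in the A–B–C plane, and D
is placed so that |D−C| = r, ∠(B,C,D) = θ and the A-B-C-D torsion is φ.
The sign convention — φ > 0 for a counter-clockwise rotation sighting
along B→C — is fixed once and shared by the templates, the placement
routine and its inverse `measure_internal()`, which exists purely as a
test oracle: placement followed by measurement round-trips to 1e-9 over
randomized cases, and placement is equivariant under rigid motions.
Additions are applied in plan order, so later atoms may reference
earlier placed ones (the phosphate oxygens reference the phosphorus).
Template geometry uses ideal bond lengths and angles from standard
chemical tables, not any server's pre-minimized values, which were never
published.

## 3. The energy model

The force field is deliberately a *documented placeholder*.  Its tested
contract is analytical: forces are the exact negative gradient of the
energy (checked against central finite differences at 1e-4 relative),
the term decomposition sums to the total, and the net force vanishes.
Its parameters are not those of any production force field.

Functional forms, all in kJ, nm, degrees-on-file/radians-internal:

* harmonic bonds ½k~b~(b−b₀)² and harmonic angles ½k~θ~(θ−θ₀)²;
* proper dihedrals k~φ~(1+cos(nφ−φ~s~));
* harmonic impropers ½k~ξ~(ξ−ξ₀)² on every 3-coordinated sp2 center
  (the out-of-plane dihedral of a planar group is ±180°, and the
  deviation is angle-wrapped so both signs count as planar);
* Lennard-Jones 12-6 with Lorentz–Berthelot combination, and Coulomb
  with an effective relative dielectric ε~r~ = 4;
* a hard cutoff (default 1.4 nm) truncating both LJ and Coulomb; no
  periodicity, no solvent (in vacuo).

Exclusions are exactly the pairs at bond-graph distance 1 or 2 (verified
in the tests against a brute-force adjacency-matrix enumeration).
Third neighbours (1-4) interact with Coulomb at full strength but with
LJ softened (σ×0.85, ε×0.5), in the spirit of the reduced 1-4 parameters
united-atom force fields use.

Three numerical choices deserve explanation, because each was forced by
an explicit diagnosis rather than taste:

* **Impropers exist at all** because without them an sp2 center's
  pyramidalization is a zero-curvature mode: steepest descent stalls far
  above any tight force threshold.
* **1-4 LJ is softened** because full-strength 1-4 walls dominate the
  Hessian spectrum (we measured condition numbers ≈ 4000 on a
  tripeptide), making the 1500-step protocol unattainable.
* **ε~r~ = 4 screens the Coulomb term** because bare vacuum charges
  drive slow hydrogen-bond collapse cascades — the minimizer spends
  thousands of steps walking polar hydrogens through shallow
  electrostatic wells.  An effective dielectric of 2–4 is the standard
  stand-in for missing solvent screening; with it a perturbed
  tripeptide converges in a few hundred steps.

For the same reason the overall stiffness scale is compressed (bonds
25 000 kJ/mol/nm², angles 300 kJ/mol/rad², generic torsion 8 kJ/mol):
with spectroscopic bond constants (~10⁵–10⁶), plain steepest descent has
a conditioning bound that makes "maximum force ≤ 1.0 kJ/mol/nm within
1500 steps" impossible for *any* chain molecule.  A minimization-only
toolkit does not need spectroscopic stiffness; it needs a well-behaved
landscape with the right minima.  Consequently **absolute energies from
this package are not physical** and must not be compared with any real
force field.

## 4. The minimization protocol

`steepest_descent()` implements the workflow's stated protocol: at most
**1500 steps**, convergence when the largest per-atom force norm reaches
**1.0 kJ/mol/nm**, nonbonded cutoff **1.4 nm**, in vacuo.  The update is
x ← x + s·F/|F|~max~ (every atom moves along its force; the
largest-force atom moves by the step size s).  The line-search policy is
ours, since only "steepest gradient minimization" was specified: accept
a trial iff the energy strictly decreases, grow s ×1.2 on acceptance,
shrink ×0.5 on rejection, and terminate distinctly if s underflows below
1e-10 nm (a *stall*, reported separately from the step cap).  Every
accepted step lowers the energy, so the energy trace is non-increasing
by construction, and the whole procedure is deterministic.

Before minimizing, `check_minimizable()` reports *every* reason a
structure is unsuitable — unparameterized residues or ligands, missing
atoms, malformed residue contents — and an ineligible structure simply
skips minimization: the modified PDB is still produced, only the GROMACS
files are withheld.  A run that hits the step cap also still writes its
last structure, with a log note.  An `.mdp`-style echo of the effective
settings is written next to the log for provenance.

## 5. Synthetic fixtures: what a green test establishes

`make_peptide()` builds united-atom peptides by the same
internal-coordinate machinery the engine uses: backbone placed at preset
φ/ψ (extended −120°/+120° by default, chosen clash-free; a helix preset
exists), side chains from the residue templates, a C-terminal `OXT`, and
an optional uniform coordinate perturbation of ±`perturb` nm under a
mandatory seed.  The default perturbation in the tests, 0.005 nm
(0.05 Å), is the scale of coordinate uncertainty in a good experimental
model.  Two coherence choices matter: the amide hydrogen's build record
references the *previous* residue's carbonyl carbon (the actual peptide
plane), and the backbone φ torsion's phase puts the generator's extended
conformation at a torsional minimum — the generator and the force field
are two halves of one stated world, and fixtures should start near
mechanical equilibrium, not on top of a barrier.

What fixtures do **not** emulate: real side-chain rotamer distributions,
folded tertiary structure, crystallographic artifacts (altlocs, partial
occupancy, missing loops), or solvent.  A green end-to-end test
establishes that the machinery — parsing, planning, placement,
bookkeeping, minimization, export — is correct on well-formed input; it
says nothing about the thermodynamics of any real protein.

## 6. File handling choices

Only ATOM records are interpreted; HETATM and header content pass
through verbatim, with HETATM renumbered after the protein (TER records
consume serials and are regenerated per chain).  Multi-model input
parses fully but model 1 is the modification target, the written file
contains model 1 only, and the log says so.  Alternate locations: blank
and `'A'` kept, others dropped with a note (the source left this
undefined; this is our rule, not inferred behaviour).  Coordinates are
ångströms on file and nanometres internally, converted only at the I/O
boundary, because the minimizer and the `.gro` format are nm-native.
Serials above 99999 are an error rather than hybrid-36, keeping the
fixed-column format bit-exact.  The `.top` writer emits one standalone
modern dialect; the force-field flavour flag (`45a3`/`54a7`) is accepted,
recorded in headers, and maps to the single packaged parameter table —
the genuine parameter distinction lives outside this package's scope.

## 7. The packaged catalogue and the waived count check

The complete 256-reaction catalogue of the original service is defined
in supplementary material that is not available here; the packaged
catalogue is a documented representative subset (63 reaction entries, 57
distinct products at the time of writing — the table itself is the
source of truth), with the full executable layer listed in section 1.
The acceptance check on the full-catalogue figures is therefore waived
and replaced by internal identities: the product count never exceeds the
reaction count, several reactions genuinely share a product, and every
executable plan reproduces its product block at load time.

## 8. Known limitations

* No rotamer optimization or clash resolution at placement time; a
  clashing addition is the minimizer's problem, and an unconverged
  minimization is reported, not hidden.
* The plain cutoff creates energy discontinuities when a pair crosses
  1.4 nm; for peptides longer than the cutoff the minimizer can stall on
  such a crossing.  Fixtures used in the tests stay compact.
* Doubly charged products (phosphate) on flexible hosts may legitimately
  fail to reach the 1.0 kJ/mol/nm threshold within 1500 steps; the
  workflow's own fallback (emit the last structure) applies.
* Charges, radii and stiffnesses are placeholders (sections 3); any use
  of the `.top` output for production simulation requires replacing the
  parameter table.
* Ring closure in built fixtures (His, Phe, Tyr, Trp, Pro) is
  approximate at build time and relies on minimization to tidy up.
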