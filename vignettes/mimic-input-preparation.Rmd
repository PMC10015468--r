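---
title: "Preparing MiMiC QM/MM inputs: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preparing MiMiC QM/MM inputs: models, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimicprep)
```

## The problem

MiMiC couples CPMD (the QM engine) with GROMACS (the MM engine) in a
loose-coupling QM/MM scheme: each engine reads its own input file, and both
must agree on which atoms form the QM region and on how atom indices map
between the two programs. Writing these files by hand is error-prone — the
CPMD `&ATOMS` section reorders atoms by chemical species, the QM cell and
total charge must be computed from the selection, and covalent bonds severed
by the QM/MM boundary need special treatment. `mimicprep` automates this:
from a GROMACS topology and a coordinate file it builds a QM region through
a small selection language and emits a MiMiC-compliant CPMD input plus a
GROMACS index file, together with repair and translation tools.

## The workflow

1. Parse the topology (`read_topology()`): `#include` trees, `[ atomtypes ]`,
   per-moleculetype atom/bond tables, flattened into a global atom table in
   GROMACS order.
2. Read coordinates (`read_coordinates()`): gro, PDB, XYZ or CPMD GEOMETRY,
   normalized to nanometers.
3. Select the QM region (`qm_add()`/`qm_delete()`, or the interactive
   `prepqm` session).
4. Generate (`generate_mimic_input()`): QM cell, declared charge, boundary
   detection, species blocks, OVERLAPS index pairs, index group, optionally
   a patched `.mdp`.

```{r workflow}
fx <- make_solvated_small_molecule(n_waters = 5, seed = 1)
top <- guess_elements(read_topology(fx$top, include_dirs = fx$dir))
prep <- preparation(top, read_coordinates(fx$gro))
prep <- qm_add(prep, "resname is ACT")
pp <- pp_info(c("H", "C", "O"),
              c("H_MT_BLYP.psp", "C_MT_BLYP.psp", "O_MT_BLYP.psp"),
              lmax = c("S", "P", "P"))
res <- generate_mimic_input(prep, pp)
res$charge
round(res$box$lengths_bohr, 3)
```

## The selection language

```
expr       := term ("or" term)*
term       := factor ("and" factor)*
factor     := "not" factor | "(" expr ")" | comparison
comparison := keyword operator literal
```

Keywords: `resname`, `resid`, `name`, `type`, `id`, `mol`; operators `is`,
`not`, `>`, `<`, `>=`, `<=` (Unicode `≥`/`≤` accepted). Names and ids follow
the GROMACS topology's own conventions. Two choices were genuinely open and
are resolved as follows:

* **Ordering operators on strings.** `>`/`<`/`>=`/`<=` are accepted only for
  the integer fields `id` and `resid`; applying them to a name is a parse
  error rather than a silent lexicographic comparison.
* **The two roles of `not`.** `not` is both a comparison operator
  (`name not CA`) and a unary prefix (`not name is CA`); the position
  disambiguates — directly after a keyword it is the comparison operator.
* **`mol`** matches the moleculetype name from `[ molecules ]`; for
  coordinate-only (PDB-sourced) systems it matches the chain ID instead.

Precedence is comparison > `not` > `and` > `or`, so `a or b and c` is
`a or (b and c)`. Evaluation is pure set algebra on the global atom table
and is checked in the test suite against a row-by-row brute-force predicate
on randomized expression trees.

## Element inference

CPMD needs the chemical species of every QM atom (and the index map needs it
for every atom), but force fields routinely omit it for nonstandard
molecules. Elements already present in the topology (an `at.num` column in
`[ atomtypes ]`) are always kept — this makes `guess_elements()` idempotent.
For the rest, resolution per atom proceeds:

1. a user-supplied nonstandard-species table (atom type → element);
2. **mass**: the nearest standard atomic weight within ±0.5 amu among
   elements 1–86, with masses below 3.5 amu resolving to H (deuterium-like
   force-field masses);
3. the leading alphabetic characters of the **atom name**, tried as a
   two-letter, then a one-letter element symbol;
4. the same procedure on the **atom type**.

The precedence is a package decision: force-field masses deviate from
standard weights only by rounding, so the mass rule is by far the most
reliable signal, while names ("CA" — carbon alpha or calcium?) are the most
ambiguous and are only consulted when the mass fails. The ±0.5 amu tolerance
is deliberately tight for the same reason. Mass ties and atoms falling
through every rule are reported; with guessing disabled, any atom not
covered by the species table is an error, listing the offending types.

## Topology repair (`fix_top`)

QM-side element fixing at generation time covers only QM atoms; MM atoms of
nonstandard molecules (a cofactor left in the MM region) still need species
information for the engines and for index translation. `fix_top()` copies
the whole `#include` tree into an output directory and replaces the
`[ atomtypes ]` body of the nonbonded force-field include (the deepest
include whose name contains "nonbonded") with a consolidated registry in
which every type carries its atomic number and mass. Without such an
include, a new `atomtypes_fixed.itp` is written and `#include`d at the top
of the copied topology; that file is recognized as the consolidation target
on a re-run, which is what makes `fix_top` idempotent byte-for-byte.

Duplicate atom-type definitions merge with *first-definition-wins*
semantics (later duplicates only fill missing fields). GROMACS itself would
let the last definition win; first-wins makes the consolidated registry at
the top of the file authoritative over stale element-free sections that are
preserved when `-cls` is not given, so the repaired topology stays
element-complete on re-parsing either way.

Preprocessor handling is minimal by design: `#ifdef`/`#ifndef`/`#else`/
`#endif` evaluated against a user-supplied symbol set (empty by default, so
solvent files fall through to their rigid-water `#else` branch), plus
`#define` collection. Full cpp semantics is out of scope. `[ settles ]`
water constraints are translated into the two O–H bonds of a 3-site water so
that boundary detection sees solvent connectivity; `[ pairs ]`, `[ angles ]`,
`[ dihedrals ]` and other parameter sections are skipped — they carry no
information the preparation needs.

## QM cell, charge, and boundary atoms

**Cell.** Per axis, the cell length is the coordinate extent of the region
plus twice the padding (default 0.35 nm, the practical lower bound for the
Martyna–Tuckerman Poisson solver for isolated systems; larger regions
typically need more). Lengths are converted to Bohr
(1 Bohr = 0.0529177210903 nm). A degenerate extent with zero padding is an
error, not a zero-volume cell.

**`&ATOMS` frame.** Species-block coordinates are absolute Bohr, shifted so
the region's minimum corner sits at (padding, padding, padding) — the
molecule is centred in the minimal cell. Consequently `cpmd2coords`
recovers the QM geometry exactly *up to this uniform translation*; the test
suite compares coordinates after aligning minimum corners.

**Charge.** The declared `CHARGE` is the rounded sum of the region's
partial charges. A deviation beyond 0.01 e warns: it is the signature of a
selection that severs a charge group, which bond-cutting QM regions
routinely do.

**Boundary atoms.** A QM atom with at least one bonded neighbour outside
the region has an open valence and must be described by a monovalent
boundary pseudopotential. Detection is an exact scan of the bond graph.
Generating input with cut bonds but without the boundary option enabled is
an error — silently writing an unsaturated QM region would produce a
physically meaningless simulation.

**Species-block order** is ascending atomic number, boundary blocks last
(also by atomic number), ascending GROMACS index within a block. The order
is a package convention chosen for determinism: identical inputs produce
byte-identical outputs.

## Index translation

CPMD numbers atoms by species blocks, so MM atoms especially end up far
from their GROMACS positions. `build_index_map()` reproduces the
reordering: QM atoms take CPMD ids 1..|QM| in `&ATOMS` emission order; MM
atoms take the rest grouped by species in ascending atomic number,
ascending GROMACS index within a species. The MM rule is an explicit
assumption — the engine's exact convention is not documented — and it is
centralized in one function so it can be swapped without touching anything
else; the OVERLAPS records in generated input are derived from the same
ordering, so the two can never disagree. `format_indices()` renders
selections as a table (debugging), a list (pasting into an input), or
maximal consecutive ranges (thermostat groups).

## File-format conventions

* **gro** is parsed strictly fixed-width (residue id 1–5, residue name
  6–10, atom name 11–15, serial 16–20, three `%8.3f` coordinate fields):
  names adjacent to digits make whitespace splitting unsafe. Velocities are
  ignored on read and omitted on write. Missing boxes on write are
  synthesized from the extent plus a 0.1 nm margin, with a warning.
* **PDB**: `ATOM`/`HETATM` only; the chain column maps to `chain_or_mol`;
  occupancy/B-factor are ignored on read and written as 1.00/0.00; `CRYST1`
  carries the box when present.
* **CPMD GEOMETRY**: one line per atom, the first three whitespace-separated
  floats are Bohr positions; trailing columns (velocities) are ignored on
  read and written as zeros. The dialect is isolated in one parser.
* **pp-info file**: one record per element —
  `<element> <pp_file> LMAX=<l> [LOC=<l>] [<boundary_pp_file>]`, `#`
  comments. The syntax is this package's own documented convention covering
  the fields the generator needs.
* Serial fields overflowing their fixed width (gro/PDB, > 99999 atoms) wrap
  modulo the field width with a warning rather than failing.

## What the synthetic systems do and do not show

`make_solvated_small_molecule()` emulates a nonstandard ligand in water: a
10-atom ketone with zero net charge, realistic masses and *no* element
information, plus 3-site settles-constrained waters on a jittered grid.
`make_peptide_chain()` emulates boundary-cutting selections: toy residues
(N, CA, C, O + a 2-atom side chain) joined by peptide bonds, with optional
+1 residues. Coordinates are quantized to 3 decimals (nm) so gro
round-trips are exact, and generation is a pure function of (arguments,
seed), byte-identical across runs.

These systems exercise the bookkeeping the package owns — parsing,
selection, index mapping, charge/cell arithmetic, boundary detection. They
are *not* physically realistic: geometries are schematic, force-field
parameters are placeholders, and no claim about actual QM/MM energetics
follows from passing tests. Tests run on systems of 18–1000 atoms and
peptide chains of 2–20 residues, sizes chosen to keep the full suite fast
while covering every code path; all properties checked are
size-independent.

## Known limitations

* Only the GROMACS topology dialect is supported; `[ atomtypes ]` layout
  detection anchors on the particle-type column and recognizes the common
  layouts (with/without bonded type and atomic number).
* Trajectories, multi-model PDB, CONECT records and binary tpr files are
  out of scope; external executables (`gmx grompp`, `cpmd.x`) are never
  invoked — the exact command lines are printed instead.
* Link-atom capping schemes beyond flagging boundary atoms for monovalent
  pseudopotentials, and charge-redistribution at the cut, are not
  implemented.
* The MM part of the index map is an assumption (above); validate against
  your engine version before relying on MM indices in constraints.
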