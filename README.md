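# mimicprep

Preparation of MiMiC QM/MM input files from GROMACS topologies, in R.

MiMiC couples CPMD (quantum mechanics) with GROMACS (molecular mechanics) in
a loose-coupling QM/MM scheme. Each engine needs its own input file, and both
must agree on the QM region and on the atom-index mapping between the two
programs — CPMD reorders atoms by chemical species, so indices shift in a
way that is hard to track by hand. `mimicprep` automates the setup for
computational chemists preparing such simulations:

* **Coordinate I/O** — GROMACS gro, PDB, XYZ and CPMD GEOMETRY, unified in a
  nanometer-normalized atom table (1 Bohr = 0.0529177210903 nm, 1 Å = 0.1 nm).
* **Topology parsing** — `.top` with recursive `#include`s, `[ atomtypes ]`,
  bonds and settles, flattened into a global atom table in GROMACS order.
* **Element inference** — species table → mass (nearest standard atomic
  weight within ±0.5 amu, Z = 1–86, < 3.5 amu → H) → atom name → atom type;
  `fix_top()` consolidates the result into a repaired force-field include.
* **Selection language** — `resname`, `resid`, `name`, `type`, `id`, `mol`
  with `is`/`not`/`>`/`<`/`>=`/`<=`, combined by `and`/`or`/`not` and
  brackets, e.g. `(resid is 100 or resid is 109) and not name is CA`.
* **Preparation engine** — per axis the QM cell is
  `extent + 2 × padding` (default padding 0.35 nm, the Martyna–Tuckerman
  isolated-system requirement); the declared `CHARGE` is the rounded sum of
  the region's partial charges; QM atoms bonded to MM atoms (open valences)
  are detected exactly from the bond graph and assigned monovalent boundary
  pseudopotentials.
* **Index translation** — the GROMACS ↔ CPMD bijection implied by the
  species-block ordering, printable as a table, list, or consecutive ranges.
* **CLI** — `exec/mimicprep` with subcommands `prepqm`, `fixtop`, `cpmdid`,
  `cpmd2coords`, `geom2coords`; selections come from a TTY, a `-sele` file,
  or redirected stdin.

## Worked example

A 10-atom nonstandard ketone solvated in 5 waters (a built-in synthetic
system); the ketone becomes the QM region:

```r
library(mimicprep)

fx   <- make_solvated_small_molecule(n_waters = 5, seed = 1)
top  <- guess_elements(read_topology(fx$top, include_dirs = fx$dir))
prep <- preparation(top, read_coordinates(fx$gro))
prep <- qm_add(prep, "resname is ACT")

pp  <- pp_info(c("H", "C", "O"),
               c("H_MT_BLYP.psp", "C_MT_BLYP.psp", "O_MT_BLYP.psp"),
               lmax = c("S", "P", "P"))
res <- generate_mimic_input(prep, pp)

res$charge
#> $raw_sum
#> [1] 5.551115e-17
#> $declared
#> [1] 0
round(res$box$lengths_bohr, 3)
#>      a      b      c
#> 21.354 18.557 16.441
```

The raw charge sum of the neutral ketone is zero to rounding, so the CPMD
`&SYSTEM` section declares `CHARGE 0`; the cell is the region's coordinate
extent plus 0.7 nm (2 × 0.35 nm padding), in Bohr. The GROMACS → CPMD index
map shows the species reordering — GROMACS atom 1 (the carbonyl carbon) is
CPMD atom 7, because the six hydrogens fill the first species block:

```r
map <- build_index_map(top, prep$region)
cat(format_indices(map, c(1, 12, 15), "table"), sep = "\n")
#> gromacs_id    cpmd_id   name  resid  species
#>          1          7     C1      1        C
#>         12         11    HW1      1        H
#>         15         13    HW1      1        H
```

`res$cpmd` serializes to the `&MIMIC`/`&SYSTEM`/`&ATOMS` sections of the
CPMD input (template `&CPMD`/`&DFT` sections, when given, pass through
untouched); `res$ndx` holds the `QMatoms` index group. The same workflow on
the command line:

```sh
mimicprep prepqm -top topol.top -coords coords.gro -pp pp_info.dat \
                 -inp template.inp -mdp mimic.mdp -pad 0.35
> add resname is ACT
> q
```

which writes `cpmd.inp`, `index.ndx` and the patched mdp, and prints the
`gmx grompp` command line to produce the tpr file (external executables are
never invoked).

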