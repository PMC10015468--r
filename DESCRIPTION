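Package: mimicprep
Title: Preparation of MiMiC QM/MM Input Files from GROMACS Topologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for setting up MiMiC-based QM/MM simulations that couple
    CPMD (quantum mechanics) with GROMACS (molecular mechanics). Reads GROMACS
    topologies (.top with included .itp files) and coordinate files (gro, PDB,
    XYZ, CPMD GEOMETRY), selects a QM region with a small atom-selection query
    language, detects boundary atoms with open valences, computes the QM cell
    and total charge, and writes a MiMiC-compliant CPMD input file together
    with a GROMACS index file. Additional tools repair element information in
    topologies (fix_top), translate GROMACS atom indices to CPMD indices, and
    convert between coordinate formats. A command-line interface mirrors the
    library API; deterministic fixture generators build small solvated-ligand
    and peptide test systems.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
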