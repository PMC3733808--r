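Package: ligqc
Title: Electron-Density Fit Validation of Ligands and Binding Sites
Version: 0.1.0
Authors@R:
    person("ligqc", "developers", email = "ligqc@example.org", role = c("aut", "cre"))
Description: Automatic classification of crystallographic ligands and their
    binding sites as Good, Dubious or Bad, based on how well per-residue
    coordinates fit the electron density (real-space R-value, real-space
    correlation coefficient, average occupancy, and optional further
    criteria) under configurable threshold profiles.  Includes a fixed-column
    PDB coordinate reader/writer with alternate-location resolution,
    exclusion-list based ligand extraction with a covalent-bond distance
    rule, distance-cutoff binding-site detection backed by a cell-list
    neighbour search, a per-residue fit-statistics table format, an offline
    density engine (Gaussian atom model, RSR/RSCC over residue masks), CSV
    result and rejection reporting, and a deterministic synthetic-fixture
    generator with known ground-truth labels.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
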