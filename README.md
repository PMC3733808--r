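# ligqc — electron-density fit validation of ligands and binding sites

Most users of crystallographic structure databanks treat deposited
coordinates as ground truth, but a model is an interpretation of an
electron-density map, and its local accuracy varies — nowhere more
consequentially than at a ligand and the residues lining its pocket.
`ligqc` is for the structure-based drug-design side of that problem:
docking, pharmacophore and conformer work that needs *well-supported*
protein–ligand complexes, selected without manual map inspection.

It classifies every crystallographic ligand and every binding-site residue
as **Good**, **Dubious** or **Bad** from per-residue fit statistics — the
real-space R-value (RSR), the real-space correlation coefficient (RSCC)
and the residue average occupancy by default, optionally also
occupancy-weighted B, R-free and resolution.

## The algorithm

For each ligand component and site residue, the score starts at 0 and each
enabled, unmet condition adds 1 (comparisons inclusive at the printed
thresholds):

    score = [rscc < rscc_min] + [occ < occupancy_min] + [rsr > rsr_good_max] + ...
    label = Good   if score = 0
            Dubious if 0 < score <= tolerance
            Bad    if score > tolerance

`rsr > rsr_max` (0.4 by default) additionally forces Bad outright.
Ligands and binding sites take the **worst** label of their components.
Binding sites are all residues within 4.5 Å of any ligand atom; ligands
are hetero compounds after exclusion-list filtering (solvents/buffers are
never ligands; a covalent contact < 2.1 Å to the polymer or to a
blacklisted compound rejects; metal-ion contacts neither reject nor merge
components).  Two default profiles ship — `Default (PDB)` and
`Default (PDB_REDO)` — identical except for the good-RSR cutoff (0.24
vs 0.165; the two databanks compute RSR with different software).

## Worked example

The published worked example is a guanosine-5′-monophosphate ligand whose
fit improves from RSR 0.154 / RSCC 0.86 as deposited to 0.065 / 0.97 after
re-refinement:

```r
library(ligqc)
ps <- default_profiles()
evaluate_component(residue_stats(rsr = 0.154, rscc = 0.86, avg_occupancy = 1),
                   profile = ps[["Default (PDB)"]])[c("score", "label")]
#> $score
#> [1] 1
#> $label
#> [1] "Dubious"
```

Only RSCC fails as deposited → score 1 → Dubious at the default tolerance
of 1; the re-refined values give score 0 → Good under
`Default (PDB_REDO)`.

A full run works from a directory of `<id>.pdb` coordinate files and
`<id>.tsv` per-residue stats tables (the package's offline stand-in for
databank data; `write_fixture_set()` generates such directories with known
ground truth):

```r
p <- ps[["Default (PDB_REDO)"]]
spec <- fixture_spec(seed = 42, n_polymer_residues = 10,
                     decoys = list(list(comp_id = "ZN", distance = 2.2)),
                     target_labels = c("GLY:A:5" = "Dubious"))
write_fixture_set(list(spec), dir, p)
res <- run_validation(run_config(ids = "FX01", data_dir = dir,
                                 profile = p, out_dir = file.path(dir, "out")))
res$results[, c("model_id", "ligand_id", "ligand_label", "site_label",
                "n_site_residues")]
#>   model_id ligand_id ligand_label site_label n_site_residues
#> 1     FX01 LIG:L:101         Good    Dubious               2
res$components[, c("res_key", "role", "score", "label", "failed_conditions")]
#>     res_key   role score   label failed_conditions
#> 1 LIG:L:101 ligand     0    Good
#> 2   GLY:A:5   site     1 Dubious               rsr
#> 3  ZN:D:201   site     0    Good
```

The ligand itself fits (Good), but its site is Dubious because one
residue's RSR exceeds the good-RSR cutoff; the zinc ion within the 4.5 Å
cutoff is counted as a site residue and scored.  `results.csv`,
`components.csv` and `rejections.tsv` (subject + machine-readable reason
for every rejected structure or ligand) land in `out_dir`, filterable in
any spreadsheet.

## Command line

```sh
Rscript -e 'ligqc::ligqc_cli()' classify --data-dir data/ --id-file ids.txt \
    --profile pdb_redo --out-dir results/
Rscript -e 'ligqc::ligqc_cli()' profiles --out-dir profiles/
Rscript -e 'ligqc::ligqc_cli()' fixtures --out-dir demo_data/ --seed 1 --n 3
```

Flags `--blacklist` / `--non-propagating` swap in user exclusion lists
(plain text, one compound code per line), `--site-cutoff`,
`--bond-cutoff`, `--tolerance` tweak the active profile, `--overrides`
applies a post-hoc label override file (the non-interactive replacement
for visual re-review).

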