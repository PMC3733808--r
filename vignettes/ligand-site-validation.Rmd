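---
title: "Validating ligands and binding sites against electron density"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating ligands and binding sites against electron density}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligqc)
```

## The problem

A crystallographic model is an interpretation of an electron-density (ED)
map, not an observation, and its accuracy is not homogeneous: the ligand
and the residues lining its pocket may fit the density much worse (or
better) than the model as a whole.  For structure-based work — docking,
pharmacophore building, conformer benchmarking — what matters is precisely
the local quality of the ligand and its binding site.  `ligqc` automates
that local check: it classifies every ligand and every binding-site residue
as **Good**, **Dubious** or **Bad** from per-residue fit statistics, so a
non-crystallographer can select well-supported complexes without inspecting
maps by hand.

## The classification model

For a residue (or ligand component) with real-space R-value $R$, real-space
correlation coefficient $C$, and average occupancy $q$, a profile with
thresholds $(C_{\min}, q_{\min}, R_{\mathrm{good}}, R_{\max})$ and
tolerance $t$ assigns a score

$$ s \;=\; [C < C_{\min}] + [q < q_{\min}] + [R > R_{\mathrm{good}}]
   \;(+\,\text{optional OWAB, } R_{\mathrm{free}}, \text{resolution terms}) $$

and the label

$$ \text{Good if } s = 0, \qquad
   \text{Dubious if } 0 < s \le t, \qquad
   \text{Bad if } s > t. $$

Ligands composed of several hetero residues and whole binding sites take
the **worst** label among their components: one Bad residue makes the site
Bad; a site is Good only when every residue is Good.  Worst-of aggregation
is idempotent, commutative and associative, and adding a Good component
never changes an aggregate — the test suite asserts these laws.

Two printed cut-offs govern RSR.  `rsr_good_max` is the scored condition
above; `rsr_max` (0.4 in both defaults) is a hard cap: a residue with
$R > R_{\max}$ is forced Bad regardless of everything else, implemented by
flooring its score at $t + 1$.  The two values necessarily play different
roles — with one printed "maximum good RSR" and one printed "maximum RSR",
the only consistent reading is a Good/Dubious/Bad banding of an
otherwise-clean residue at $R \le R_{\mathrm{good}}$ /
$(R_{\mathrm{good}}, R_{\max}]$ / $> R_{\max}$.

### Default profiles and parameters

| parameter | Default (PDB) | Default (PDB_REDO) | meaning |
|---|---|---|---|
| `rscc_min` | 0.9 | 0.9 | minimum real-space correlation |
| `occupancy_min` | 1.0 | 1.0 | minimum residue average occupancy |
| `rsr_good_max` | 0.24 | 0.165 | RSR above this fails the scored condition |
| `rsr_max` | 0.4 | 0.4 | RSR above this forces Bad |
| `tolerance` | 1 | 1 | scores in (0, t] are Dubious |
| `site_cutoff` | 4.5 Å | 4.5 Å | binding-site distance (inclusive) |
| `bond_cutoff` | 2.1 Å | 2.1 Å | covalent-contact distance (strict <) |

The good-RSR cutoff differs by dialect because the two databanks compute
RSR with different software, so the scales are not comparable; a profile
therefore records its `source` and refuses to run against a stats table of
the other dialect.  OWAB, R-free and resolution conditions ship disabled;
when enabled, the model-level ones (R-free, resolution) are evaluated once
and contribute to every component's score, since they are listed among the
per-component conditions without any separate mechanism.

**Default tolerance.**  No tolerance value is printed anywhere; we chose 1,
so a single marginal criterion yields Dubious and two yield Bad.  This is
the smallest value for which Dubious is reachable at all, and it makes the
worked example below behave as published.  It is user-settable per profile.

**Inclusive comparisons.**  "Minimum RSCC of 0.9" is read as `rscc >= 0.9`:
a residue sitting exactly at a printed threshold passes.  The covalent rule
is printed as "< 2.1 Å" and stays strict; the site rule ("nearer than
4.5 Å") is read as `<=` so that the boundary behaves predictably after
coordinates round-trip through the PDB format's three decimals.

**Missing data.**  An enabled condition whose statistic is absent counts as
unmet (conservative) and is reported separately in `missing_conditions`, so
a data gap is distinguishable from a measured failure.  A structure with no
stats table at all is rejected with reason `no_stats_data` rather than
classified.

## Ligand extraction and binding sites

Hetero residues that are not water and not on either exclusion list are
candidate ligand components; components closer than `bond_cutoff` are
merged into one multi-component ligand (glycosylation chains, covalent
conjugates).  Two lists modulate this:

* the **blacklist** (solvents, buffers, additives — sulfate, glycerol, PEG
  fragments, ...): its members are never ligands, and a candidate within
  covalent range of one is rejected (`covalent_to_blacklisted`), as is a
  candidate bonded to the polymer (`covalent_to_polymer`);
* the **non-propagating list** (mainly metal ions): its members are not
  ligands either, but contact with them neither rejects nor merges — a
  zinc-bridged inhibitor in a metalloprotein stays analyzable, which is the
  point of keeping the two lists separate.

Neither list's exact original membership is published; the shipped files
unite the common PDB additive codes with buffer codes of the kind collected
by ligand-quality tools, are documented as package data, and are fully
user-replaceable (`--blacklist`, `--non-propagating`).  The binding site of
a ligand is every polymer residue — plus every non-water, non-blacklisted
hetero residue, metals included — with any atom within `site_cutoff` of any
ligand atom.  Waters and blacklisted solvents are excluded from sites: they
would dominate site labels while carrying no stats interest.  Distances are
center-to-center with no van der Waals radii (a single printed distance, so
a single convention).  The neighbour search bins atoms into cells of edge
`>= cutoff` and sweeps 27 cells; the suite checks it against the exhaustive
double loop on 1,000 seeded configurations.

## Worked example

The published example ligand (guanosine-5′-monophosphate in entry 1A97,
chain C) carries RSR 0.154 and RSCC 0.86 as deposited, improving to 0.065
and 0.97 after re-refinement:

```{r}
ps <- default_profiles()
evaluate_component(residue_stats(rsr = 0.154, rscc = 0.86,
                                 avg_occupancy = 1),
                   profile = ps[["Default (PDB)"]])[c("score", "label")]
evaluate_component(residue_stats(rsr = 0.065, rscc = 0.97,
                                 avg_occupancy = 1),
                   profile = ps[["Default (PDB_REDO)"]])[c("score", "label")]
```

Only the RSCC condition fails in the deposited model (score 1 → Dubious at
tolerance 1); nothing fails after re-refinement (score 0 → Good).  These
two numbers are also what `scripts/acceptance.R` reports.

## The offline density engine

The classifier normally consumes databank statistics, but the package must
be testable end-to-end with no network.  The density module therefore
synthesizes a calculated map by placing on each atom a normalized isotropic
Gaussian of amplitude $\mathrm{occ} \cdot Z$ and width set by
$B + B_{\mathrm{added}}$:

$$ \rho(\mathbf r) = \mathrm{occ}\cdot Z\cdot
   \left(\tfrac{4\pi}{B + B_a}\right)^{3/2}
   \exp\!\left(-\tfrac{4\pi^2\,\lvert\mathbf r-\mathbf r_0\rvert^2}{B + B_a}\right) $$

with $B_a = 10\,$Å² by default (a single-Gaussian stand-in for a form
factor; the integral over space is exactly $\mathrm{occ}\cdot Z$, which the
tests verify to 1%).  RSR over a residue's mask (all voxels within
`mask_radius` = 1.5 Å of one of its atoms) is
$\sum\lvert\rho_{obs}-\rho_{calc}\rvert \,/\, \sum(\lvert\rho_{obs}\rvert+\lvert\rho_{calc}\rvert)$,
and RSCC is the Pearson correlation over the same voxels.  Grids are
orthogonal, evaluated at voxel centers; the on-disk format is a small text
header plus a flat value stream.  CCP4 ingestion would be a boundary
adapter and is not included (no CCP4 reader exists in the supported R
stack); the internal format is the contract.

These synthesized maps are **not** expected to match databank RSR values
numerically — the two databank pipelines disagree with each other, which is
exactly why the profiles carry dialect-specific cutoffs.  What the engine
supports is relative statements, and those are tested: a noiseless map
recovers RSR 0, RSCC 1 for every residue; noise injected into one residue's
mask makes that residue's RSR the model's largest; and mean RSR rises
(RSCC falls) monotonically with noise amplitude across 20 seeds.

## What the synthetic fixtures emulate — and what they don't

`fixture_spec()`/`make_complex()` build a glycine-like polymer on a
jittered helix with ligand components, at exact (±0.01 Å) planned
distances, plus solvent/metal decoys; `make_stats()` draws per-residue
statistics from within the region of stat-space that the chosen profile
maps to each residue's target label (Good: all pass; Dubious: exactly one
scored condition fails; Bad: two fail or the hard cap is broken — margins
of ≥ 0.005 keep the 3-decimal file format from crossing a threshold).  The
geometry is deliberately unphysical: no chemistry, rotamers or realistic
ligands are claimed, because only distances, occupancies and the stats
values reach the engine under test.  A green label-recovery test therefore
establishes that extraction, site detection, lookup and classification
compose correctly — it does not validate the thresholds against real
crystallographic practice, which is what the published calibration did.

All generation is deterministic per seed; every stochastic test states its
seed and repetition count.

## Numerical and degenerate-input choices

* Alternate locations: per atom name the highest-occupancy conformer wins,
  ties to the alphabetically first alt-loc; resolution never increases the
  atom count.  Occupancies outside [0, 1] are clamped with a warning.
* Multi-MODEL files: first coordinate model only (X-ray entries rarely
  carry more).
* Polymer vs hetero follows the record type (`ATOM` vs `HETATM`), needing
  no chemical dictionary; peptide-like ligands deposited as `ATOM` chains
  are out of scope.
* Hydrogens, when present, participate in distance tests like any atom.
* An empty binding site aggregates to Good over zero components, with a
  warning (vacuous truth, flagged rather than hidden).
* Empty residue masks, zero-variance masks and zero-density denominators
  are errors, not NaNs.
* Per-structure failures during a batch run are logged to standard error
  and skipped; the run continues.

## Known limitations

* No mmCIF input, no symmetry expansion: a site formed by a crystal
  contact's symmetry mate is invisible, matching the unknown behaviour of
  the original tool on the same point.
* UniProtKB-to-structure expansion and live databank retrieval are
  deliberately absent (offline scope); the run driver consumes a local
  directory of coordinate and stats files.
* The interactive visual review that follows automatic classification in
  GUI workflows is replaced by a plain-text override file applied after
  classification, preserving the re-classification semantics without a
  viewer.
* Whether ligands bonded to non-blacklisted hetero groups of other ligands
  should reject rather than merge is unspecified in the published
  algorithm; such contacts merge here.
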