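---
title: "Methods: steric-grid model filtering, enrichment metrics and off-target ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: steric-grid model filtering, enrichment metrics and off-target ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dockscreen)
library(dplyr)
```

`dockscreen` post-processes structure-based drug-discovery computations
against class B (secretin-family) GPCRs — the gut-hormone receptors GCGR,
GIPR, GLP1R plus VIPR1 and PAC1R. It covers four stages that sit around an
external docking engine: (1) filtering receptor-model ensembles by steric
intrusion into the peptide-occupied orthosteric pocket, (2) selecting
cluster representatives, (3) evaluating virtual-screening score lists, and
(4) correlating per-receptor docking scores of drugs with a clinical
risk ranking to flag potentially beneficial off-target binding.

## Ligand-density grid and the steric-intrusion score

Homology models of these receptors often have extracellular loops collapsed
into the orthosteric pocket, which no energy term penalises reliably. The
remedy used here is purely geometric. Given an ensemble of superposed
endogenous-peptide poses, a regular Cartesian grid (default spacing 1 Å) is
laid over the axis-aligned bounding box of all ligand heavy atoms, expanded
by a padding margin (default 2 Å). Each ligand heavy atom increments the
count of the cell containing it, every atom with equal weight; the per-cell
counts are the ligand density. Hydrogens are excluded throughout — they are
often absent from experimental structures and would make the density depend
on protonation conventions.

Cells partition into a **core** (density > 0: space the peptide actually
occupies) and a **shell** (zero-density cells adjacent to a core cell), plus
the remaining empty space. The steric score of a receptor model is the
number of *core* cells containing at least one receptor heavy-atom center —
cells are counted, not atoms, so a loop burying three atoms in one cell
intrudes once. The shell is computed and exposed because it is the relevant
region when screening small-molecule ligands rather than peptides, but the
default scoring uses the core only.

Numerical choices:

* **Cell membership** is half-open, `[origin + i·s, origin + (i+1)·s)` per
  axis, so every point maps to exactly one cell. Atoms exactly on the upper
  grid boundary are assigned to the last cell; otherwise the
  count-conservation invariant (sum of counts = number of binned atoms)
  would silently fail for bounding-box extrema when padding is zero.
* **Shell connectivity** defaults to 26 (faces, edges and corners); 6 and 18
  are available. The choice only affects the shell, never the core or the
  default score.
* **"Covered by the receptor"** means the atom *center* falls in the cell, no
  atomic radii — symmetric with the ligand-binning rule and parameter-free.
  A radius-based variant is deliberately not implemented.
* Coordinates are assumed already superposed in one frame (models built on a
  common template); the package performs no fitting anywhere.

`filter_by_steric()` retains the `floor(keep_fraction · N)` models with the
lowest scores (default 0.5, i.e. half of a 3000-model ensemble is
discarded), breaking cutoff ties by model id so reruns are deterministic.
`select_representatives()` then picks, from each of the `k = 5` most
populous clusters, its lowest-energy member; cluster-size ties prefer the
lower mean energy. Cluster labels and knowledge-based energies are inputs —
clustering and scoring are performed by external tools and only the
selection bookkeeping lives here.

## Enrichment metrics

Virtual-screening performance of a model is summarised from a ranked
active/decoy list (the study geometry: 10 known actives and 500
property-matched decoys, 50 per active). With `N` compounds, `A` actives and
`n = max(1, floor(fraction · N))`:

* **Enrichment factor**, concentration form: `EF = (a/n) / (A/N)` with `a`
  actives in the top `n`. The recall form `(a/A)/fraction` is available via
  an argument; printed EF values in the literature are convention- and
  rounding-dependent, so the convention is explicit rather than implicit.
* **ROC/AUC**: the probability that a random active outranks a random decoy,
  ties counted 1/2 (normalized Mann–Whitney U). The ROC curve is emitted
  with tied scores grouped, so its trapezoidal area equals the AUC exactly.
* **BEDROC(α)** (Truchon–Bayly): with 1-based active ranks
  `r_i`, `Ra = A/N`,
  `RIE = Σ e^{−α r_i/N} / (Ra (1−e^{−α})/(e^{α/N}−1))` and
  `BEDROC = RIE · Ra sinh(α/2)/(cosh(α/2) − cosh(α/2 − α Ra)) +
  1/(1 − e^{α(1−Ra)})`. The default α = 20 puts ~80% of the weight on
  roughly the first 8% of the list. Tied scores share their average rank.
  Closed forms for the maximum (`bedroc_max()`) and the random-ranking
  expectation (`bedroc_random()`, exact because a uniformly random placement
  gives E[RIE] = 1) serve as references.

Docking scores default to *lower = better*; the direction is always an
explicit argument, and all three metrics are invariant under strictly
monotone score transforms given a fixed direction.

## Off-target rank–score correlation and combined ranking

The clinical input is an integer ranking of reference beta-blockers by
reported propensity to disturb glucose homeostasis (1 = least disturbing;
0 = no clinical data). Two published assignments exist that swap the top
two drugs (carvedilol/nebivolol); both ship as fixtures and the choice is an
argument, with the figure-caption assignment (carvedilol = 1) as default.
Rank-0 drugs are excluded from correlations.

For every (receptor, site) pair, `rank_score_correlation()` correlates the
clinical rank with the docking score over the shared ranked drugs (at least
3 required). Pearson on the raw score is the default — the published
analysis juxtaposes binding affinity against an integer rank, and with five
drugs a rank-based coefficient is nearly degenerate — but Spearman is
provided, and the CLI reports both. A strongly positive coefficient means
the drugs least disturbing to glucose homeostasis show the strongest
predicted binding to the gut-hormone receptors: the signature of a
compensating incretin effect.

`combined_ranking()` merges both evidence sources: reference drugs keep
their clinical ordering; a query compound is inserted by its mean score
across all receptor/site keys, with ties broken toward the reference. The
published combination rule is not spelled out, so mean-score insertion is
this package's documented choice; a query with no clinical data that
out-scores every reference takes the reserved rank 0 (reproducing the
placement of the allosteric beta-blocker "compound 15" ahead of nebivolol).
`compare_query()` emits the comparison-plot content (reference mean ± SD per
replicate set vs clinical rank, query as a rank-free marker) as a plain
tibble, so no rendering backend is required; `autoplot()` draws it.

## Docking adapter

The docking engine is strictly external and optional: every other module
consumes score tables. `run_docking()` invokes a VINA-compatible executable
with the conventional flag set (`--receptor`, `--ligand`, `--center_*`,
`--size_*`, `--out`, `--seed`), captures the log verbatim, and parses the
multi-pose PDBQT output. Poses are re-sorted if the engine emitted them out
of order so the result invariant (non-decreasing scores, ranks contiguous
from 1) always holds; parse failures name the offending line. The test
suite exercises the contract with a stub shell script and a canned,
clearly-synthetic nine-mode output file. Default box specifications can be
derived from a ligand-density grid (`derive_box()`: core-centroid center,
core bounding box plus margin) — convenient defaults, not canonical
published boxes. Engine defaults (exhaustiveness, modes) are deliberately
not hard-coded; anything beyond the flag contract is passed via
`extra_args`.

Structure I/O reads PDB via `bio3d` and the PDBQT dialect via a small
fixed-column reader (AutoDock atom types such as `OA`/`HD` map back to
elements; branch/torsion records are ignored). Hydrogen detection uses the
element column when present, else the first alphabetic character of the
atom name. For alternate locations only the highest-occupancy conformer is
kept. Ligand-pose RMSD is computed over heavy atoms with *positional*
correspondence and no superposition — poses share the receptor frame in
re-docking, and whether a symmetry-aware correspondence was used in the
published self-docking is not stated, so the simpler positional convention
is used and documented here.

## Synthetic data: what it emulates, and what it does not

All generators take a mandatory seed and are pure functions of their
arguments.

* `gen_toy_complex()` emulates a superposed peptide-pose ensemble (Gaussian
  atom clouds, SD = half the pocket radius) plus a receptor whose atoms sit
  on a sphere outside the grid except for a chosen number planted into
  distinct occupied cells — so the true steric score is known by
  construction. Defaults (5 poses × 30 atoms, 6 Å pocket) give a
  peptide-sized occupied region on a grid of a few thousand cells.
* `gen_scored_library()` plants enrichment: active scores
  `N(−separation·σ, σ)`, decoys `N(0, σ)`, defaults 10 actives / 500 decoys
  matching the study's screening sets. `separation = 2` yields AUC ≈ 0.92,
  a realistic good model; 0 is the null.
* `gen_score_matrix()` plants a rank–score correlation across the
  5-receptor × 2-site key set. Because the clinical ranks form a *fixed*
  design of size 5, the sample Pearson coefficient is a biased estimator of
  the population value (for a population ρ of 0.9 its expectation is ≈ 0.93
  at n = 5); the generator therefore calibrates the signal-to-noise ratio by
  numerically integrating the expectation of the sample coefficient over the
  fixed design, so that the *expected sample* coefficient equals the
  requested `rho`. Recovery tests then compare the Monte-Carlo mean against
  `rho` directly.

What passing these tests shows: the geometry, counting, ranking and
correlation machinery is exact (against exhaustive enumeration and
brute-force oracles) and the statistical estimators are calibrated. What it
does not show: anything about real docking accuracy — synthetic poses have
no chemistry, planted score lists have Gaussian score structure that real
scoring functions do not, and the published per-drug score table (deposited
as supplementary data) is not redistributable here, so the published
correlation coefficients are reproducible only after placing that table at
`inst/extdata/betablocker_scores_s2.tsv`.

## Worked example

```{r example}
# 1. steric filtering of a toy ensemble
tc <- gen_toy_complex(receptor_intrusion = 7, seed = 11)
steric_score(tc$grid, tc$receptor)

# 2. enrichment panel for a planted screening list
lib <- gen_scored_library(separation = 3, seed = 2)
glance(enrichment_report(lib))

# 3. off-target correlation on a planted score matrix
m <- gen_score_matrix(rho = 0.9, seed = 5,
                      drugs = clinical_ranks("figure")$drug[-1])
rank_score_correlation(m$scores, clinical_ranks("figure"))

# 4. combined ranking with an out-scoring query
keys <- dplyr::distinct(m$scores, receptor, site)
query <- dplyr::mutate(keys, score = -12)
combined_ranking(m$scores, clinical_ranks("figure"), query,
                 query_name = "compound 15")
```

## Problem sizes and limitations

The shipped tests run the full pipeline at the study's bookkeeping scale
(3000-model ensembles, 510-compound libraries, 5 × 2 score matrices) and the
oracle comparisons at 100 random grids ≤ 20³ cells, 1000 random libraries of
up to 100 compounds, and 200 replicate correlation matrices — sizes chosen
so the whole suite completes in about a minute while keeping Monte-Carlo
standard errors small relative to the tested tolerances.

Known limitations: no structure preparation (protonation, charges), no
superposition or alignment, no mmCIF, no atomic radii in the coverage test,
and correlations over five drugs are fragile — a coefficient from n = 5 has
a wide sampling distribution, which is why dispersion is always reported
alongside.
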