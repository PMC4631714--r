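---
title: "Charge-tiered shape-distribution fingerprints: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charge-tiered shape-distribution fingerprints: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topotier)
```

## The model

`topotier` compares molecular topologies without alignment. The idea is a
charge-aware variant of shape distributions: instead of summarising one
global multiset of interatomic distances, the atoms are first partitioned
by partial charge into *tiers*, and each tier's internal distance
distribution is summarised separately. The default scheme is tripartite:

* **M** — charge < −0.1 e (polar negative),
* **N0** — −0.1 e ≤ charge ≤ +0.1 e (non-polar; both boundaries belong to
  this tier),
* **P** — charge > +0.1 e (polar positive).

For a tier with $n$ atoms, let $x_{ij}$ be the Euclidean distance between
its $i$th and $j$th atoms, with the diagonal $i = j$ skipped, so the sums
below run over the $n^2 - n$ ordered pairs. Five summaries are taken:

$$c_1 = \frac{\sum_i \sum_j x_{ij}}{n^3}, \qquad
  c_2 = \bar{x}_{ij}, \qquad
  c_3 = \frac{1}{n^2} \sum_i \sum_j (x_{ij} - \bar{x}_{ij})^2,$$

$$c_4 = \frac{\frac{1}{n^2} \sum_i \sum_j (x_{ij} - \bar{x}_{ij})^3}{c_3^{3/2}},
  \qquad
  c_5 = \frac{\frac{1}{n^2} \sum_i \sum_j (x_{ij} - \bar{x}_{ij})^4}{c_3^{2}} - 3.$$

$c_1$ is a count-weighted spatial dispersion, $c_2$ the mean interatomic
distance, $c_3$ the dispersion of the distance distribution, $c_4$ its
standardized skewness and $c_5$ its Fisher kurtosis (a Gaussian
distribution scores 0). The fingerprint of a molecule is the
concatenation of the five moments over the tiers in fixed order (M, N0,
P), a 15-vector under the default scheme. Tiers with zero or one atom
contribute five exact zeros. Two fingerprints are compared by the
Manhattan distance $d(\mathbf v_1, \mathbf v_2) = \sum_i |v_{1i} -
v_{2i}|$, with no vector or component normalisation: equal weight per
component, and deliberate sensitivity to molecular size.

Because only internal distances enter, the fingerprint is invariant under
rigid motion and atom reordering. It is *not* scale invariant: scaling
coordinates by $s$ scales $c_1, c_2$ by $s$ and $c_3$ by $s^2$ while
leaving $c_4, c_5$ unchanged. This is intended — with a ligand definition
spanning three orders of magnitude in size, a scale-free score would
conflate a tripeptide with a protein domain of the same shape.

Partitioning also caps the work: the per-molecule cost is
$\sum_t n_t^2 \le n^2$, one small distance matrix per tier rather than one
large one, which is what makes library-scale all-against-all matrices
tractable.

## Numerical conventions

Several small conventions are frozen here because downstream scores depend
on them:

* **Ordered pairs.** The double sums run over ordered pairs $i \ne j$;
  each unordered distance therefore appears twice. $c_2$–$c_5$ are
  unaffected by the duplication. For $c_1$ the full double sum is divided
  by $n^3$, read literally from the defining equations.
* **Normalization asymmetry.** $c_2$ is the sample mean over the
  $n^2 - n$ off-diagonal terms, while the central sums in $c_3$–$c_5$ are
  divided by $n^2$. The conventions differ by a factor $n/(n-1)$ that
  vanishes for large tiers; both are kept literally as defined, and the
  brute-force oracle in the test suite encodes exactly this reading.
* **$m_3$ in the denominators** is interpreted as the $c_3$ dispersion
  term (i.e. $c_4 = m_3^{\text{central}}/c_3^{3/2}$), the only reading
  that makes $c_4$ and $c_5$ dimensionless.
* **Degenerate tiers.** $n \le 1$ gives five zeros. If $n \ge 2$ but all
  distances are equal ($c_3 = 0$), $c_4 = c_5 = 0$ by extension of the
  same convention, avoiding 0/0.
* **Tier boundaries.** Charges exactly at ±0.1 e belong to the central
  tier (closed central interval). Custom schemes expose the per-boundary
  closure choice.
* **Tie-breaking.** Equal dissimilarity scores in ranked searches are
  ordered lexicographically by hit id, so results are deterministic.
* Double precision throughout; distances are never rounded before the
  moments are taken.

## Structure handling

PDB, MOL2 and PQR parsing is delegated to `bio3d`; `topotier` adds the
splitting and filtering layer:

* For multi-model (NMR-style) PDB entries only model 1 is used.
* Polymer (ATOM) records form one molecule per chain. Hetero (HETATM)
  records group by residue; residue groups whose atoms come within
  covalent range (sum of covalent radii + 0.45 Å) are merged, so
  multi-residue ligands such as bound peptides stay whole. Ligand–protein
  covalent links are severed at the polymer/hetero boundary.
* Alternate locations: the highest-occupancy altloc is kept, ties going
  to the first code in the file.
* Metal stripping removes all elements classified as metals, plus the
  metalloids Ge, As, Sb, Te and Po. B and Si are retained: both occur as
  covalent centers of ordinary ligands, whereas stripping targets
  coordination cores ahead of a generic charge model.
* Size filters keep molecules of 10–485 atoms (hydrogens included when
  present); this removes solvent and monoatomic ions at the bottom and
  caps ligands at roughly a 30-mer peptide at the top.
* Binding pockets come in two definitions: *residue-complete* (every atom
  of every polymer residue with at least one atom within 5 Å of the
  ligand) and *atom-level* (polymer atoms individually within 6.5 Å).
  Pocket fragments are fingerprinted as-is, with the same charge
  treatment as ligands; no re-protonation after truncation.

## Partial charges

When an input format carries charges (MOL2, PQR) they are used verbatim.
Otherwise `assign_gasteiger()` computes PEOE charges: electronegativity
$\chi = a + bq + cq^2$ per atom type (classic Gasteiger–Marsili
coefficients for H, C, N, O, S, P and the halogens), charge transferred
across each bond from the less to the more electronegative atom, damped
by $(1/2)^t$ at iteration $t$ and truncated after 6 iterations (the
classical schedule; a tolerance of 1e-6 on the largest update can stop it
earlier). Total charge is conserved exactly by construction.
Hybridization comes from SYBYL atom types when parsed from MOL2, else
from a heavy-atom degree heuristic (C: 4 neighbours → sp³, 3 → sp², else
sp; N: ≥3 → sp³, 2 → sp², 1 → sp; O: 2 → sp³, 1 → sp²). Elements without
parameters keep their formal charge, with a warning (or an error in
strict mode).

No protonation-state modelling is performed: inputs are taken as
protonated, or charges are supplied on input. Charge values near a tier
boundary can change tier membership between charge models; this is a
known sensitivity of any binned scheme and is left to the charge model
chosen upstream.

## Evaluation statistics

* **Enrichment factor.** For one active used as query against the
  remaining actives and all decoys,
  $EF_{x\%} = (a/d)\,/\,(A/D)$ with $a$ actives and $d$ decoys in the top
  $x\%$ segment of the ranked list and $A, D$ the unique counts in the
  set. The segment holds `round(x/100 * list length)` entries — half-up
  rounding with a floor of one entry, a choice that only matters for
  fractions like 0.25 % on small sets. If the segment contains no decoy
  the EF is reported as incalculable (`NA`) and excluded from averages
  but counted; a pseudo-count mode is available but non-default.
* **ROC AUC.** Each item queries the grouped dissimilarity matrix; the
  tie-corrected rank-sum (Mann–Whitney) estimator gives its AUC for
  retrieving its own group, and the average is taken over queries.
  Singleton-group queries are skipped with a warning.
* **Multi-conformer queries** score each database entry by the minimum
  over conformers (mean aggregation is available behind a flag), matching
  the practice of sorting combined hit lists to inspect the dissimilarity
  minima.
* Self-matches are kept in all-against-all reduced matrices (a zero-d
  self hit flags repeated near-identical molecules in the collection) but
  the query active is excluded in screening benchmarks; `exclude_ids`
  controls both.

## The synthetic generators, and what the tests do and do not show

Real benchmark corpora (PDB-wide ligand sets, decoy-enhanced screening
sets, curated pocket classifications) require large downloads and
external conformer generation, so the test surface is built from
synthetic structures:

* `make_molecule()` builds point clouds (line, ring, Gaussian blob,
  helix) with prescribed charges; elements are carbon throughout since
  fingerprinting consumes only coordinates and charges.
* `perturb_conformer()` displaces atoms isotropically, rescaled to an
  exact coordinate RMSD — a stand-in for conformational jitter.
* `make_grouped_benchmark()` (default 9 groups × 10 members, blob
  templates of 24–60 atoms with group-specific spread, 0.3 Å within-group
  RMSD, random poses) emulates a pocket-classification set at desk scale.
  Its "pockets" are shells of charge-complementary points offset 3–6.5 Å
  outward from the ligand atoms — a *fixture semantic*, not a claim about
  binding-site chemistry: it encodes exactly the property under test,
  that a cleft complements its ligand's shape and charge layout.

Passing tests therefore show that the machinery is correct and that the
method separates geometry-plus-charge classes when such classes exist.
They do not show screening power on real chemistry: synthetic blobs have
no bond structure, no conformational correlations, no decoys matched on
physical properties, and their group structure is cleaner than any real
ligand taxonomy. Full-scale benchmark numbers must come from runs on the
real corpora, for which the fingerprinting and evaluation machinery here
is the engine.

Desk-scale problem sizes used by the test suite and the acceptance
script: 100 random fixtures for the moment oracle, 1000 resamples for
the EF null, 500 for the AUC null, a 9 × 10 grouped benchmark (90
ligands + 90 pockets) for the end-to-end separation checks, and 720
comparisons for the conformational-sensitivity check. These sizes give
Monte-Carlo standard errors comfortably below the decision thresholds
while keeping the default run in seconds.

## Known limitations

* Global fingerprint only: substructure or surface-restricted matching is
  out of scope; adding or removing a large moiety changes the scores
  substantially, and very small molecules are poorly discriminated
  (narrow distance distributions crowd near each other).
* The charge model is a fast empirical one; QM-grade charges, tautomers
  and protonation states are upstream concerns.
* Bond perception is geometric (covalent radii); exotic geometries can
  mis-perceive bonds, which affects charge assignment but not the
  fingerprint of charge-carrying inputs.
* Tier membership of atoms with charges near ±0.1 e depends on the charge
  model; cross-toolkit score comparisons should use one charge treatment
  throughout.
* Scores are comparable only within one tier scheme; the TSV headers
  record the scheme signature and readers refuse mixed-scheme
  comparisons.
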