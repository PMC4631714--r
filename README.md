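# topotier

Alignment-free comparison of molecular topologies by **charge-tiered
shape-distribution fingerprints**, for ligand-based virtual screening and
binding-pocket similarity analysis at library scale.

## The method

Classical shape distributions summarise a molecule by the multiset of its
pairwise interatomic distances — rotation- and translation-invariant, but
blind to electrostatics. `topotier` first partitions the atoms by partial
charge into tiers (default tripartite: negative < −0.1 e, non-polar in
[−0.1, +0.1] e, positive > +0.1 e) and summarises each tier's internal
distance distribution by five moments. For a tier of *n* atoms with
off-diagonal ordered pairwise distances *x<sub>ij</sub>* (*i* ≠ *j*):

- *c₁* = ΣΣ *x<sub>ij</sub>* / *n*³ — count-weighted spatial dispersion
- *c₂* = mean of the *x<sub>ij</sub>* — average interatomic distance
- *c₃* = (1/*n*²) ΣΣ (*x<sub>ij</sub>* − *c₂*)² — statistical dispersion
- *c₄* = [(1/*n*²) ΣΣ (*x<sub>ij</sub>* − *c₂*)³] / *c₃*^(3/2) — skewness
- *c₅* = [(1/*n*²) ΣΣ (*x<sub>ij</sub>* − *c₂*)⁴] / *c₃*² − 3 — Fisher kurtosis

Tiers with ≤ 1 atom contribute five zeros. The fingerprint is the
15-vector (5 moments × 3 tiers, most negative tier first); two molecules
are compared by the Manhattan distance
*d*(**v₁**, **v₂**) = Σ |*v₁ᵢ* − *v₂ᵢ*|, with no normalisation — the score
deliberately responds to molecular size. Partitioning also caps the cost
at one small distance matrix per tier, which keeps PDB-scale
all-against-all comparisons tractable.

Around this core the package provides the full tool chain: PDB/MOL2/PQR
parsing and molecule splitting, metal stripping and the 10–485-atom
ligand filters, binding-pocket extraction (residue-complete within 5 Å or
atom-level within 6.5 Å of the ligand), Gasteiger-type (PEOE) partial
charges for inputs without them, ranked searches with multi-conformer
queries, reduced top-*k* dissimilarity matrices, enrichment factors at
top-scoring fractions, per-query ROC AUC over ligand groups, and
deterministic synthetic structure generators for testing.

## Worked example

```r
library(topotier)

# parse a charged MOL2 structure and fingerprint it
path <- system.file("extdata", "peoe_ref", "ethanol.mol2",
                    package = "topotier")
mol <- parse_structure(path)[[1]]
fingerprint(mol)
#> <topo_fp> ethanol_1 (tier counts: 1/7/1)
#>        M.c1        M.c2        M.c3        M.c4        M.c5       N0.c1
#>  0.00000000  0.00000000  0.00000000  0.00000000  0.00000000  0.23940757
#>       N0.c2       N0.c3       N0.c4       N0.c5        P.c1        P.c2
#>  1.95516181  0.32492802  0.04465145 -0.57553190  0.00000000  0.00000000
#>        P.c3        P.c4        P.c5
#>  0.00000000  0.00000000  0.00000000
```

The hydroxyl oxygen (charge −0.40 e) and its hydrogen (+0.21 e) occupy
the M and P tiers alone, so those blocks are zero; the seven non-polar
atoms populate the N0 block: mean interatomic distance 1.96 Å, dispersion
0.32 Å², mildly right-skewed, platykurtic.

```r
# a grouped benchmark: 9 ligand classes x 10 conformers, plus pockets
b <- make_grouped_benchmark(9, 10, seed = 1)
fps <- fingerprint_set(b$ligands)
fp_search(fingerprint(b$ligands[["g03_lig01"]]), fps, top_k = 5)
#>    query_id rank    hit_id         d
#> 1 g03_lig01    1 g03_lig01 0.0000000
#> 2 g03_lig01    2 g03_lig07 0.9292628
#> 3 g03_lig01    3 g03_lig04 0.9971498
#> 4 g03_lig01    4 g03_lig08 1.1313660
#> 5 g03_lig01    5 g03_lig09 1.3029456

gm <- grouped_matrix(dissimilarity_matrix(fps),
                     stats::setNames(b$groups, names(b$ligands)))
roc_analysis(gm)
#> <roc_report> 90 queries, average AUC = 1.0000
```

The query retrieves itself at *d* = 0 and its own group's conformers
next (*d* ≈ 1, against between-group scores an order of magnitude
larger); ranking every molecule against all others retrieves its group
with average AUC 1.0 on this clean synthetic set.

## Command line

A thin CLI over the same functions lives at `inst/cli/topotier.R`:

```sh
Rscript inst/cli/topotier.R synth --preset grouped --seed 5 --out demo/
Rscript inst/cli/topotier.R fingerprint --in demo/ --out fp.tsv.gz
Rscript inst/cli/topotier.R search --query demo/g01_lig01.mol2 \
    --db fp.tsv.gz --top 100 --out hits.tsv
Rscript inst/cli/topotier.R matrix --db fp.tsv.gz --top 100 --out top.tsv
```

Other commands: `extract` (ligand/pocket extraction over a PDB
directory), `screen` (enrichment factors from an active/decoy manifest),
`pocketbench` (per-query AUC from a grouped matrix). Exit codes: 0
success, 2 configuration error, 3 input error, 4 internal error.

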