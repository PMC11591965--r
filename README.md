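# netdiverge

Residue correlation networks meet molecular evolution. `netdiverge` is an
R package for asking a specific question about an enzyme family: **are the
residues that dominate the protein's internal communication network the
same residues whose evolutionary rates shifted after gene duplication?**

It was built for analyses of the alcohol-dehydrogenase kind — a protein
with a C-alpha trajectory from molecular dynamics, and an amino-acid
alignment of two paralogous gene clusters — but every stage is generic.

## What it computes

**Dynamics side.** From a trajectory (multi-model PDB or plain XYZ):
Kabsch superposition (iterative mean-structure or first-frame reference),
RMSD/RMSF profiles, essential-dynamics PCA, and the dynamic
cross-correlation map

    C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)

which becomes a weighted network (edge iff `|C_ij| >= cutoff`, weight
`-ln|C_ij|`) on which closeness, betweenness and degree centrality are
computed and ranked (`rank_top()`, the "top-15 per measure" table with its
overlap set).

**Evolution side.** From a two-cluster alignment with cluster trees
(p-distance + neighbor joining are included): per-site Fitch parsimony
change counts `X1, X2`, the coefficient of type-I functional divergence
`theta = 1 - r_lambda` by the gamma-Poisson moment method, and per-site
posterior probabilities of the rate-shifted state

    P(F1 | X1, X2) = theta Q1 Q2 / [(1 - theta) K12 + theta Q1 Q2]

with `Q` the negative-binomial marginal and `K12` the shared-rate joint of
the gamma-Poisson model.

**Integration.** Posteriors are mapped onto structure residues, both
scores are min-max normalized, correlated (Pearson/Spearman), and residues
that are high on both and near the diagonal are flagged as hotspots.

**Synthetic data.** Seeded generators produce trajectories with a
prescribed correlation structure and alignments with known divergent
sites, so the whole pipeline validates against planted ground truth with
no external data.

## Worked example: the planted-hotspot benchmark

Residues 1–3 are planted as both network hubs and canonically divergent
sites (constrained in cluster 1, relaxed in cluster 2); everything else is
background. One call runs trajectory simulation, DCCM, network
centralities, Fitch counts, the divergence model and the integration:

```r
library(netdiverge)
res <- run_reference_scenario(seed = 1)

print(res$dccm)
#> <dccm_map> 50 residues; off-diagonal C in [-0.039, 0.624]

print(res$divergence)
#> <divergence_result> 50 sites
#>   theta = 0.1967 (SE NA), r_lambda = 0.8033
#>   gamma rate fit: alpha = 1.276, beta = 1.499
#>   sites with posterior > 0.5: 6

print(res$table)
#> <integration_table> 50 residues (50 mapped)
#>   q vs betweenness pearson +0.702  spearman +0.409  (hotspots: 3)
#>   q vs closeness   pearson +0.688  spearman +0.026  (hotspots: 3)
#>   q vs degree      pearson +0.703  spearman +0.409  (hotspots: 3)

res$hotspots$closeness
#> [1] "ALA 1" "ALA 2" "ALA 3"
```

Reading the output: the sample DCCM reproduces the planted correlation
block (max target correlation 0.6); the moment estimate of theta on only
50 sites is noisy (truth here is ~0.5), but the *ranking* of sites by
posterior is what integration consumes, and all three planted residues —
and nothing else — are flagged as hotspots on every centrality measure.

The same analysis can be run stage by stage on disk, with a JSON manifest
(parameters, seed, md5 checksums) per stage:

```r
run_pipeline(list(seed = 1), outdir = "run1")   # simulate ... integrate
```

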