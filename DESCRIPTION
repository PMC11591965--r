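Package: netdiverge
Title: Residue Correlation Networks and Type-I Functional Divergence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links the internal dynamics of a protein to the molecular
    evolution of its gene family. From a C-alpha coordinate trajectory it
    computes the dynamic cross-correlation map (DCCM), turns it into a
    weighted residue interaction network, and ranks residues by closeness,
    betweenness and degree centrality. From a two-cluster amino-acid
    alignment it estimates the coefficient of type-I functional divergence
    (theta) under a gamma-Poisson model of site-specific substitution
    counts and assigns each site a posterior probability of rate-shifted
    (F1) status. An integration step normalizes both scores per residue and
    flags "hotspots" that are simultaneously network-central and
    evolutionarily divergent. Includes seeded synthetic generators for
    trajectories with prescribed correlation structure and for two-cluster
    alignments with known divergent sites, plus neighbor-joining trees from
    p-distances, per-site Fitch parsimony counts, trajectory superposition,
    RMSD/RMSF profiles and essential-dynamics PCA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    bio3d,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
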