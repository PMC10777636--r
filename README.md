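# coremf

Soil "core" microbiota — the taxa that are both highly abundant and present
in essentially every sample — are thought to do a disproportionate share of
the work in maintaining soil ecosystem multifunctionality (nutrient cycling,
fertility, enzyme activity). `coremf` is an R package plus a scripted
analysis workflow for testing that idea in zoned planting designs (e.g.
abandoned land / root zone / transition zone with a few replicates each). It
is aimed at microbial ecologists who have an OTU table, a taxonomy table,
sample metadata, and a table of measured soil functions, and want the full
downstream chain with exact small-sample inference and a tested,
reproducible implementation.

## What it computes

* **Core microbiota** by the dual abundance–occupancy criterion: core =
  top decile of OTUs by mean relative abundance **and** occupancy ≥ 95% of
  samples (with 12 samples that means all 12).
* **Ecosystem multifunctionality (EMF)** by the averaging approach: each
  soil variable is normality-screened (Shapiro–Wilk; log/sqrt transforms),
  min–max standardized to [0, 1], and EMF(s) is the mean across variables.
  Zones are compared by Kruskal–Wallis plus *exact* pairwise Wilcoxon
  rank-sum tests (all C(8,4) = 70 assignments enumerated for 4 vs 4; the
  two-sided floor is 2/70 ≈ 0.0286).
* **Community structure**: Bray–Curtis distances on the core community,
  classical PCoA with explicit negative-eigenvalue handling, and ANOSIM
  R = (r̄_between − r̄_within)/(M/2) with exhaustive permutation when
  feasible.
* **Weighted co-occurrence network** in the WGCNA style, from scratch:
  soft-thresholded unsigned adjacency A_ij = |cor|^β chosen by the
  scale-free criterion (R² ≥ 0.9, sample-size-capped power scan),
  topological overlap matrix TOM_ij = (L_ij + A_ij)/(min(k_i,k_j) + 1 −
  A_ij), average-linkage clustering of 1 − TOM with an adaptive tree cut,
  module eigengenes, kME module membership, and hub taxa (kME > 0.9).
* **Drivers of EMF**: random-forest %IncMSE importance of each taxon with a
  core vs non-core contrast, OLS regressions of EMF on cluster abundance,
  copiotroph/oligotroph composition per cluster, and zone-wise cluster
  comparisons.
* **A synthetic community generator** (log-normal latent factors ×
  multinomial read sampling) that plants a known core set, five correlated
  ecological modules, zone effects, and function variables causally driven
  by one module (+) and another (−) — so every stage of the pipeline is
  testable against ground truth.

## Worked example

The numbered scripts under `analysis/` run the whole study on simulated
data (seed 1):

```sh
Rscript analysis/01_simulate.R 1        # 3 zones x 4 reps, 400 taxa
Rscript analysis/02_core_taxa.R
Rscript analysis/03_multifunctionality.R
Rscript analysis/04_ordination.R 1
Rscript analysis/05_network.R
Rscript analysis/06_drivers.R 1
```

which prints, among other things:

```
core microbiota: 40 of 400 OTUs (Bacteria=40)
Kruskal-Wallis across zones: H = 6.00, p = 0.0498
  AL vs RZ: Wilcoxon p = 0.0286, change = -76.0%
PCoA1/PCoA2 explain 53.50% / 15.71% of core-community variance
  AL vs RZ: R = 0.6146, p = 0.0571
soft threshold power 3; 5 clusters (sizes 8, 8, 8, 8, 7); 1 unassigned
34 hub taxa with kME > 0.9
core vs non-core %IncMSE: W = 9869, p = 6.37e-03 (median 0.141 vs 0.000)
  cluster1: slope +0.303, R2 = 0.80, p = 0.0001
  cluster2: slope -0.248, R2 = 0.57, p = 0.0045
cluster1: 87.50% copiotrophs; cluster2: 25.00% copiotrophs
```

Reading this: the planted 40-taxon core is recovered exactly (all 40 are
top-decile and ubiquitous); EMF is highest in the root zone — the AL → RZ
change of −76% from the AL side corresponds to a +317% gain in RZ; the core
community separates AL from RZ (ANOSIM R = 0.61 at the exact-test floor
region of an n = 4+4 design); the network resolves the five planted
ecological clusters; the cluster built around the function-driving module
associates positively with EMF (R² = 0.80) and the antagonist cluster
negatively (R² = 0.57); the driver cluster is copiotroph-dominated and
core importance significantly exceeds non-core importance. Each stage
writes its tables under `results/`.

The same chain is available as one call:

```r
library(coremf)
report <- run_pipeline(default_config(seed = 1), outdir = "results/run")
report$headline
```

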