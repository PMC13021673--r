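# snfkit

Structural network fingerprints from multi-study regional MRI abnormality
reports.

## The problem

Structural MRI studies of conditions such as mild traumatic brain injury
(mTBI) report statistically significant regional abnormalities — grey- or
white-matter volume or probability changes from VBM, volumetry, tissue
probability mapping or tensor-based morphometry — but the findings are
heterogeneous across cohorts and are usually reported region by region,
outside any network context. Coordinate-based meta-analysis (e.g. ALE)
measures spatial peak convergence but discards study-level profiles, the
direction of each change, and large-scale network organisation.

`snfkit` implements the complementary, coordinate-free representation: each
study's findings are coded into a ternary **region-by-study fingerprint
matrix**

```
X(r, s) = -1  region r significantly decreased in study s
X(r, s) = +1  region r significantly increased in study s
X(r, s) =  0  region r not reported abnormal in study s
```

and the matrix is interrogated at the level of canonical large-scale brain
networks (DMN, salience, frontoparietal, limbic/memory,
sensorimotor/dorsal-attention, interhemispheric/callosal,
brainstem/cerebellar). It is intended for researchers performing structured
syntheses of regional morphometric findings; it deliberately does **not**
pool effect sizes, which are not comparable across morphometric pipelines.

## What it computes

For each network *k* with assigned region set *R<sub>k</sub>* (regions may
belong to several networks and count fully in each):

* **Total abnormal load** `L_k = sum over r in R_k, s in S of |X(r,s)|`
* **Distinct abnormal regions** `N_k = #{r in R_k : X(r,s) != 0 for some s}`
* **Abnormality-per-region index** `A_k = L_k / N_k` (NA when `N_k = 0`)
* **Mean direction** `D_k = (1/L_k) * sum X(r,s)` in [-1, 1]
  (-1 = uniform loss, +1 = uniform gain; NA when `L_k = 0`)

Plus:

* the **co-alteration matrix** `C(r1, r2)` = number of studies reporting both
  regions abnormal (direction-blind), and the undirected graph with an edge
  wherever `C >= tau` (default `tau = 2`, replication in two independent
  studies), with connected modules, node strengths and a threshold
  sensitivity sweep;
* **row-centered Gram-matrix PCA**: `Sigma = X~ X~' / (|S| - 1)` over the
  row-centered matrix, eigendecomposition `Sigma v_i = lambda_i v_i`, and
  region scores `v_i * sqrt(lambda_i)` (principal-coordinate convention, so
  full-dimensional scores preserve inter-region distances);
* **Ward hierarchical clustering** of region abnormality profiles
  (Euclidean, ward.D2 heights, deterministic tie-breaking), with Newick
  export and an adjusted-Rand agreement score against dominant-network
  labels;
* a **planted-network synthetic generator** (per-network detection and loss
  probabilities, per-study sensitivity panels) with parameter-recovery
  estimators, for validating the whole chain;
* a packaged, documented reconstruction of a 10-study mTBI corpus
  (35 atlas regions x 10 studies) with per-cell provenance.

## Worked example

```r
library(snfkit)

fx <- mtbi_fixture()
fx$matrix
#> <fingerprint_matrix> 35 regions x 10 studies; 42 abnormal entries (40 decreases, 2 increases)

metrics_table(fx$matrix, fx$scheme)[, c("network", "region_count", "load",
  "distinct_regions", "per_region_index", "mean_direction")]
#>   network region_count load distinct_regions per_region_index mean_direction
#> 1     DMN            8    9                8         1.125000     -0.7777778
#> 2     SAL            5    5                5         1.000000     -0.6000000
#> 3     FPN            9   12                9         1.333333     -1.0000000
#> 4     LIM            8   11                8         1.375000     -1.0000000
#> 5     SMN            6    6                6         1.000000     -1.0000000
#> 6     CAL            1    1                1         1.000000     -1.0000000
#> 7     BSC            3    3                3         1.000000     -1.0000000
```

The limbic/memory network carries the highest abnormality-per-region index
(1.375: its affected regions recur across studies), with the frontoparietal
and default mode networks next; every network's mean direction is negative
except for the two isolated cingulate volume increases that pull the DMN and
salience means above -1. At the replication threshold:

```r
g <- build_graph(coalteration_matrix(fx$matrix), tau = 2, fx$scheme)
g
#> <coalteration_graph> tau=2; 35 nodes, 1 edges, density 0.0017
connected_modules(g)[[1]]
#> [1] "HIPP_B" "THAL_B"
```

the single replicated co-alteration pair is hippocampus-thalamus, the
limbic/relay core; lowering `tau` to 1 raises the edge count to 109
(density 0.18) as single-study co-reporting floods in. The embedding and
dendrogram:

```r
emb <- snf_embedding(fx$matrix, n_components = 2, fx$scheme)
emb
#> <snf_embedding> mode=gram; 35 regions, 2 components; PC1 explains 31.5%

cl <- ward_dendrogram(fx$matrix)
cluster_network_agreement(cl, fx$scheme, k = 7)
#> [1] 0.08003753
```

PC1 carries 31.5% of the variance and separates the recurrently-reported
midline/limbic rows from single-study regions. The cluster-vs-network
adjusted Rand index at k = 7 is 0.08 — weakly positive: with 28 of 35
regions reported exactly once, profile clustering on this corpus can only
partially recover network labels. (Under dense reporting the pipeline does
recover planted network partitions — the synthetic-module runs in
`scripts/acceptance.R` achieve ARI >= 0.9 in 20 of 20 seeds.)

A shell interface mirrors the R surface:

```sh
Rscript inst/cli/snf.R fixture --out corpus
Rscript inst/cli/snf.R report --matrix corpus/fingerprint_matrix.csv \
  --regions corpus/roi_metadata.tsv --studies corpus/study_metadata.tsv \
  --out report
```

writing `metrics.csv`, `edge_list.tsv`, `graph.graphml`, `eigen_summary.csv`,
`scores.csv`, `dendrogram.newick`, `merge_table.csv` and `run_summary.json`.

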