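---
title: "Structural network fingerprints: model, parameters and design choices"
author: "snfkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural network fingerprints: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snfkit)
```

## The representation and its assumptions

`snfkit` synthesizes regional structural-MRI findings across independent
studies without pooling effect sizes. Each study contributes a column of a
ternary matrix `X` over atlas regions: `-1` for a reported significant
decrease (volume, tissue probability, or tensor-derived contraction), `+1`
for a reported increase, `0` for "not reported abnormal". Three assumptions
are built into this coding and everything downstream inherits them:

* **Reported, not measured.** A `0` means a study did not report the region,
  not that the region was measured and found normal. All metrics therefore
  quantify convergence of *reporting*, and are exposed to publication and
  reporting bias in the source literature.
* **Direction, not magnitude.** Morphometric pipelines differ enough
  (smoothing, normalisation, thresholds) that absolute effect sizes are not
  comparable; only the sign of each finding is retained.
* **Atlas-level consolidation.** Multiple significant clusters inside one
  atlas region in one study collapse to a single cell. Left and right
  instances of a structure are distinct regions when the source reports
  laterality; `BILATERAL` is used only for findings reported bilaterally.

Opposite-sign reports for the same (region, study) cell have no natural
resolution at this granularity, so the default policy is to raise an error;
an explicit `MAJORITY` override resolves by count and still refuses exact
ties. Silent resolution would fabricate data.

## Network metrics

Regions are annotated with one or more of seven canonical systems (DMN, SAL,
FPN, LIM, SMN, CAL, BSC); alternative grouping schemes load from the same
TSV format, so the vocabulary is a default rather than a constraint. For the
region set `R_k` of network `k`:

| metric | definition | meaning | range |
|---|---|---|---|
| `L_k` | number of non-zero cells over `R_k` | reporting frequency | `0 .. |R_k||S|` |
| `N_k` | regions of `R_k` non-zero in >= 1 study | spatial extent | `0 .. |R_k|` |
| `A_k` | `L_k / N_k` | recurrence per affected region | `1 .. |S|`, NA if `N_k = 0` |
| `D_k` | mean of non-zero cells | direction balance | `-1 .. 1`, NA if `L_k = 0` |

Dual-membership regions count with full weight in every network they belong
to — membership defines `R_k`, and fractional splitting would manufacture a
weighting scheme the representation cannot justify. Sums of `L_k` over
networks therefore double-count such regions by design. Undefined ratios are
emitted as `NA`, never 0: a zero would fabricate a "mixed direction" or
"no burden" signal. The table also carries `L_k / |R_k|` as a supplementary
column since the per-region bar chart one usually draws can be normalised
either way; the primary index is `L_k / N_k` as defined. Ranking ties are
broken by scheme order so regression outputs are stable.

## Co-alteration graph

`C(r1, r2)` counts studies in which both regions are non-zero, ignoring
sign — co-alteration is about joint involvement, and a decrease co-occurring
with an increase is still co-occurrence. The graph at threshold `tau` keeps
edges with `C >= tau`; `tau = 2` by default, the minimal replication
requirement (an edge must recur in two independent cohorts). The sweep over
`tau = 1, 2, 3` exposes the robustness of any module to this choice; edge
sets are nested in `tau` and densities non-increasing, which the tests
verify as an invariant.

Two operationalisation choices were genuinely open:

* **"Module" = connected component** of the thresholded graph. Community
  detection (weighted greedy modularity) is available via
  `modularity_modules()` but is not the default: on sparse replication
  graphs components are already the interpretable unit, and they carry no
  tuning parameters.
* **Node set = regions abnormal in at least one study.** Never-reported
  regions cannot bear edges; including them would only deflate density.
  The restriction is recorded in the graph object and the run summary.
* **Dominant network for colouring/labelling** of dual-membership nodes:
  first match in a fixed priority order (DMN > LIM > SAL > FPN > SMN >
  CAL > BSC), chosen once for determinism and overridable per scheme.

## PCA on the Gram form

After row-centering (each region's mean across studies subtracted,
emphasizing profile shape over reporting frequency), the decomposition works
on the region-by-region matrix

```
Sigma = X~ X~' / (|S| - 1),
```

i.e. the Gram form with the `1/(|S|-1)` covariance normalisation, not the
conventional study-by-study feature covariance. Scores follow the
principal-coordinate convention `v_i * sqrt(lambda_i)`, which makes
full-dimensional scores reproduce inter-region Euclidean distances (up to
the global `1/sqrt(|S|-1)` factor) — the natural convention when regions are
the analysis unit. The conventional PCA is exposed as `mode = "feature"`,
and the singular-value duality (non-zero spectra of the two forms are equal)
is enforced as a test invariant rather than assumed. Because rows are
centered, the all-ones study vector is a null direction and at most
`|S| - 1` eigenvalues are non-zero.

Numerical conventions, stated once and tested: eigenvalues are clamped at
`-1e-9` (anything below is an error, anything in `(-1e-9, 0]` is numerical
zero); positive-eigenvalue count uses the same `1e-9` cut; each eigenvector
is unit-norm with its largest-magnitude loading made positive (first such
on ties), so signs are reproducible across platforms; trace and distance
identities are checked at `1e-6` relative, eigen residuals at `1e-8`.

## Ward clustering

Regions are clustered on their raw ternary rows by default — the profile
vector a study-level reader would recognise — with `use_centered = TRUE`
available for consistency with the PCA view; both modes are tested. The
implementation is the Lance–Williams recurrence for Ward linkage on squared
Euclidean distances, reporting ward.D2-convention heights (two singletons
merge at their Euclidean distance). It is written out rather than delegated
so that the tie-break is pinned: among minimal-distance pairs, the pair
whose clusters contain the lowest original row indices merges first, with
ties in distance detected at `1e-9` relative tolerance (ternary data makes
exact rational ties common, and floating-point noise must not reorder
them). Tests cross-check the trees against `stats::hclust(method =
"ward.D2")` on tie-free continuous data and against a direct centroid-form
evaluation of the Ward objective on ternary data.

Dendrograms export to Newick with branch length = parent merge height minus
child merge height (leaves at height 0), giving an ultrametric tree whose
leaf-to-root depth is the final merge height. Cluster-vs-network agreement
is the adjusted Rand index between a `k`-cut and dominant-network labels;
the contingency-table implementation is cross-checked against pair counting
and `mclust`.

## The synthetic generator

`generate_fingerprint()` plants a known network partition: region `r` in
network `k` is non-zero in study `s` with probability `p_k * eta_s`, and
negative with probability `q_k` given non-zero, all cells independent. This
is the simplest generative model consistent with the ternary coding. It
emulates network-organised convergent reporting with study-level
sensitivity differences; it does **not** emulate correlated reporting
within a study, publication bias, atlas mis-assignment, or directionality
that depends on post-injury timing — so recovery results validate the
estimators and the pipeline mechanics, not the realism of any particular
corpus. `eta` may be a per-study vector in `(0, 1]` or a network-by-study
matrix in `[0, 1]`; the matrix form (0 = this study's panel does not cover
that network) is what makes planted-module recovery testable with
network-exclusive study panels.

Recovery uses method-of-moments estimators: `p_hat = L_k / (|R_k| |S|
mean(eta_k))` and `q_hat = (1 - D_k) / 2` from the identity
`E[D_k] = 1 - 2 q_k`, each with a binomial standard error. The validation
conditions are fixed: two networks of 10 regions, `p = (0.8, 0.2)`,
`q = (0.9, 0.5)`, 500 studies for parameter recovery (both estimators
within 0.05); and `p = q = 0.9`, 30 exclusive-panel studies, 20 seeds for
module recovery (components at `tau = 2` vs the planted partition,
ARI >= 0.9 expected in at least 18 of 20 seeds). Reproducibility is exact:
one integer seed determines the realization bitwise.

## The packaged corpus

`mtbi_fixture()` returns a 35-region x 10-study matrix reconstructed from
the published study-by-study narrative of T1-weighted mTBI findings, with
hemisphere, tissue class and network assignments per region and per-cell
provenance tags. Nine study columns transcribe enumerated findings
(including the one cohort reporting only cingulate volume *increases*); the
tenth study has no enumerated region list in its source and is populated as
a documented low-confidence reconstruction (thalamus, hippocampus, corpus
callosum), flagged `RECONSTRUCTED_LOW_CONFIDENCE` in both the study
metadata and the provenance table. Consolidation granularity (e.g. keeping
bilateral and right-hemisphere instances of the superior frontal gyrus as
distinct rows, splitting white-matter tracts individually) was chosen once
so the corpus has exactly 35 distinct regions, and is documented row by row
in `provenance.tsv`. Analyses conditional on unenumerated cells of the
original figure are out of reach by construction; the packaged tests
therefore assert only narrative-backed facts (dimensions, the location of
the two positive cells, precuneus recurrence, provenance flags, and the
rank of DMN/limbic per-region indices).

## Problem sizes and limitations

The test suite and the acceptance script run on deliberately small problem
sizes — random matrices up to 20 x 10 for oracle equivalence (200 draws),
8 x 4 for clustering oracles, 20-region/500-study synthetic corpora — which
exercise every code path while keeping a full run in seconds. Known
limitations, restated so they are not discovered the hard way: the
framework provides no inferential statistics (no permutation nulls for
edges, no confidence intervals on metrics); it cannot distinguish absence
of abnormality from absence of reporting; per-study columns are treated as
independent even when cohorts overlap in the literature; and the packaged
corpus is a narrative reconstruction suitable for methods work, not a
clinical reference dataset.
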