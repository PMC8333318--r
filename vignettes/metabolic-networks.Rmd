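---
title: "Metabolic covariance networks: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic covariance networks: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabnet)
```

## The analysis model

`metabnet` compares the *metabolic covariance networks* of two subject
groups. The unit of analysis is a group, not a subject: after
preprocessing, region *i* and region *j* are "connected" in a group's
network to the extent that their metabolism values correlate across
that group's subjects. The chain is:

1. **Regional means.** Either supplied directly as a subjects × regions
   table, or extracted as per-region voxel means from volumetric images
   over an integer-labelled atlas (`extract_roi_means()`). Extraction
   assumes the images are already voxel-aligned with the atlas; no
   spatial normalization or smoothing is performed here.
2. **Whole-brain normalization** (`normalize_whole_brain()`). Each
   subject's regional means are divided by that subject's whole-brain
   mean, removing global metabolic scale (scanner dose, global
   metabolism). With voxel counts available the whole-brain mean is the
   voxel-count-weighted mean over atlas foreground — identical to the
   mean over all in-atlas voxels — which is the default because it
   matches normalization of the image by its global signal. The
   unweighted mean of the regional means is available via
   `method = "region"` and is the automatic fallback for table-only
   input.
3. **Covariate residualization** (`residualize()`). Per region, OLS
   residuals on an intercept, age (years), sex (0/1) and fasting
   glucose (mmol/L). The regression pools both groups in one design
   *without* a group term: residualizing per group (or including a
   group indicator) would subtract each group's mean and erase exactly
   the between-group signal the downstream contrast is meant to find.
   A per-group option exists for sensitivity analysis. Residuals are
   exactly orthogonal to the design, so injected linear covariate
   effects vanish to numerical precision.
4. **Correlation and thresholding.** Per group, the regions × regions
   Pearson matrix of the residuals (`correlation_network()`), binarized
   at each density *D* of a sweep by keeping the
   `E = floor(D · N(N−1)/2)` strongest edges
   (`threshold_by_density()`, `density_sweep()`).
5. **Graph statistics** (`clustering_coefficient()`,
   `characteristic_path_length()`, `small_world()`,
   `betweenness_centrality()`, `classify_hubs()`).
6. **Permutation inference** (`permutation_test()`).

The key statistical assumption of step 6 is exchangeability of subjects
under the null: if the groups do not differ, any relabelling of
subjects is as likely as the observed one, so rebuilding both group
networks under random relabellings yields the null distribution of any
network statistic — with no distributional assumptions on the
metabolism values themselves.

## Statistics and conventions

* **Clustering coefficient.** `C_i` is the fraction of a node's
  neighbour pairs that are themselves connected, 0 for degree < 2;
  `Cp` is the unweighted mean over all nodes (including degree-< 2
  nodes), bounded in [0, 1].
* **Characteristic path length.** Mean unweighted shortest-path
  distance over all unordered node pairs; 1 on a complete graph.
  Defined only for connected graphs (below).
* **Betweenness.** `B(i)` sums, over unordered pairs `(s, t)` with
  `i ∉ {s, t}`, the fraction of shortest s–t paths through *i*
  (Brandes' accumulation internally; pinned by the star fixture
  `B(centre of K1,4) = C(4,2) = 6`). Normalized centrality
  `b_i = B(i) / mean(B)` has unit mean whenever any path passes through
  any node; on a graph where every `B(i) = 0` (complete graph) all
  `b_i` are defined as 0 with a warning. A region is a **hub** when
  `b_i` exceeds a threshold — 1.5 by default, with 2.0 the common
  stricter alternative; both appear in the applied literature and both
  are supported rather than adjudicated.
* **Small-world indices.** `γ` and `λ` divide `Cp` and `Lp` by their
  means over an ensemble of degree-preserving random references
  (Maslov–Sneppen double edge swap, `n_swaps = 10` attempted swaps per
  edge, ensemble of 100 by default); `σ = γ/λ` exactly, and `σ > 1` is
  read as small-world organization. References are required to be
  connected and are redrawn (up to `max_retries`) otherwise.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| density sweep | 0.10–0.40, step 0.01 | edge fraction | standard sweep for binarized covariance networks; below ~0.10 a 90-node network typically fragments |
| edge ranking | `signed` | — | most-positive correlations first, the covariance-network convention; `absolute` available |
| edge-count rounding | `floor` | — | never exceeds the requested density; `D = 1` is allowed and yields the complete graph |
| tie-breaking | lexicographic (i, j) | — | bit-reproducible thresholding across platforms |
| hub threshold | 1.5 (alt. 2.0) | dimensionless `b_i` | see above |
| permutations | 1000 | count | add-one p resolution ≈ 0.001; 95th-percentile critical value |
| reference ensemble | 100 (20 inside permutation loops) | count | γ/λ standard; the reduced in-loop ensemble keeps σ testing tractable and is configurable |
| connectedness | strict | — | `Lp`/`B(i)` are undefined on disconnected graphs; permissive mode drops those densities with a warning instead |

Numerical details pinned by tests: the permutation critical value is
`quantile(null, 0.95)` (R's default type-7 interpolation); the
empirical p is `(#{null ≥ observed} + 1)/(reps + 1)`, never exactly 0;
permutations whose split yields a disconnected graph for a path-based
metric are resampled and counted, and more than 10% resampling aborts
the test; one relabelling is shared across all densities and metrics,
so per-density results have the correct joint null (and support a
max-statistic option). Per-density decisions are reported without
multiplicity correction across densities, matching the way density
sweeps are conventionally presented; the regional contrast
(`group_metabolic_contrast()`) does control family-wise error, by a
max-|t| label permutation across regions.

## The synthetic cohort generator

`generate_cohort()` emulates a matched two-group imaging cohort:
balanced 0/1 sex, age ≈ 52–54 ± 8 years, fasting glucose ≈ 5.3–5.4
mmol/L, linear covariate effects (defaults: 0.02 per year of age, 0.1
per sex unit, 0.1 per mmol/L glucose), Gaussian residual noise
(`noise_sd = 0.2`) around a baseline of 10 arbitrary metabolic units.
All randomness flows from one seed: the latent graphs consume the
stream seeded with `seed`, subject sampling the stream seeded with
`seed + 1`, so `latent_graph_metrics()` can regenerate the ground-truth
graphs without drawing subjects, and generation is bit-reproducible.

The group structure lives in latent binary graphs. The control graph
is Watts–Strogatz: a ring lattice of degree 6 with each edge rewired
with probability 0.3. The patient graph perturbs it by `patient_effect`
under one of three models — `rewired` (long-range shortcuts replaced by
triangle-closing local edges), `block` (between-module edges folded
into 6 contiguous modules), or `shared` (identical graphs; the null
construction). Both non-null perturbations raise the latent clustering
coefficient and path length at constant edge count, and skip any
removal that would disconnect the graph.

A latent graph becomes a correlation matrix as adjacency plus diagonal
loading sized so the smallest eigenvalue is 0.05, standardized to unit
diagonal. This mapping is simple and exactly invertible, but it has a
hard ceiling: a correlation matrix with a uniform value *r* on edges
and exact zeros elsewhere must satisfy `r ≤ 1/|λ_min(A)|`. That bound
drove the lattice-degree default: at degree 10, `|λ_min| ≈ 4.5` caps
edge correlations near 0.22, which 50 subjects per group cannot
reliably separate from zero (edge recovery ≈ 40%); at degree 6,
`|λ_min| ≈ 3.8` permits *r* ≈ 0.26 and ≈ 70% recovery at 40 regions.
Diffusion (`(I − αA)⁻¹`) and Gaussian-Markov precision mappings were
evaluated and recover worse, because they spread correlation mass onto
non-edges.

**What the generator does not emulate.** No PET physics (point-spread,
attenuation, partial-volume spill-over between adjacent regions), no
spatial autocorrelation between neighbouring regions beyond the latent
graph, no non-Gaussian tails, and — most importantly — real metabolic
covariance is far stronger and denser than the exact-zero synthetic
construction allows. A consequence measured during development: at 90
regions, even a maximal latent perturbation is not sample-detectable
from 50 subjects per group under this mapping (the 305 latent edges sit
at relative density 0.067, below the 0.10 sweep floor, and are only
half-recovered), whereas at 40 regions the same machinery detects the
injected difference in ≈ 90% of cohorts. Passing tests therefore
validate the *inference machinery* — calibrated type-I error,
directionally correct detection when structure is recoverable — not any
claim about effect sizes in real PET data.

## Test and simulation scale

The test suite checks the graph statistics against brute-force oracles
(literal neighbour-pair counting, Floyd–Warshall, the combinatorial
path-count identity for betweenness): exhaustively over all connected
labelled graphs on 4–5 nodes, on 200 random connected graphs each at
6–8 nodes, and on 100 random 30-node graphs, at tolerance 1e-9.
Calibration simulations use 200 null cohorts (type-I error at density
0.20, 40 regions, 100 relabellings each; the rejection rate must sit in
the 95% binomial band around 0.05) and 50 effect cohorts
(block-modular patients, `patient_effect = 0.6`, latent ΔCp ≥ 0.1
verified before power is claimed; detection = a significant,
correctly-signed Cp or Lp difference at ≥ 1 density of the 0.15–0.40
sweep). These sizes keep the full suite to a few minutes while leaving
the binomial bands meaningful.

## Known limitations

* Weighted, directed and efficiency-based network formulations are out
  of scope, as are statistical (r- or p-value) edge thresholds.
* The voxelwise contrast of a full imaging pipeline is replaced by a
  region-level ANCOVA-style contrast with max-|t| permutation control;
  cluster-extent logic has no regional analogue.
* `Lp` requires connectedness; rather than imputing disconnected pairs
  (e.g. harmonic means), the package restricts the density range, which
  is the conservative convention.
* Synthetic full-scale (90-region) cohorts under-represent detectable
  structure, as described above; conclusions about real-data power
  should not be drawn from the generator.
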