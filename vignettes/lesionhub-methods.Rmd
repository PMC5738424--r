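---
title: "Methods: lesion models of functional network topology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lesion models of functional network topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and numerical choices
behind `lesionhub`, in the spirit of a methods section: what is computed,
under which assumptions, and where the design was genuinely open.

## 1. From connectivity to binary networks

The pipeline consumes symmetric functional connectivity matrices on the
Fisher-z scale (`fisher_z()` applies `atanh` elementwise; off-diagonal
correlations must lie strictly inside (−1, 1), and the diagonal is fixed at
zero). Negative z values are carried through this stage and discarded only
at binarization: `threshold_by_sparsity()` ranks the n(n−1)/2 upper-triangle
weights and keeps the strongest `round(s · n(n−1)/2)` strictly positive ones
as edges of an undirected, unweighted graph.

Conventions worth making explicit:

* **Tie-breaking.** Rank ties at the sparsity cutoff are broken by
  lexicographic (row, column) order. Ties are measure-zero for real data but
  common in constructed examples; a deterministic rule makes results
  bit-identical across platforms.
* **Saturation.** If fewer positive weights exist than requested, all
  positive weights are kept and the achieved sparsity is recorded on the
  `binary_network` object rather than silently ignored.
* **Grids.** Sparsity grids use step 0.01 with values rounded to two
  decimals, avoiding floating-point drift in grid membership tests.
  `sparsity_range()` returns the usable range for a cohort: the smallest
  grid sparsity at which every subject's network is fully connected, and the
  smallest retaining every subject's positive edges. Because connectivity is
  monotone in the edge count, the scan is a binary search per subject.

## 2. Topology metrics

Global efficiency is the mean inverse shortest path length over node pairs;
local efficiency is the mean, over nodes, of the global efficiency of each
node's neighbour-induced subgraph (the node itself excluded). Two
conventions close the definition on degenerate inputs: unreachable pairs
contribute efficiency 0 (the standard convention for disconnected graphs),
and neighbourhoods with fewer than two nodes score 0 in local efficiency.
Note that some libraries compute "local efficiency" with distances taken in
the full graph minus the vertex rather than in the neighbour-induced
subgraph; the neighbour-subgraph definition used here is the one standard in
the brain-connectivity literature, and the test suite pins it against an
independent brute-force Floyd–Warshall oracle on every 5-node graph
(exhaustive 1024-graph sweep).

The small-world index is
`sigma = (locE / <locE>_null) / (gE / <gE>_null)`, with null means over
`n_random = 100` degree-matched random networks produced by attempted
double-edge swaps (default `10 · |E|` attempts; swaps creating self-loops or
multi-edges are rejected, so the degree sequence is preserved exactly).
Nulls do not enforce connectedness: rewired nulls of a connected graph are
almost always connected at the densities in play, and conditioning on
connectedness would bias the null ensemble. Shortest-path computations are
BFS in compiled code; at the default scale (180 nodes, s = 0.15) a full
sigma evaluation with 100 nulls takes about one second, which is what makes
per-patient sigma labels and permutation inference tractable.

AUC summaries over a sparsity grid use the trapezoid rule — the integral is
specified but its discretization is not, and the trapezoid rule is exact for
the piecewise-linear curves a 0.01 grid induces.

## 3. The linear SVR lesion model

Features are per-node lesion percentages in [0, 1]; nodes lesioned in no
patient are dropped (and recorded) because a constant-zero feature carries
no information and would receive an arbitrary null band. Optional covariates
(total lesion volume, age, time post onset) are min–max scaled to [0, 1] so
that they are commensurate with the lesion features; the lesion features
themselves are *not* standardized — they already share a scale, and
standardizing would inflate rarely-lesioned nodes.

The regression is epsilon-SVR with a linear kernel and the conventional
defaults C = 1, epsilon = 0.1, stopping tolerance 1e−3. The solver is a
sequential-minimal-optimization routine on the standard 2n-variable dual
with a precomputed Gram matrix; the test suite cross-checks its weights and
bias against an independent libsvm-based implementation (`e1071`) on random
problems. The Gram-matrix formulation is what makes the permutation
machinery cheap: leave-one-out folds and label shuffles reuse the same
kernel, so a 96-patient, 200-permutation run costs seconds rather than
hours.

**Label standardization.** The epsilon-insensitive loss is scale-dependent
in y: with epsilon = 0.1, any label whose spread is well below the tube
width is fitted perfectly by a constant, and the model degenerates. Network
metrics live on exactly such scales (gE and locE in [0, 1] with
between-patient SDs of order 0.01–0.03). `lesion_model()` therefore z-scores
the labels before fitting and maps predictions, weights and bias back to the
original units. The permutation nulls are computed under the same transform,
so accuracies, P values and significance flags are invariant to the label's
units; the choice is exposed as `standardize_labels` and can be switched
off.

**Inference.** Accuracy is the Pearson correlation between leave-one-out
predictions (assembled in patient order) and the actual labels; if either
vector is constant the correlation is defined as 0 with a warning. The
permutation test shuffles the labels, re-runs the *full* LOOCV, and uses the
one-tailed rule `P = (#{null accuracy ≥ actual} + 1) / (n_perm + 1)`, whose
smallest attainable value is 1/(n_perm+1). The "≥" direction is the standard
one for a test of above-chance accuracy: counting null accuracies *below*
the observed one would assign good models large P values. Note that LOOCV
accuracy under shuffled labels is not centred at zero but slightly below it
(the left-out observation pulls the training mean away from itself); the
permutation null inherits this bias, which is precisely why significance is
assessed against the permutation distribution rather than against zero.

**Feature significance.** Per-feature null weight distributions come from
full-sample refits under the *same* permutation draws used for the model
test (one shared shuffle stream per seed); a feature is significant outside
its own 2.5th–97.5th null percentiles (two-tailed at 0.05). With fewer than
40 permutations those percentiles are under-resolved and a warning is
issued.

**Hub classification.** Significant nodes are classified from the sign
pattern across the three models: integration effect when damage makes the
network more global (negative locE or sigma weight, and/or positive gE
weight), segregation effect for the mirror pattern, `unclassified` when the
significant signs conflict. The function is pure in the flags and signs, so
its behaviour is unit-testable without any fitting.

## 4. The synthetic cohort generator

The generator exists so that every stage of the pipeline can be exercised,
and its planted structure recovered, without patient data. Its defaults
define the reference study conditions: 96 patients, 180 nodes in 4 modules,
6 effector hubs, and the sizes below were chosen once, on the development
seeds, to land the cohort in a realistic regime (LOOCV accuracies in the
0.2–0.9 band, lesion frequency heterogeneity of the kind seen in vascular
cohorts).

* **Healthy base.** A block-structured Fisher-z matrix: within-module mean
  0.5, between-module mean 0.12, SD 0.12 — values in the range typical of
  averaged resting-state connectomes. Effectors receive cross-module weights
  with mean 0.58 ("connector" placement; a "provincial" variant boosts
  within-module weights instead), which makes them genuine connector hubs of
  the thresholded graph (PC far above the median) while leaving modularity
  detectable (leading-eigenvector recovery of the planted blocks with
  adjusted Rand index above 0.9).
* **Lesions.** Nodes get synthetic 3-D coordinates clustered by module;
  blobs grow over the 6-nearest-neighbour adjacency from seed nodes drawn
  with log-normal ("vascular") propensities, boosted ×12 at effectors and
  their neighbours — hub territories are over-exposed, mirroring the strong
  non-uniformity of real lesion frequency maps. Blob sizes are rounded
  normal (mean 10, SD 4, clipped to [3, 30]); one blob per patient, a second
  with probability 0.35. Within a blob, lesion fractions are Beta(2, 2)
  scaled by a core-to-periphery decay (factor 1 at the seed down to 0.5 at
  the rim): damage is deepest at the vascular core, which also concentrates
  identifiable lesion variance on the seed node rather than smearing it
  uniformly across the blob.
* **Forward model.** Edge weights attenuate multiplicatively,
  `w_ij ← w_ij (1−lp_i)^α (1−lp_j)^α` with α = 1, plus symmetric Gaussian
  observation noise (SD 0.03). Multiplicative attenuation keeps the
  lesion-to-connectivity map approximately linear in the lesion fractions,
  matching the linear-SVR working assumption; a fully lesioned node loses
  all its edges.
* **Ground truth.** Expected effect signs are *derived*, not asserted: for
  each effector the three labels are recomputed on the noise-free base with
  that node fully lesioned, and the sign of the change is recorded. This
  keeps the generator from hard-coding any claim about which direction
  connector damage shifts the topology; under the defaults the oracle finds
  connector deletion lowers gE and raises locE and sigma (a segregation
  effect).
* **Null mode.** Lesion patterns are shuffled across patients *after* the
  matrices are generated, which severs the lesion-topology coupling while
  preserving both marginal distributions exactly — the right null for
  calibration studies of the permutation test.

What the generator does **not** emulate: BOLD time series and their noise
structure, distance-dependent connectivity, hemispheric symmetry, lesion
mass effects or diaschisis beyond the multiplicative attenuation, and the
anatomical identity of real modules. Passing tests on synthetic cohorts
therefore demonstrate that the statistical machinery is correct and
calibrated — not that any particular real-data result will replicate.

## 5. Healthy-connectome hub metrics

Modularity uses the leading-eigenvector spectral method plus a
Kernighan–Lin-style refinement (single-node moves accepted while modularity
increases); module labels are canonicalized by descending size with ties
broken by smallest member node id, making partitions invariant to node
input order. `consensus_modules()` runs the detection across sparsities
0.05–0.20 (step 0.01), returns the representative-sparsity (0.15) partition,
and flags nodes whose aligned assignment disagrees with it in more than half
the grid levels — a stability summary rather than a co-classification
consensus matrix, which matches how the robustness check is typically done.

Participation coefficient uses `PC_i = 1 − Σ_s (k_is/k_i)²` with PC = 0 for
isolated nodes; within-module degree is the Guimerà–Amaral z-score with the
*population* (n) standard deviation, and modules of size 1 or zero spread
score 0. Nodal efficiency z-scores are standardized across all nodes of the
network. Hub flags use the conventional thresholds PC > 0.3, WMD > 0,
nodal-gE z > 0. PC and WMD are computed at the representative sparsity (not
averaged over the grid) — the natural reading when a representative
threshold has been fixed.

## 6. Reproducibility and problem sizes

All stochastic stages take explicit seeds. A master seed fans out through a
fixed integer map (`derive_seed`), so stages are decoupled: changing the
number of permutations does not alter the cohort, and every sub-seed stays
below 2^31. Given a config and seed, cohorts are byte-identical; the run
manifest written by `write_report()` echoes the configuration and seeds, so
any CLI run is reproducible from its manifest alone.

The test suite exercises the pipeline at these scales, chosen as the
smallest sizes at which each property is meaningfully tested: exhaustive
5-node graph sweeps for the efficiency oracles; 40-patient / 60-node null
cohorts, 200 repeats at 99 permutations, for permutation-test calibration
(rejection rate at α = 0.05 expected in [0.02, 0.09]); and the full
96-patient / 180-node planted cohort at 199 permutations for effector
recovery. The whole suite runs in a few minutes on one CPU.

## 7. Known limitations

* Binary, undirected networks only; weighted or directed topology, rich-club
  and patient-level modularity are out of scope.
* The SMO solver and libsvm agree to their common stopping tolerance
  (about 1e−2 on weights in poorly conditioned problems), not to machine
  precision; significance calls are insensitive to this because the same
  solver produces both the observed and the null weights.
* Permutation P values are granular (1/(n_perm+1)); with the default 1000
  permutations the floor is ≈ 0.001.
* The sigma label carries Monte-Carlo noise from the finite null ensemble;
  with 100 nulls this is small relative to between-patient variation, but
  comparisons of sigma across pipelines should use a common `n_random` and
  seed policy.
* NIfTI inputs must share grid and affine exactly; the package refuses to
  resample rather than guessing an interpolation.
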