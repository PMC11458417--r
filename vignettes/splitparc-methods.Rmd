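---
title: "Split-half consensus parcellation: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Split-half consensus parcellation: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Functional network parcellations group brain voxels by the similarity of
their resting-state connectivity fingerprints. Most published parcellations
come from cohorts of hundreds to a thousand participants; labs that need a
map specific to their own (often small, often clinical) sample need a method
whose output is *demonstrably stable* at that sample size rather than merely
plausible. `splitparc` implements a split-half consensus estimator: it only
keeps network distinctions that replicate when the cohort is repeatedly
split into two random halves and each half is parcellated independently. The
user is shown, for every candidate graph threshold, how much of the region
is covered by replicating networks and how many networks survive — and makes
the final threshold call themselves.

## The estimator, stage by stage

Let $R$ be the ROI mask (the voxels to parcellate) and $C$ the context mask
(the voxels connectivity is measured against, typically the whole brain),
both at an analysis resolution that may be coarser than the acquired data.

1. **Timeseries extraction** (`extract_timeseries`, `downsample_mask`,
   `downsample_timeseries`). Data and masks are optionally downsampled
   (block mean for data; a target cell is a mask member when at least 50% of
   its in-grid source voxels are members). Rows of every extracted matrix
   follow one canonical voxel order — row-major over $(i,j,k)$ — so matrices
   from different participants align.
2. **Split-half connectivity** (`make_split_plan`,
   `roi_context_correlation`, `group_average`, `similarity_matrix`). For
   each of $n_\text{iter}$ iterations the cohort is split uniformly at
   random into two equal halves. Per participant, the $|R|\times|C|$ Pearson
   correlation matrix is computed over timepoints; within each half these
   are averaged (Fisher-z by default) and the group matrix is squared into
   the $|R|\times|R|$ similarity matrix $S$, $S_{ab} =
   \mathrm{cor}(\mathbf{c}_a, \mathbf{c}_b)$, where $\mathbf{c}_a$ is ROI
   voxel $a$'s connectivity pattern over the context.
3. **Graphs and communities** (`binarize_top`, `detect_communities`). $S$ is
   thresholded at each value $p$ of a grid: the cutoff is the $p$-quantile
   of the off-diagonal upper triangle and an edge joins pairs strictly above
   it, so $p = 0.90$ keeps roughly the top 10% of connections. Each binary
   graph is clustered with two-level InfoMap (the map equation), taking the
   best partition over $n_\text{trials}$ restarts.
4. **Replication and consensus** (`match_prototypes`,
   `accumulate_agreement`, `consensus_prototypes`, `agreement_curve`).
   Communities from the two halves are matched greedily by descending Dice
   $D(X,Y) = 2|X\cap Y|/(|X|+|Y|)$; a pair replicates when $D > 0.5$ and the
   intersection covers at least 2% of the ROI. The intersections are the
   iteration's replicated prototypes. Across iterations the agreement matrix
   $A_{uv}$ records the proportion of iterations in which $u$ and $v$ shared
   a replicated prototype (a pair present in 8 of 10 iterations scores 0.8).
   Binarizing $A$ at 50% and taking connected components (minus components
   under the 2% floor) yields the consensus prototypes; coverage and
   prototype count per threshold form the agreement curves shown to the
   user.
5. **Winner-take-all labeling** (`fullres_patterns`, `prototype_patterns`,
   `assign_labels`). Each prototype's member rows of the all-cohort group
   connectivity matrix are averaged into a template pattern; prototypes from
   all ROI masks are pooled. Every brain voxel at the *original* resolution
   gets its group-average fingerprint against the (downsampled) context, and
   receives the label of the prototype with the largest squared Pearson
   correlation $R^2$ — but only if that $R^2 > 0.5$, i.e. the winner
   explains more than half the variance in the voxel's fingerprint.
   Prototypes may claim voxels anywhere, including outside their source
   mask.
6. **Volume rendering** (`fill_unlabeled`, `write_parcellation`). Remaining
   unlabeled in-brain voxels take the label of the nearest labeled voxel in
   physical mm (majority, then lowest label, among equidistant candidates).
   This step is intended for small gaps; fills beyond a configurable radius
   raise a warning because large unlabeled regions signal unstable
   connectivity, not missing data.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| `n_iterations` | 10 | random split-halves; a good stability/computation trade-off |
| `n_trials` | 100 | InfoMap restarts per graph |
| `thresholds` | 0.80–0.95 by 0.03 | graph density grid (proportion of pairs removed) |
| `dice_min` | 0.5 | cross-half Dice floor for replication |
| `min_intersection_frac` | 0.02 | prototype volume floor, as a fraction of the ROI mask size |
| `consensus_min` | 0.5 | minimum proportion of iterations for co-membership |
| `r2_min` | 0.5 | variance-explained floor for a final label |
| `average` | `fisher_z` | correlation averaging across participants |
| `seed` | — | master seed; split plans and every InfoMap search derive from it |

Threshold selection is deliberately manual: the non-interactive pipeline
requires explicit per-mask thresholds, and the interactive mode pauses at
the agreement curves. No automatic selection rule is provided, because the
stable point depends on the dataset (sample size, tSNR) and inspecting the
curves — ideally together with the prototypes rendered by
`prototypes_to_volume` — is part of the method.

## Design decisions in ambiguous corners

* **Pattern spaces in labeling.** Prototype templates live over the
  downsampled context; voxel fingerprints at the original resolution are
  therefore also computed against the *downsampled* context so the two
  vectors are comparable. The alternative (upsampling prototype patterns to
  a full-resolution context) differs slightly; the choice is recorded in the
  run metadata (`pattern_space`).
* **Sign of the winner.** The label goes to the prototype explaining the
  most variance, which lets a strongly *negative* correlation win.
  `sign_restricted = TRUE` additionally requires $r > 0$, since
  negative-winner labels are physiologically questionable; the literal
  $R^2$ rule is the default.
* **Replicated set = intersection.** A replicating cross-half pair
  contributes $X \cap Y$ (conservative); the union is available via
  `use_union = TRUE` in `match_prototypes`.
* **Matching multiplicity.** Greedy one-to-one matching in descending Dice
  order prevents one large community from absorbing several partners; ties
  break on community ids, keeping runs deterministic.
* **Averaging.** Fisher-z is the statistically conventional way to average
  correlations and is the default; the raw mean is available. Perfect
  correlations are clipped at $|r| = 1 - 10^{-7}$ before `atanh`, so a
  noiseless fingerprint caps at $1-10^{-7}$ rather than overflowing.
* **Undefined voxels.** Zero-variance voxels make Pearson correlation
  undefined. They are removed from the ROI/context before graph
  construction and reported in the fit (`dropped`), never silently zeroed.
  Voxels whose fingerprints are undefined at labeling time stay unlabeled.
* **Quantile and ties in `binarize_top`.** Linear-interpolation (type-7)
  quantile; edges require *strictly* exceeding the cutoff, so ties at the
  cutoff drop together. With an all-tied matrix the graph is empty and a
  warning is raised. The extreme case matters in the noiseless limit: with
  zero voxel noise, within-network similarities are exact ties at 1, so a
  threshold whose quantile lands inside that tie block would drop the whole
  block. The test suite therefore places the threshold in the quantile
  gap just below the tie block when exercising that limit.
* **Downsampling rules.** The mask rule (50% occupancy, configurable) and
  the data rule (block mean) are the package's choices; the upstream
  tooling this emulates does not pin down its resampling interpolant.
* **Distances in mm.** Nearest-neighbour filling measures Euclidean
  distance through the grid affine, so anisotropic voxels are handled
  correctly; the majority-then-lowest-label tie rule makes filling
  deterministic and idempotent.
* **Map-equation engine and codelength.** Partitions come from
  `igraph::cluster_infomap` (best of `n_trials` internal restarts, seeded
  from R's RNG). The codelength reported on a partition is recomputed with
  the package's own evaluator (`map_equation_codelength`): the standard
  two-level map equation for undirected, unweighted graphs with
  degree-proportional visit rates, no teleportation, in bits. igraph's
  internal objective (an older teleportation variant) can differ
  numerically; the partition is igraph's, the reported number is ours, and
  the test suite checks the winning partition against exhaustive
  enumeration on small graphs using an independently written evaluator.
* **Isolated nodes** become singleton communities; singletons never survive
  the volume floor in realistic ROI sizes, and components of size one are
  never reported as prototypes.

## The synthetic data generator

`synth_config()` / `synth_generate()` plant $K$ networks in a 3D grid: each
network owns a strip of the ROI slab plus a context-only block, and every
network voxel mixes the network's latent unit-variance Gaussian series with
i.i.d. voxel noise,
$$x_v(t) = a\,L_{k(v)}(t) + \sigma\,\varepsilon_v(t) + \text{baseline},$$
so two voxels of one network correlate at $a^2/(a^2+\sigma^2)$ in
expectation and voxels of different networks are uncorrelated. Background
brain voxels are pure noise; optional "vessel" voxels get noise with a much
larger SD to emulate prominent blood-vessel signal (they exercise both the
high-SD exclusion utility and the $R^2$ labeling gate). The defaults are the
desk-scale study conditions used throughout the tests: a
$24\times24\times12$ grid of nominal 6 mm voxels, a 600-voxel ROI slab
inside a ~5,300-voxel in-brain context, $K = 5$, 20 participants, 140
timepoints, and $a = \sigma = 1$ for a within-network $r \approx 0.5$. The
two-level variant (`synth_config_twolevel`) adds a shared parent signal per
group of sub-networks; its default is deliberately compact (an
$18\times18\times12$ grid, 240-voxel ROI, 2 parents × 3 sub-networks),
because the focused-parcellation mode re-runs the entire pipeline once per
parent parcel.

What the generator does *not* emulate: hemodynamic smoothing and temporal
autocorrelation, motion and physiological artifacts, spatial noise
correlations, inter-individual topography differences. Passing the planted
recovery tests therefore demonstrates that the estimator's machinery is
correct and stable under its own assumptions — not that any particular real
dataset will yield a stable parcellation, which is exactly what the
agreement curves are for.

## Problem sizes in the test suite

The suite validates at two scales, chosen as the package's own desk-scale
study conditions: the full default generator (600-voxel ROI, ~5,300-voxel
context, 20 participants, 140 timepoints, six thresholds, 10 iterations,
100 InfoMap trials) for end-to-end recovery and the sample-size comparison,
and a miniature 3-network configuration (90-voxel ROI in a
$14\times14\times12$ grid, 8 participants, 60 timepoints) for unit-level
pipeline behaviour, the noiseless consensus limit and determinism checks.

## Focused (recursive) parcellation

`run_focused()` builds a new ROI mask from one parcel of a previous
parcellation and re-runs the whole pipeline, optionally excluding the
parcel's own voxels from the context (useful for small regions whose
internal correlations would otherwise dominate the fingerprints). Context
exclusion is restricted to single-ROI runs: with several ROI masks each
excluding its own voxels, the pooled winner-take-all templates would live
over different context sets and would not be comparable.

## Determinism and provenance

All randomness — the split plan, every InfoMap search, and synthetic data
generation — derives from a single integer seed, so identical configurations
reproduce agreement curves and final volumes bit-identically. Runs persist
their thresholds, criteria, seeds and the labeling pattern-space decision in
a JSON metadata sidecar next to the output volume.

## Known limitations

* Assignment is purely per-voxel: no spatial regularization or smoothing of
  labels, by design.
* The nearest-neighbour fill guarantees full coverage but is only sensible
  for small gaps; wide fills are flagged, not prevented.
* Similarity uses full pairwise Pearson matrices in memory; ROI masks beyond
  a few thousand analysis-resolution voxels should be downsampled first.
* The consensus step extracts connected components, so chains of pairwise
  agreement can bridge blocks that no single iteration produced; with the
  default 50% consensus this requires consistent co-replication and has not
  been a practical concern at the tested scales.
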