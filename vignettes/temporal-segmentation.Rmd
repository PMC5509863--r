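---
title: "Temporal segmentation of robot-assisted surgery procedures with surgseg"
author: "surgseg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal segmentation of robot-assisted surgery procedures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surgseg)
```

## The problem

A robot-assisted surgery (RAS) training procedure is a long multivariate time
series: the surgical system continuously records surgeon-side-console
kinematics (SSC), patient-side instrument and camera kinematics (SI) and a
handful of binary system events (EVT — camera control, master clutches,
instrument following, energy activation, head in/out), all synchronized at
50 Hz. Clinically, such a procedure decomposes into a sequence of tasks
(suturing, dissection, clipping, ...), and task-level rather than
whole-procedure metrics are what surgeons need for directed feedback. surgseg
segments a procedure into `K` such tasks **without supervision**, using only
these lightweight system streams — no video.

Four temporal clustering algorithms are provided and compared:

* **ACA** (aligned cluster analysis): kernel k-means over temporal *segments*
  rather than frames, with a dynamic-programming search over segment
  boundaries;
* **HACA**: ACA run twice, at a fine and then a coarse temporal scale;
* **SC**: spectral clustering of frames on a Gaussian similarity graph;
* **GMM**: a Gaussian mixture over frames, cut wherever consecutive frames
  change component.

Because the study dataset behind this design (nine surgeons on a porcine
model) is proprietary, the package ships a synthetic pseudo-procedure
generator with the same statistical skeleton, so that every stage of the
pipeline is testable end to end from a fresh install.

## The model

### Frame kernel

All clustering operates on a per-frame feature matrix
$X \in \mathbb{R}^{d \times N}$ and its Gaussian **frame kernel**

$$f_{ij} = \exp\!\left(-\frac{\lVert t_i - t_j\rVert^2}{2\sigma^2}\right),$$

which doubles as the spectral-clustering similarity graph. When frames within
a task are mutually similar and frames across tasks are not, `F` is close to
block-diagonal, and the segmentation problem becomes finding that block
structure. The bandwidth $\sigma$ is never dictated by the data model;
`frameKernel()` defaults to the median heuristic (median pairwise distance
over a seeded subsample of at most 2000 frames, zeros excluded), which is
scale-free and stable across feature sets. An explicit $\sigma$ can always be
given.

### Segment kernel (DTAK)

Segments of different lengths are compared with the dynamic time alignment
kernel. For segments $Q_a, Q_b$ of lengths $n_a, n_b$, a DP table over the
restriction of `F` to the two segments,

$$u(p,q) = \max\bigl(u(p-1,q) + f_{pq},\; u(p-1,q-1) + 2f_{pq},\;
u(p,q-1) + f_{pq}\bigr), \qquad u(0,0) = 2 f_{00},$$

gives $\tau(Q_a,Q_b) = u(n_a-1, n_b-1)/(n_a+n_b)$. The $(1,2,1)$ step weights
and the $1/(n_a+n_b)$ normalization make $\tau$ symmetric, bounded by 1, and
exactly 1 for a segment against itself under a unit-diagonal kernel; the
normalized correspondence weighting is absorbed into this normalization
rather than materialized as a separate matrix. The DP is implemented in
C++ (`src/`) because it sits in the innermost loop of the boundary search.

### ACA objective and optimization

A segmentation is a boundary vector $s$ (0-based, half-open) and per-segment
labels $g$. The objective is the within-cluster scatter in the implicit DTAK
feature space,

$$J = \sum_{k=1}^{K}\sum_{m=1}^{M} g_{k,m}\, D^2(Q_m, z_k), \qquad
D^2(Q_m,z_k) = \tau_{mm} - \frac{2}{M_k}\sum_j g_{kj}\tau_{mj}
+ \frac{1}{M_k^2}\sum_{j_1 j_2} g_{kj_1}g_{kj_2}\tau_{j_1 j_2},$$

with $z_k$ the geometric centroid of cluster $k$ and $M_k$ its segment count.
The equivalent trace form
$J = \mathrm{tr}\bigl((I - G^{\top}(GG^{\top})^{-1}G)\,\tau\bigr)$ is used as
an independent oracle in the test suite, never as the implementation.

`aca()` minimizes $J$ by coordinate descent:

1. **Initialize** with random boundaries (lengths uniform over the feasible
   subset of $[l_{\min}, l_{\max}]$) and random labels.
2. **Assignment**: every segment moves to its nearest centroid; an emptied
   cluster is re-seeded with the segment farthest from its own centroid
   (never emptying another cluster in the process). The data model is silent
   on empty clusters; this is the package's choice.
3. **Boundary search**: a DP over the end frame,
   $V(v) = \min_{l,k} V(v-l) + D^2([v-l,v), z_k)$ with
   $l \in [l_{\min}, l_{\max}]$, re-cuts the whole series against the current
   centroids. All candidate-segment DTAK values are computed incrementally in
   C++ (one DP table per (candidate start, existing segment) pair, read out
   at every candidate length), which keeps an iteration at roughly
   $O(N\, l_{\max} \bar{n} M)$.
4. Stop when $J$ decreases by less than `tol` (default `1e-7`) or after
   `maxIter` iterations.

Each step can only lower $J$ (assignment by the kernel k-means argument,
boundaries because the previous segmentation is a feasible DP solution), so
the per-iteration trace is non-increasing — asserted to $10^{-9}$ in the
tests. DP ties prefer the longer segment, then the smaller cluster index,
fixed for determinism. The whole procedure runs `nInit = 5` seeded restarts
and keeps the minimum-energy solution, the study's protocol.

### HACA

`haca()` runs ACA twice. Level 1 uses a finer motif vocabulary
(`level1_K = 2K` by default; the finer motifs are regrouped at level 2) and
shorter segments (`l_max_1 = 20` frames). Level 2 builds the reduced kernel
$F^{(2)}[a,b] = \tau(Q_a, Q_b)$ over the $M_1$ level-1 segments — a valid
unit-diagonal kernel — and re-runs ACA on it, merging whole level-1 segments.

Both length bounds are in **frames** (`l_max_1 = 20 < l_max_2 = 30`): the
level-2 DP carries each level-1 segment's frame span and caps the total span
of a merged segment at `l_max_2`. The alternative reading — `l_max_2` counted
in level-1 segments — degenerates at moderate `N`: with ~100 level-1
segments, 30-unit segments let the DP tile the series with exactly `K`
singleton-cluster segments, which makes $J \equiv 0$ with arbitrary
boundaries. The frame reading keeps the constraint meaningful at every scale
and preserves the intended ordering of the two bounds.

The restart energy for HACA is the level-2 objective: recomputing the
frame-level $J$ of the expanded segmentation would require DTAK between
segments hundreds of frames long, which is exactly the cost the hierarchy
exists to avoid.

### SC and GMM baselines

`spectralSegment()` embeds frames in the `K` leading eigenvectors of
$D^{-1/2} F D^{-1/2}$ (the smallest eigenvalues of the symmetric normalized
Laplacian), row-normalizes, and runs seeded k-means with 10 restarts.
`gmmSegment()` fits a `K`-component diagonal-covariance mixture by EM with
seeded k-means initialization and a variance floor of $10^{-6}$ (full
covariances on ~32-dimensional centroid features with a few hundred frames
are singular-prone), cutting the series wherever consecutive MAP labels
differ. Both are frame-marginal methods: temporal structure enters only
through run-length encoding of the labels, which is why they fragment where
the aligned methods do not.

## Preprocessing

The pipeline (`segmentTrial()` wires it together):

1. **Temporal reduction** to 1 Hz by default: kinematics are window-averaged,
   events take the window-wise maximum (one activation anywhere in the window
   survives — an event's information is its occurrence, not its duty cycle).
   Ground-truth labels are reduced by per-window majority vote, ties toward
   the earlier task. The working rate is a package decision: segment-length
   bounds of ~30 frames against tasks lasting many minutes imply a frame unit
   of roughly a second, and an $N \times N$ kernel at 50 Hz over a two-hour
   procedure would be infeasible anyway ($N^2 \approx 10^{11}$). At 1 Hz a
   full pseudo-procedure gives $N \approx 7600$ and tasks span hundreds of
   frames.
2. **Z-scoring** per channel (population sd; constant channels map to zeros)
   makes the Euclidean geometry of k-means and the Gaussian kernel
   scale-free across heterogeneous channels (metres, radians, unit poses).
3. **Symbolization**: per-trial k-means (10 seeded restarts, best inertia)
   quantizes the kinematic frames into `n_symbols = 15` symbols; each frame
   is then **re-embedded as its centroid vector** rather than a one-hot
   code, so the kernel retains graded between-symbol similarity and the
   kernel image shows soft blocks rather than a binary mosaic. Fewer symbols
   give visibly blockier kernels; 15 was the best-performing codebook size in
   the study's search grid (10–200). No codebook is shared across trials.
4. **Events are appended raw** (8 binary channels, never symbolized), and
   `EVT` alone is not a valid feature set; the six valid sets are the
   combinations of SSC/SI with optional EVT.

## The synthetic generator

`generateTrial()` emulates the study conditions, not the surgical system:

* five tasks in a fixed order form one pseudo-procedure;
* task durations are Normal with the study's per-task means and standard
  deviations (e.g. task 1: 1329.2 ± 733.9 s), truncated below at
  `max(5/rate, 1)` s so every task remains segmentable; `timeScale` shrinks
  all durations proportionally for desk-scale runs;
* kinematics follow per-channel AR(1) dynamics pulled toward a task-specific
  emission mean, with the latent state carried across task boundaries (smooth
  transitions, transient of a few frames). The default smoothness is 0.5: at
  that value the stationary spread is 1.15 noise units, so the default
  emission separation of 6 noise units leaves a 5-class Bayes frame accuracy
  above 0.95 — the "easy" regime the recovery tests rely on is verifiably
  easy;
* each event channel fires as an independent Bernoulli per frame with a
  task-specific per-second rate (a dominant and a secondary channel per
  task), so EVT alone carries task identity;
* everything is bit-reproducible from `(config, profiles, seed)`.

Synthetic kinematic dimensionality defaults to 12 (SSC) + 24 (SI) rather than
the real 56 + 156: algorithm behaviour depends on the kernel's block
structure, not on raw dimensionality, and the real dimensions remain
available through `GeneratorConfig`. The generator emits no inter-task gap
frames. `overlapDynamicsProfiles()` provides a deliberately harder regime
(emission separation 1.5, task-specific AR coefficients 0.3–0.95) in which
tasks are distinguished by dynamics more than by marginal position — the
regime where frame-marginal GMM falls measurably behind HACA.

What passing tests on this generator do **not** show: robustness to
non-stationary drift within a task, to shared low-dimensional structure
across streams, to label noise in human ground truth, or to tasks performed
out of order — none of which the generator emulates.

## Evaluation

`confusionMatrix()` cross-tabulates frames by the indicator product
$C = G_\mathrm{out} H_\mathrm{out} H_\mathrm{true}^{\top}
G_\mathrm{true}^{\top}$;
`clusterAccuracy()` maximizes $\mathrm{tr}(CP)$ over permutations $P$ with a
hand-written $O(K^3)$ Hungarian solver (no installed package provides
weighted bipartite assignment; the test suite checks it against exhaustive
permutation enumeration). Equal-trace ties leave the accuracy unchanged even
when the permutation is not unique. `perTaskMetrics()` reports per-task
precision/recall/F1 under the accuracy-optimal matching; per-task
"performance" tables report **recall** and are labeled as such. A task with
no true frames yields `NA` and is excluded from the macro average.
`proportionalBaseline()` predicts boundaries from mean normalized task
durations alone (leave-one-out by default in the experiment harness) — the
sanity floor any temporal model must beat.

## Worked example

```{r example, eval = FALSE}
cfg <- GeneratorConfig(timeScale = 0.13)          # ~1000 frames at 1 Hz
trial <- generateTrial(cfg, defaultTaskProfiles(cfg), seed = 1)
rec <- downsampleRecording(trial$recording, 1)
truth <- downsampleSegmentation(trial$truth, 50, 1)

X <- buildFeatures(rec, "SI+EVT", n_symbols = 15, seed = 1)
Fk <- frameKernel(X)
seg <- haca(Fk, ACAConfig(K = 5, nInit = 5), seed = 1)
evaluateSegmentation(seg, truth)$accuracy

plotSegmentations(list(GT = truth, HACA = seg))
```

The experiment harness sweeps algorithms and feature sets over many trials
(`runExperiment()`), derives per-run seeds by a stable hash so the sweep is
extensible without perturbing existing runs, and formats the aggregate as the
usual algorithm-by-feature-set grid (`reportResults()`).

## Numerical choices and limitations

* Problem sizes in the shipped tests and the acceptance script: 10 trials of
  ~1000 frames at 1 Hz for end-to-end recovery, 300-frame kernels for
  convergence checks, and 200 sampled duration vectors for generator
  fidelity — chosen as the smallest sizes at which the properties are
  statistically meaningful.
* `l_min = 3` frames (no minimum is inherent to the model; 3 prevents
  single-frame slivers), `l_max = 30` for plain ACA, 20/30 for the HACA
  levels.
* The objective tolerance is `1e-7`; the monotonicity assertion allows
  `1e-9` of floating-point slack.
* Kernel entries are floored at `1e-300` to keep them strictly positive
  under exp underflow.
* Degenerate inputs: all-identical frames make the median bandwidth
  undefined (explicit error asking for a σ); `N < K l_min` and infeasible
  tilings are rejected up front; an empty cluster raises a typed condition
  (`emptyClusterError`) in the low-level distance API.
* ACA/HACA cost grows linearly in `N` per iteration but with a large
  constant; at 50 Hz (untypical) the kernel itself is the bottleneck.
  Everything here is off-line by design; there is no streaming variant, and
  no significance testing across algorithms is included.
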