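---
title: "Membrane boundary detection and gap amendment: models and methods"
author: "neuroseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane boundary detection and gap amendment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroseg)
```

## The problem

Serial-section transmission electron microscopy (ssTEM) of nervous tissue
produces low-contrast grayscale images in which the objects of interest —
neurite cross-sections — are delimited by thin dark membranes. Tracing
those membranes is the bottleneck of connectomic reconstruction: the
images are noisy, organelles (mitochondria, endosomes) clutter the cell
interiors with equally dark structures, and classical edge operators leave
the membrane network riddled with gaps. A gap is far more damaging than a
displaced boundary, because it merges two cells into one region and
corrupts every downstream topology-dependent measurement.

`neuroseg` implements a three-stage answer:

1. **Detection** — Laplacian-of-Gaussian (LoG) zero-crossing boundary
   extraction at every level of a Gaussian image pyramid, fused by a
   weighted per-pixel vote (`detectBoundaries()`).
2. **Amendment** — closing of gaps in the detected boundary curves by a
   SARSA(λ) agent that walks the pixel grid from an open curve endpoint,
   supervised by a local polynomial model of the curve fitted by
   per-sample gradient descent (`amendBoundaries()`).
3. **Evaluation** — pixel error, Rand error and topology-aware warping
   error, with macro averaging over image sets (`evaluateBoundary()`).

A synthetic phantom generator (`generatePhantom()`, `injectGaps()`)
provides EM-like images with exact ground truth, so the whole stack is
testable without any external dataset.

Throughout the package, rasters are base R matrices indexed `[row, col]`,
1-based, origin top-left; binary boundary maps use 1 for a *marked*
(boundary) pixel and 0 for a *blank* one.

## Multi-scale fused boundary detection

At a small scale LoG localises boundaries precisely but responds to every
noise grain; at a large scale it is stable but imprecise. The detector
therefore builds an `l`-level Gaussian pyramid (5×5 binomial kernel
`(1,4,6,4,1)/16`, decimation by 2), applies LoG at each level, and lets
the levels vote.

For a pixel \((x,y)\), with per-level boundary verdicts \(b_i \in
\{0,1\}\),

\[
\mathrm{account}(x,y) \;=\; \sum_{i=1}^{l}
  \begin{cases} \alpha\, w_i & b_i = 1\\ \beta & b_i = 0 \end{cases},
\qquad
\text{mark} \iff \mathrm{account} \ge \text{threshold}.
\]

Defaults: \(\alpha = 1\), \(\beta = 0\), threshold \(= 0.5\alpha\), and
weights proportional to each level's linear resolution (finer levels
higher), normalised to sum 1 — fine scales carry the positional accuracy,
coarse scales corroborate. The comparison is `>=`: a pixel is marked
exactly when its account is *not below* the threshold.

Per level, the LoG response is a Gaussian blur at `sigma` (default 1 px at
every level — scale is carried by the decimation, not by growing kernels)
followed by the 4-neighbour Laplacian. A pixel is marked when its response
changes sign against a 4-neighbour and the response difference across the
crossing exceeds `gradThresh` (default 0); of the two pixels straddling
the crossing, the one with the smaller absolute response is marked, since
it lies closer to the true zero and hence to the boundary centre. All
convolutions use reflect padding, and the outermost 1-px frame is never
marked, which keeps padding artefacts out of the maps.

Coarse-level maps are block-upsampled to base resolution and dilated once
with a 3×3 element before voting: adjacent scales localise the same
boundary within about one pixel of each other, and the dilation absorbs
that drift. Level 1 needs no dilation. The pipeline contains no
randomness; identical inputs give bit-identical outputs.

## Local curve models by per-sample gradient descent

When a gap is to be closed, the curve arm adjacent to the open endpoint is
traced backwards along marked 8-neighbours (`traceCurveSegment()`), up to
15 pixels, dropping the 2 pixels nearest the break — right at a break the
detection is least trustworthy. The trace stops early at a branch point
rather than guessing which way the curve continues. A polynomial

\[ y \;=\; \theta_0 + \theta_1 x + \theta_2 x^2 \]

is then fitted to the traced points with the per-sample update

\[ \theta \leftarrow \theta + \alpha_{lr}\,(y - G\theta)\,G,
   \qquad G = (1, x, x^2), \quad \alpha_{lr} = 0.1 , \]

sweeping the points in traced order (far → near). A batch variant
accumulates 5 residual gradients and applies their mean.

Three numerical decisions matter here:

* **Orientation.** The model assumes \(y = F(x)\), which a near-vertical
  segment violates. Axes are exchanged when the second coordinate carries
  more *distinct values* than the first; ties (45° segments) keep the
  original orientation. Orienting by coordinate extents instead would
  mis-handle data whose ordinate range merely exceeds its abscissa range
  (any steep parabola), turning a function-like sample into a two-branched
  one.
* **Conditioning.** The abscissa is internally rescaled to \([-1, 1]\).
  On \([0,1]\) the moment matrix of the quadratic basis is
  Hilbert-matrix-like and the per-sample iteration needs thousands of
  sweeps; centring the interval makes odd and even basis functions nearly
  orthogonal and convergence roughly 20× faster. Coefficients are mapped
  back by polynomial composition, so the returned model lives in pixel
  coordinates.
* **Termination.** Sweeps repeat until the largest coefficient change
  over a full sweep falls below `thetaTol = 0.001`. With the fixed
  learning rate 0.1 this takes on the order of 50 sweeps for a clean
  quadratic; the `episodes` slot (default 500) is a hard safety cap, not
  the intended stopping rule. Terminating after a fixed small number of
  sweeps would leave the coefficients far from the least-squares solution
  and the walker's supervision useless.

The fit cost of a pixel is its vertical distance \(|y - F(x)|\) in the
oriented frame: it is zero exactly on the curve, and its gradient is
linear in \(\theta\), which is what makes the per-sample update above
exact. Euclidean point-to-curve distance is available for inspection but
is not the default. On noiseless polynomial data of matching degree the
fit converges to the normal-equations solution (the test suite asserts
agreement within \(10^{-2}\) coefficient-wise); on noisy data its total
cost stays within 10% of the least-squares fit's.

## SARSA(λ) curve traveling

Gap closing is framed as an episodic control problem on the pixel grid.
The state is the walker's pixel; the actions are the 8 unit moves; the
tabular action value \(Q(s,a)\) and eligibility trace \(e(s,a)\) start at
zero and update after every step with the standard on-policy rule

\[
\delta_t = r_{t+1} + \gamma\,Q(s_{t+1},a_{t+1}) - Q(s_t,a_t), \qquad
e(s_t,a_t) \mathrel{+}= 1,
\]
\[
Q \mathrel{+}= \alpha\,\delta_t\,e \quad\text{(all stored pairs)}, \qquad
e \mathrel{*}= \gamma\lambda ,
\]

with step size \(\alpha = 0.1\), discount \(\gamma = 0.95\), and trace
decay \(\lambda = 0.9\) (an ordinary "most of the credit flows backwards"
value; with \(\lambda = 0\) the implementation reduces exactly to
one-step SARSA, which the tests verify against an independent reference).

The reward of a step onto pixel \(p\) is

\[
r \;=\; \begin{cases} +\,\mathrm{gain} & p \text{ marked} \\
        -\,\mathrm{gapPenalty} & p \text{ blank} \end{cases}
\;-\; w_m \cdot d_{\mathrm{model}}(p),
\]

with gain 1, gap penalty 10 and model weight \(w_m = 1\): staying on
detected boundary is good, walking through blank space is expensive, and
in both cases straying from the fitted curve model costs extra. This
reward shaping is how the curve model "supervises" the walk.

Decisions the formulation leaves open, and how the package takes them:

* **Exploration.** ε-greedy with ε = 0.1, decayed ×0.95 per episode.
  With the default single episode per gap, Q is all-zero when the walk
  starts, so greedy-over-Q alone cannot express the supervision; ties
  among maximal-Q moves therefore break toward (1) a marked, gap-closing
  target pixel, then (2) the smallest model distance, then (3) a fixed
  move order. When no model could be fitted (arm too short), the
  tie-break distance falls back to the straight-line distance to the
  nearest marked pixel outside the walker's own arm — the cheapest
  connection target.
* **Own arm vs. other arm.** The episode succeeds when the walker reaches
  a marked pixel *outside its own arm*, defined as the marked pixels
  within geodesic distance 15 (the trace neighbourhood) of the start
  along the curve. Connected-component identity cannot serve here: a
  single gap in a closed ring leaves both endpoints in one component.
  The walker never steps onto its own arm — walking backwards along the
  curve cannot close a gap.
* **Failure modes.** Returning to the start, the chosen Q falling below
  `qThreshold` (default −100, roughly ten consecutive blank steps), the
  step cap `maximalStep` (default 40 × `maxGapLen` = 600), or running out
  of unvisited pixels all end the episode without committing anything.
  Pixels may not be revisited within an episode, which rules out loops.
* **Commit rule.** Only the blank pixels of the final successful
  trajectory are marked in the output; failed exploration never scribbles
  on the map.

`amendBoundaries()` drives the walker over all endpoints in raster order.
An endpoint is an interior marked pixel with exactly one marked
8-neighbour; isolated pixels are not endpoints, and pixels on the 1-px
image frame are excluded — a curve clipped by the canvas is not a gap.
The gap length is estimated as the straight-line distance to the nearest
marked pixel outside the endpoint's arm; gaps longer than `maxGapLen`
(default 15 px, matching the trace neighbourhood) are skipped, and
endpoints consumed by an earlier closure are not revisited. Amendment
never deletes a marked pixel and, for a fixed seed, is fully
deterministic.

## Evaluation metrics

*Precision / recall / F.* Computed from pixel-wise confusion counts. A
zero denominator yields 0 with a warning rather than NaN, so macro
averages over image sets remain defined.

*Pixel error.* \(1 - \max_t F(t)\): for a graded prediction the F-score
is maximised over thresholds drawn from the distinct predicted values
plus \{0, 1\} (binarising at `pred >= t`); for a binary prediction it is
exactly \(1 - F\) of that single binarisation.

*Rand index / error.* A boundary map induces a segmentation by
4-connected labelling of its non-boundary pixels
(`regionsFromBoundary()`); boundary pixels get label 0 and are excluded
from pair counting. The 4-connected flood cannot cross an 8-connected
curve, so closed curves separate regions. The Rand index is the fraction
of pixel pairs on which two labelings agree, computed from the label
contingency table; tests verify it against exhaustive \(O(n^2)\) pair
enumeration.

*Warping error.* The Hamming distance between the candidate and the best
*topology-preserving* deformation of the reference onto it, normalised by
the pixel count. Deformation steps are single-pixel flips of *simple
points* in the standard 2-D digital-topology sense (foreground
8-connectivity, background 4-connectivity, out-of-canvas pixels
background), so no flip can ever split or merge a foreground or
background component — displacements are forgiven, splits, merges and
holes are not. Simplicity is decided by a 256-entry neighbourhood lookup
table derived from the two topological numbers; the tests confirm every
entry against brute-force component counting. The search is a greedy
descent — repeatedly flip any mismatched simple point — attempted under a
fixed family of six deterministic scan orders (forward/reverse raster ×
plain/additions-first/deletions-first) keeping the best result, because a
single scan order can wedge the warp into a configuration where every
remaining mismatch is non-simple. No geometric restriction is placed on
how far the reference may deform. The warping itself is exercised in the
tests on 32×32 rasters, where the full flip sequences are re-verified
with an independent component counter.

*Macro metrics.* Unweighted arithmetic means of the per-image values.

## The phantom generator

`generatePhantom()` emulates the geometry that matters to this pipeline,
not EM appearance:

* **Cells**: a Voronoi partition from seed points rejection-sampled to a
  minimum separation of \(0.5\sqrt{HW/n}\), giving cells of comparable
  size, as in nervous tissue cross-sections. Default 12 cells on a
  256×256 canvas.
* **Membranes**: a Gaussian absorption profile over the Euclidean
  distance to the 1-px Voronoi edge set, with σ = `membraneWidth`/4 so
  that `membraneWidth` (default 3 px) is the full visible width; the
  intensity drop is `membraneDarkness` (default 0.6) below a 0.85
  background. A stained membrane's cross-profile is smooth, not a box,
  and a constant-width rendering keeps the centerline skeleton honest
  everywhere, including near the canvas border (the fields are computed
  on an internally padded canvas so membranes meet the border cleanly).
* **Ground truth**: the 1-px, 8-connected skeleton of the membrane band,
  obtained by morphological thinning, with short dead-end spurs (thinning
  artefacts at junctions) pruned — spurs never separate regions.
* **Clutter**: dark elliptical blobs (axes 1.5-3.5 px) strictly inside
  cells, default 0.5 per 1000 px² — the organelle-like distractors that
  make EM segmentation hard.
* **Noise**: additive Gaussian, default σ = 0.1, clipped to \([0,1]\),
  after a slight optical blur (σ = 0.5 px).

Everything is determined by the seed. `injectGaps()` removes disjoint
runs of interior degree-2 curve pixels (default 8 runs of 3-10 px, at
least 5 px apart), accepting a removal only if it creates exactly two new
endpoints, and returns exact records of what was removed.

What the phantoms do **not** model: EM texture inside organelles,
staining gradients, section artefacts, membrane junction triple-point
geometry beyond what Voronoi edges produce, or 3-D continuity across
sections. Tests passing on phantoms therefore demonstrate the
correctness and the geometric behaviour of the algorithms — localisation,
topology handling, gap closure — not photometric robustness on real
ssTEM data. The `evaluate` CLI harness can regenerate per-image/macro
reports for users who have such data.

## Problem sizes and study conditions

The test suite and the acceptance script use desk-scale studies chosen to
exercise every code path on one CPU: 50 phantoms of 256×256 px with 12
cells, noise σ = 0.1 and 8 injected gaps of 3-10 px for the amendment
study; 10 noiseless 2-cell phantoms (128×128) for detection recall;
32×32 smoothed-blob rasters for the warping-error topology checks; and
13-point quadratics for the fit-recovery oracle. The amendment study's
acceptance thresholds (at least 80% of gaps closed, Rand error reduced on
at least 90% of phantoms) are properties of the method under these
conditions, verified end to end at run time.

## Known limitations

* The walker optimises each gap independently with a freshly reset Q;
  nothing is learned across gaps or images (by design — transfer is out
  of scope).
* Gap-length estimation is straight-line; a gap that is short as the
  crow flies but long along the curve is attempted anyway.
* The warping-error search is greedy; it bounds the true minimal warping
  error from above. The multi-order family removes the order traps seen
  in practice, but optimality is not guaranteed.
* Detection emits the two LoG flanks of a thick dark band as parallel
  lines; on phantom-scale membranes (≈3 px) the marked line sits within
  1 px of the centerline, but for much thicker bands a ridge detector
  would centre better.
* 2-D only.
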