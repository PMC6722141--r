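---
title: "Groupwise registration by hierarchical graph shrinkage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Groupwise registration by hierarchical graph shrinkage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Groupwise registration warps a population of linearly pre-aligned scalar
volumes $I_1,\dots,I_N$ to a common, unbiased *group center* — no single
subject is privileged as the template. `hgshrink` treats the images as
points on a manifold where proximity is measured by the sum of squared
intensity differences (SSD), and registration as the *shrinkage* of a
vertex-labeled graph living on that manifold:

1. **Hierarchical clustering.** Affinity propagation (AP) on the similarity
   matrix $s(i,j) = -\mathrm{SSD}(I_i, I_j)$, with all preferences set to
   the median off-diagonal similarity, partitions the population into
   clusters of anatomically similar images; clusters larger than
   `max_cluster_size` are re-clustered recursively. AP is used because the
   number of clusters is not known in advance.
2. **Graph set.** Each bottom-level cluster gets an *intra-graph* over its
   members; each interior node of the cluster tree gets an *inter-graph*
   over its children's exemplars. Edges are the union of the SSD
   minimum-spanning tree (guaranteeing connectivity) and each vertex's $k$
   nearest neighbours (local redundancy); the edge count is at most
   $N - 1 + kN$. A vertex's label $l_i$ is its degree, except that a
   cluster exemplar appearing in a parent graph carries the *total* degree
   $2|E|$ of its cluster's graph — so representatives of large,
   well-connected clusters move slowly and cluster-size imbalance does not
   drag the center toward the largest cluster.
3. **Graph shrinkage.** Every edge $\{i,j\}$ carries a stationary velocity
   field $v_{ij}$ estimated by symmetric diffeomorphic demons between the
   currently warped images, with $v_{ji} = -v_{ij}$. The objective is the
   total edge energy $F = \sum_{i,j} e_{ij} \lVert v_{ij}\rVert^2$ (each
   undirected edge counted twice). Each vertex moves along its
   label-averaged velocity $\hat v_i = \tfrac{1}{l_i}\sum_j e_{ij} v_{ij}$
   for an adaptive time step
   $\Delta t = \min\!\big(1/\max_i\lVert\hat v_i\rVert_\infty,\;
   \sum_i l_i\lVert\hat v_i\rVert^2 / \sum_i (l_i{+}1)\lVert\hat
   v_i\rVert^2\big)$, whose first term bounds any voxel's motion by one
   voxel per iteration and whose second term is strictly below 1. The
   step's diffeomorphism $\exp(\Delta t\,\hat v_i)$ is composed, newest
   outermost, onto the vertex's accumulated deformation $\varphi_i$.
4. **Hierarchy and composition.** After a leaf graph has shrunk, the warped
   image with the highest local degree is promoted (never a mean image,
   which would blur the target) and the parent inter-graph is shrunk over
   the promoted warped images. Every image's final path is its own
   bottom-level field followed by the fields its chain of representatives
   earned at higher levels, composed in that order.
5. **Multi-resolution.** The whole hierarchy is shrunk at a coarse
   resolution first (default schedule 4, 2, 1); each finer level starts
   from the upsampled solution, so native-resolution registration only
   polishes. Clustering and graph topology are computed once, at the
   coarsest level, and reused — recomputing them per level could change
   the partition mid-run and break the continuity of the deformation
   paths.

## Conventions that matter

* **Voxel-unit, pull-back warping.** All fields are displacements in voxel
  units on the common grid; world affines are metadata. Warping is
  `out(x) = img(x + u(x))` with trilinear interpolation and zero
  background. `compose_fields(outer, inner)` satisfies
  `warp(img, compose(g, f)) == warp(warp(img, f), g)`: the *inner* field
  is applied to the image first, so time-ordered flows compose with the
  newest step as `outer`, and deformation paths compose bottom level
  first.
* **Field boundary handling.** Displacement/velocity fields are sampled
  with edge-clamped (replicate) boundaries during composition and
  exponentiation. With zero-background sampling the scaling-and-squaring
  exponential and a fine Euler integration of the same velocity disagree
  by a fifth of a voxel near the grid edge; with clamping they agree
  everywhere to the tested 0.05-voxel level for fields that decay toward
  the boundary, which demons fields do (no gradient, no force).
* **Exponential map.** `exp(v)` uses scaling and squaring with a 0.5-voxel
  halving threshold — the field is halved until its maximum displacement
  is at most half a voxel, then squared back by self-composition. The
  norms in the time step are deliberately different: the first term uses
  the maximum per-voxel magnitude (so the bound has voxel meaning), the
  second uses global field energies, matching the objective's norm.

## Pairwise demons

The per-edge registration is a self-contained stationary-velocity
symmetric demons: force
$u = (f - m)\,J / (\lVert J\rVert^2 + (f-m)^2/\sigma_x^2)$ with $J$ the
mean of fixed and warped-moving gradients, per-voxel step capped at
`step_cap` (1 voxel), fluid smoothing (Gaussian, 1 voxel) of the update,
zeroth-order log-domain accumulation, diffusion smoothing (1.5 voxels) of
the velocity. Cold starts use an internal coarse-to-fine pyramid
(factor-2 levels) because a single-level demons under-recovers bulk
translations in gradient-poor interiors (the aperture problem); the
standalone default is 30 iterations per level with early exit once the
relative SSD improvement drops below 0.2% per iteration.

Within the shrinkage engine, velocities are re-estimated *from scratch*
between the currently warped images at every time point. Warm-starting
from the previous velocities was evaluated and rejected: a warm-started
demons converges to a higher-energy, non-minimal-norm velocity, which
inflates $F$ even while the images demonstrably get closer — destroying
the objective's role as a Lyapunov function of the dynamics. The engine
default uses 15 iterations per call (the re-estimation at the next time
point supersedes residual per-call refinement) and a 3-level internal
pyramid.

## Numerical safeguards

The exact shrinkage dynamics decrease $F$ monotonically, but $F$ is
*measured* through the demons estimator, which has a noise floor (it fits
intensity noise as well as anatomy). The engine therefore accepts a step
if it changes $F$ by at most +1% (the same per-step tolerance the trace
invariant allows), retries at $\Delta t/2$ and $\Delta t/4$ on a larger
increase, and stops at the last state if even the quarter step fails; it
also stops when $F$ has decreased by less than `3 * shrink_tol`
(relative) over the last three accepted steps, when all averaged
velocities vanish exactly, or at the iteration cap. Per-graph iteration
caps scale as three times the largest vertex label when that exceeds the
base budget, because the adaptive step moves a vertex at rate $\sim 1/l_i$
— an inter-graph whose exemplars carry labels near 20 needs proportionally
more, individually cheap, steps. Finer resolution levels get half the
previous level's budget (floor 10) since they start from the upsampled
coarse solution — this is precisely the efficiency argument for the
multi-resolution schedule. Jacobian determinants of emitted deformations
are positive (checked in the test suite), so all warps are locally
invertible.

Degenerate cases: a singleton graph gets the label floor 1 so the
label-average is defined; AP runs with no positive exemplar evidence
collapse to a single cluster around the minimum-total-SSD member; an
oversized cluster AP refuses to split is bisected by deterministic
2-medoids; argmax ties anywhere break toward the lowest index, and
majority-vote ties toward the smallest label.

## The synthetic population

`generate_population()` warps a known template by known smooth
deformations. The template is a head-like ellipsoid containing six
labeled structures of distinct intensities (two lateral spheres, a
cuboid, an off-centre sphere breaking left-right symmetry, two mid-size
ellipsoids); the outer ellipsoid itself is unlabeled so the size-weighted
Dice tracks the mid-size structures that actually move, as in ROI-based
evaluation of brain registration. Deformations are sums of random
Gaussian bumps (random impulses smoothed with sigma = `smoothness`,
centred in the middle 60% of the grid), scaled so the maximum magnitude
equals the stated level: one field per cluster (`inter_mag`, default 4
voxels) plus one per image (`intra_mag`, default 1.5), composed through a
single exponential; intensities get additive Gaussian noise (default 2
units, 2% of the template's dynamic range). Globally smoothed white noise
was rejected as a deformation model: after max-normalisation its median
displacement is below a tenth of its peak, so almost nothing moves.

The standard benchmark is 2 clusters x 6 images on a 64^3 grid with the
defaults above. On seeds 0-2 it gives pre-registration overall weighted
Dice of roughly 0.67-0.81 (linearly-aligned-cohort territory), and
warping each phantom's labels by the inverse of its true generating
deformation recovers the template labels with weighted Dice above 0.95 —
the ceiling set by two nearest-neighbour resamplings, which registration
cannot beat. What passing these tests shows is that the machinery
recovers smooth, moderate, cluster-structured deformations under mild
noise; real brain MRI adds intensity non-uniformity, occult anatomy,
topology differences between subjects and much finer structure, none of
which the phantoms emulate.

## Problem sizes and parameters

Defaults: `max_cluster_size = 10`, graph `k = 2`, schedule `c(4, 2, 1)`,
`shrink_tol = 1e-3` (mirroring the 0.001 slope criterion used to read
convergence off evolution curves), base `shrink_max_iters = 20`, demons
fluid/diffusion sigmas 1.0/1.5 voxels, step cap 1 voxel. The acceptance
script and test suite run the standard 64^3 benchmark for the full
pipeline and 16-32^3 populations for unit-level properties; these sizes
exercise every code path while keeping a complete run in minutes on one
core. The three ablation modes are exposed as configuration: `HUGS` (one
flat graph, no hierarchy), `HML` (hierarchy at native resolution only),
`HMRML` (hierarchy + multi-resolution, the default).

## Known limitations

* All inputs must share one voxel grid; registration is grid-local
  (world-space registration across differing grids is out of scope).
* SSD is the only similarity (mono-modal); no feature-based similarity.
* The exemplar-inheritance of upper-level fields is first-order: a
  non-exemplar inherits its representative's field verbatim rather than a
  subject-specific refinement, which bounds attainable accuracy within
  heterogeneous clusters.
* The measured objective carries the demons noise floor, so late
  iterations can stall before the theoretical optimum; the safeguards
  above make this a graceful stop, not a failure.
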