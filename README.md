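# hgshrink

Groupwise registration of a population of 3D scalar volumes (e.g. linearly
pre-aligned brain MRI) to an unbiased group center, by **hierarchical
multi-level, multi-resolution graph shrinkage**. Intended for researchers
who need a common space for a cohort without privileging any subject as
the template, including cohorts with strong anatomical heterogeneity
(mixed diagnostic groups), where registering everything to one mean image
fails.

## The method

Images `I_1 … I_N` are points on a manifold with SSD distances
`d(i,j)² = Σ_x (I_i(x) − I_j(x))²`.

1. **Cluster** the population with affinity propagation on the similarity
   matrix `s(i,j) = −SSD(i,j)` (preferences = median similarity);
   re-cluster recursively until every cluster has at most
   `max_cluster_size` images.
2. **Build a vertex-labeled graph set**: per bottom cluster an
   *intra-graph* (edges = SSD minimum spanning tree ∪ k-nearest
   neighbours), per interior tree node an *inter-graph* over the cluster
   exemplars. Labels `l_i` are vertex degrees; an exemplar in a parent
   graph carries its cluster's total degree `2|E|`, so representatives of
   big clusters move slowly.
3. **Shrink each graph**: per edge a stationary velocity `v_ij` from
   symmetric diffeomorphic demons (`v_ji = −v_ij`); objective
   `F = Σ_{i,j} e_ij ‖v_ij‖²`; each vertex moves along
   `v̂_i = (1/l_i) Σ_j e_ij v_ij` for the adaptive step
   `Δt = min( 1 / max_i ‖v̂_i‖_∞ ,
   Σ l_i‖v̂_i‖² / Σ (l_i+1)‖v̂_i‖² )`, accumulating diffeomorphisms
   `φ_i ← exp(Δt·v̂_i) ∘ φ_i` (scaling-and-squaring exponential). `F`
   decreases monotonically along the dynamics.
4. **Promote** each shrunk cluster's highest-degree *warped image* (never
   a mean) into the parent graph; an image's full deformation is
   `ψ_i = φ_i^{P} ∘ ⋯ ∘ φ_i^1` — its own bottom-level field first, then
   the fields earned by its chain of representatives.
5. **Coarse to fine**: the whole hierarchy runs at downsampling factors
   4, 2, 1; each finer level starts from the upsampled `ψ_i`.

Ablations are exposed as modes: `HUGS` (one flat graph), `HML`
(hierarchy, native resolution only), `HMRML` (full method, default).

## Worked example

Everything below is synthetic and reproducible — no data downloads. The
generator warps a known labeled template by known smooth deformations
organised into planted clusters:

```r
library(hgshrink)

pop <- generate_population(phantom_spec(grid_size = 32, n_clusters = 2,
                                        images_per_cluster = 3,
                                        inter_mag = 3, intra_mag = 1,
                                        smoothness = 4, noise_sigma = 1,
                                        seed = 1))
res <- run_multiresolution(pop$images,
                           run_config(max_cluster_size = 3,
                                      schedule = c(2, 1)))
res
#> <hg_registration_result> 6 images, mode HMRML, schedule [2, 1], 2 leaf cluster(s)

mean_pairwise_ssd(res$warped) / mean_pairwise_ssd(pop$images)
#> 0.0549   # 95% of the pairwise intensity discrepancy removed

evaluate_run(NULL, pop$label_masks)$overall   # before registration
#> 0.691
evaluate_run(res, pop$label_masks)
#> <hg_eval_report> overall weighted Dice = 0.7985, group-mean sharpness = 2.7286
```

The registration removed 95% of the mean pairwise SSD and raised the
overall size-weighted Dice of the six labeled structures — each warped
label map against the majority-vote group label map — from 0.69 to 0.80
(at this small 32³ grid the nearest-neighbour resampling ceiling itself
is about 0.94). `res$psi` holds one diffeomorphic displacement field per
image, `res$group_center` the mean of the warped images, and
`res$levels` the per-graph objective traces, which are monotonically
non-increasing at every level.

A thin command-line front end is installed with the package
(`system.file("cli", "hgshrink", package = "hgshrink")`) with
`simulate`, `register` and `evaluate` subcommands over YAML configs.

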