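#' Specification of a synthetic phantom population
#'
#' Describes a population of phantom volumes produced by warping one known
#' template with known smooth random deformations, organised into known
#' clusters. Cluster structure is created by drawing one smooth "cluster
#' mean" velocity field per cluster (magnitude `inter_mag`) and adding a
#' smaller per-image perturbation (magnitude `intra_mag`); each image is
#' the template warped by the exponential of the summed field, plus
#' additive Gaussian intensity noise. Matching label masks are warped with
#' nearest-neighbour interpolation by the same deformations.
#'
#' @param grid_size voxels per axis (cubic grid).
#' @param n_clusters number of planted clusters.
#' @param images_per_cluster images per cluster.
#' @param inter_mag maximum magnitude (voxels) of each cluster-mean
#'   velocity field — the between-cluster anatomical variation.
#' @param intra_mag maximum magnitude (voxels) of each per-image
#'   perturbation field; must not exceed `inter_mag` when `n_clusters > 1`
#'   (clusters must remain separable).
#' @param smoothness Gaussian sigma (voxels) of the random velocity fields.
#' @param noise_sigma additive intensity noise s.d. (intensity units).
#' @param seed RNG seed; the population is fully reproducible from it.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_size = 64L, n_clusters = 2L,
                         images_per_cluster = 6L, inter_mag = 4,
                         intra_mag = 1.5, smoothness = grid_size / 8,
                         noise_sigma = 2, seed = 1L) {
  if (inter_mag < 0 || intra_mag < 0 || noise_sigma < 0)
    stop("magnitudes must be >= 0")
  if (n_clusters > 1 && intra_mag > inter_mag)
    stop("intra_mag must not exceed inter_mag when n_clusters > 1")
  if (grid_size < 16) stop("grid_size must be >= 16")
  structure(list(grid_size = as.integer(grid_size),
                 n_clusters = as.integer(n_clusters),
                 images_per_cluster = as.integer(images_per_cluster),
                 inter_mag = inter_mag, intra_mag = intra_mag,
                 smoothness = smoothness, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Template phantom: geometric primitives with a labeled ROI layout
#'
#' A head-like template: a large unlabeled ellipsoid "head" containing six
#' labeled structures — two lateral spheres (1, 2), a central cuboid (3),
#' an off-centre sphere (4) that breaks the left-right symmetry, and two
#' mid-size ellipsoids (5, 6). Keeping the head itself unlabeled makes the
#' size-weighted Dice sensitive to the mid-size structures that actually
#' move under smooth deformations, as in ROI-based evaluation of brain
#' registration. The intensity image is lightly smoothed so gradients are
#' informative for demons; the label map is built from the unsmoothed
#' primitives.
#'
#' @param grid_size voxels per axis.
#' @return List with `image` ([hg_volume], intensity range about 0-110) and
#'   `labels` ([hg_labels]).
#' @export
phantom_template <- function(grid_size = 64L) {
  n <- grid_size
  ax <- seq_len(n) - (n + 1) / 2       # centred voxel coordinates
  x <- array(ax, dim = c(n, n, n))
  y <- aperm(x, c(2, 1, 3))
  z <- aperm(x, c(3, 2, 1))
  r <- n / 2
  img <- array(0, dim = c(n, n, n))
  lab <- array(0, dim = c(n, n, n))
  inside <- function(cx, cy, cz, rx, ry, rz)
    ((x - cx) / rx)^2 + ((y - cy) / ry)^2 + ((z - cz) / rz)^2 <= 1
  put <- function(mask, intensity, label) {
    img[mask] <<- intensity
    lab[mask] <<- label
  }
  put(inside(0, 0, 0, 0.82 * r, 0.72 * r, 0.76 * r), 40, 0)
  put(inside(-0.38 * r, 0.1 * r, 0, 0.15 * r, 0.15 * r, 0.16 * r), 90, 1)
  put(inside(0.38 * r, 0.1 * r, 0, 0.15 * r, 0.15 * r, 0.16 * r), 95, 2)
  box <- abs(x) <= 0.11 * r & abs(y + 0.3 * r) <= 0.15 * r &
    abs(z) <= 0.11 * r
  put(box, 70, 3)
  put(inside(0, 0.12 * r, 0.34 * r, 0.12 * r, 0.12 * r, 0.12 * r), 110, 4)
  put(inside(0, 0.42 * r, -0.18 * r, 0.15 * r, 0.12 * r, 0.13 * r), 60, 5)
  put(inside(-0.1 * r, -0.12 * r, -0.36 * r, 0.16 * r, 0.13 * r, 0.12 * r),
      85, 6)
  list(image = hg_volume(cpp_gaussian_smooth(img, 1.0)),
       labels = hg_labels(lab))
}

# Smooth random velocity field: a superposition of Gaussian bumps (random
# impulses smoothed with the given sigma) centred in the middle 60% of the
# grid so the deformation acts on the object, not the empty background.
# Scaled so the maximum vector magnitude equals `max_mag`; the bump count
# grows with grid size so coverage (and hence the typical-to-peak magnitude
# ratio) is scale-free.
random_smooth_field <- function(d, sigma, max_mag) {
  v <- array(0, dim = c(d, 3L))
  if (max_mag > 0) {
    n_bumps <- min(200L, max(8L, round(prod(0.6 * d) / sigma^3)))
    for (k in seq_len(n_bumps)) {
      pos <- vapply(d, function(n) sample.int(round(0.6 * n), 1) +
                      as.integer(round(0.2 * n)), integer(1))
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2)) * stats::runif(1, 0.5, 1)
      v[pos[1], pos[2], pos[3], ] <- v[pos[1], pos[2], pos[3], ] + dir
    }
    v <- cpp_gaussian_smooth(v, sigma)
    m <- cpp_max_magnitude(v)
    if (m > 0) v <- v * (max_mag / m)
  }
  hg_field(v, kind = "velocity")
}

#' Generate a synthetic phantom population
#'
#' @param spec a [phantom_spec].
#' @return List with `images` (list of [hg_volume]), `label_masks` (list of
#'   [hg_labels]), `template` / `template_labels`, `truth` (per-image true
#'   velocity and displacement fields), `assignment` (planted cluster index
#'   per image), `spec`.
#' @export
generate_population <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  tpl <- phantom_template(spec$grid_size)
  d <- rep(spec$grid_size, 3L)
  n_img <- spec$n_clusters * spec$images_per_cluster

  cluster_fields <- lapply(seq_len(spec$n_clusters), function(c)
    random_smooth_field(d, spec$smoothness, spec$inter_mag))
  images <- vector("list", n_img)
  masks <- vector("list", n_img)
  velocities <- vector("list", n_img)
  fields <- vector("list", n_img)
  assignment <- rep(seq_len(spec$n_clusters),
                    each = spec$images_per_cluster)
  for (i in seq_len(n_img)) {
    pert <- random_smooth_field(d, spec$smoothness, spec$intra_mag)
    v <- hg_field(cluster_fields[[assignment[i]]]$vectors + pert$vectors,
                  kind = "velocity")
    phi <- exponentiate_velocity(v)
    img <- warp_image(tpl$image, phi)
    if (spec$noise_sigma > 0)
      img <- hg_volume(img$data +
                         array(stats::rnorm(prod(d), sd = spec$noise_sigma),
                               dim = d),
                       img$spacing, img$affine)
    images[[i]] <- img
    masks[[i]] <- warp_labels(tpl$labels, phi)
    velocities[[i]] <- v
    fields[[i]] <- phi
  }
  list(images = images, label_masks = masks, template = tpl$image,
       template_labels = tpl$labels,
       truth = list(velocities = velocities, fields = fields,
                    cluster_fields = cluster_fields),
       assignment = assignment, spec = spec)
}

#' Write a phantom population to a directory
#'
#' Writes `img_<id>.nii.gz`, `labels_<id>.nii.gz`, the template pair, and a
#' `truth.json` with the planted cluster assignment and the generator spec.
#'
#' @param pop output of [generate_population].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_population <- function(pop, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(pop$images)) {
    write_volume(pop$images[[i]], file.path(dir, sprintf("img_%03d.nii.gz", i)))
    write_volume(pop$label_masks[[i]],
                 file.path(dir, sprintf("labels_%03d.nii.gz", i)))
  }
  write_volume(pop$template, file.path(dir, "template.nii.gz"))
  write_volume(pop$template_labels, file.path(dir, "template_labels.nii.gz"))
  jsonlite::write_json(list(assignment = pop$assignment,
                            spec = unclass(pop$spec)),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
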