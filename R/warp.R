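#' Warp an image by a displacement field
#'
#' Pull-back (backward) warping: `out(x) = img(x + field(x))`, trilinear
#' interpolation, background 0 outside the grid. The identity field returns
#' the image unchanged.
#'
#' @param img an [hg_volume].
#' @param field an [hg_field] on the same grid.
#' @return Warped [hg_volume].
#' @export
warp_image <- function(img, field) {
  check_same_grid(img, field)
  out <- cpp_warp_trilinear(img$data, field$vectors)
  hg_volume(out, spacing = img$spacing, affine = img$affine)
}

#' Warp a label mask by a displacement field (nearest-neighbour)
#'
#' @param mask an [hg_labels].
#' @param field an [hg_field] on the same grid.
#' @return Warped [hg_labels].
#' @export
warp_labels <- function(mask, field) {
  check_same_grid(mask, field)
  out <- cpp_warp_nearest(mask$labels, field$vectors)
  hg_labels(out, spacing = mask$spacing, affine = mask$affine)
}

#' Compose two displacement fields
#'
#' `compose_fields(outer, inner)(x) = outer(x) + inner(x + outer(x))`.
#' Under the pull-back warping convention this composes so that warping by
#' the result equals warping by `inner` first, then by `outer`:
#' `warp_image(img, compose_fields(g, f)) == warp_image(warp_image(img, f), g)`
#' up to interpolation error. Composition with the identity field returns the
#' other operand exactly. When accumulating a time-ordered flow, the newest
#' step is therefore passed as `outer`.
#'
#' @param outer,inner [hg_field]s on one common grid.
#' @return Composed [hg_field] (displacement).
#' @export
compose_fields <- function(outer, inner) {
  check_same_grid(outer, inner)
  out <- cpp_compose_fields(outer$vectors, inner$vectors)
  new_field(out, spacing = outer$spacing, affine = outer$affine,
            kind = "displacement")
}

#' Exponential of a stationary velocity field (scaling and squaring)
#'
#' Computes the diffeomorphic displacement `exp(dt * v)` as the time-1 flow
#' of the stationary velocity `dt * v`: the field is halved until its maximum
#' displacement is at most 0.5 voxel, then squared back by repeated
#' self-composition. `exp(0)` is the identity field exactly; a spatially
#' constant velocity integrates to the exact translation at interior voxels.
#'
#' @param v an [hg_field] (velocity).
#' @param dt positive time increment.
#' @return Displacement [hg_field].
#' @export
exponentiate_velocity <- function(v, dt = 1) {
  if (dt <= 0) stop("`dt` must be positive")
  u <- v$vectors * dt
  maxmag <- cpp_max_magnitude(u)
  if (!is.finite(maxmag)) stop("non-finite velocities")
  if (maxmag == 0)
    return(new_field(u, spacing = v$spacing, affine = v$affine))
  n_sq <- max(0L, ceiling(log2(maxmag / 0.5)))
  u <- u / 2^n_sq
  if (n_sq > 0) {
    for (k in seq_len(n_sq)) u <- cpp_compose_fields(u, u)
  }
  new_field(u, spacing = v$spacing, affine = v$affine,
            kind = "displacement")
}

#' Resample a displacement field to a rescaled grid
#'
#' Grid dimensions are scaled by `factor` (per axis, recycled) with
#' align-corners trilinear interpolation; displacement vectors are rescaled
#' by the same factor so that physical displacement is preserved under the
#' voxel-unit convention.
#'
#' @param field an [hg_field].
#' @param factor positive scale(s); `2` doubles the grid.
#' @return Resampled [hg_field].
#' @export
resample_field <- function(field, factor) {
  if (any(factor <= 0)) stop("`factor` must be positive")
  factor <- rep_len(factor, 3L)
  d <- dim(field$vectors)[1:3]
  newdim <- as.integer(round(d * factor))
  if (any(newdim < 2L)) stop("degenerate grid: target < 2 voxels per axis")
  comps <- lapply(1:3, function(c3) {
    cpp_resample_trilinear(array(field$vectors[, , , c3], dim = d), newdim) *
      factor[c3]
  })
  out <- array(unlist(comps, use.names = FALSE), dim = c(newdim, 3L))
  hg_field(out, spacing = field$spacing / factor, affine = field$affine,
           kind = field$kind)
}

#' Gaussian-smooth and resample an image to a rescaled grid
#'
#' Used by the multi-resolution pyramid. When downsampling (`factor < 1`)
#' the image is pre-smoothed with sigma = `0.5 / factor` voxels for
#' anti-aliasing.
#'
#' @param img an [hg_volume] or [hg_labels].
#' @param factor positive scale(s) per axis.
#' @param presmooth override the anti-aliasing sigma (voxels).
#' @return Resampled object of the same class (labels use nearest source
#'   voxel via trilinear-then-round, and are never pre-smoothed).
#' @export
resample_image <- function(img, factor, presmooth = NULL) {
  factor <- rep_len(factor, 3L)
  d <- grid_dim(img)
  newdim <- as.integer(round(d * factor))
  if (any(newdim < 2L)) stop("degenerate grid: target < 2 voxels per axis")
  if (inherits(img, "hg_labels")) {
    # nearest-neighbour downsample of integer labels
    idx <- lapply(1:3, function(a) {
      if (newdim[a] > 1) round(seq(0, d[a] - 1, length.out = newdim[a])) + 1
      else 1L
    })
    out <- img$labels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    return(hg_labels(array(out, dim = newdim), spacing = img$spacing / factor,
                     affine = img$affine))
  }
  a <- img$data
  sig <- if (is.null(presmooth)) {
    if (any(factor < 1)) 0.5 / min(factor) else 0
  } else presmooth
  if (sig > 0) a <- cpp_gaussian_smooth(a, sig)
  out <- cpp_resample_trilinear(a, newdim)
  hg_volume(out, spacing = img$spacing / factor, affine = img$affine)
}

#' Gaussian smoothing of a volume or field
#'
#' Separable Gaussian with replicate boundaries; fields are smoothed per
#' component.
#'
#' @param x an [hg_volume] or [hg_field].
#' @param sigma standard deviation in voxels; `0` is a no-op.
#' @return Smoothed object of the same class.
#' @export
smooth_gaussian <- function(x, sigma) {
  if (inherits(x, "hg_volume"))
    hg_volume(cpp_gaussian_smooth(x$data, sigma), x$spacing, x$affine)
  else if (inherits(x, "hg_field"))
    hg_field(cpp_gaussian_smooth(x$vectors, sigma), x$spacing, x$affine,
             kind = x$kind)
  else stop("unsupported type")
}

#' Jacobian-determinant map of a displacement field
#'
#' Finite-difference determinant of `I + Du`; strictly positive values at
#' interior voxels certify the field is locally diffeomorphic.
#'
#' @param field an [hg_field] (displacement).
#' @return 3D numeric array of per-voxel determinants.
#' @export
jacobian_determinant <- function(field) {
  d <- dim(field$vectors)[1:3]
  g <- lapply(1:3, function(c3)
    cpp_gradient(array(field$vectors[, , , c3], dim = d)))
  # J[r,c] = d u_r / d x_c + delta_rc
  j11 <- g[[1]][, , , 1] + 1; j12 <- g[[1]][, , , 2]; j13 <- g[[1]][, , , 3]
  j21 <- g[[2]][, , , 1]; j22 <- g[[2]][, , , 2] + 1; j23 <- g[[2]][, , , 3]
  j31 <- g[[3]][, , , 1]; j32 <- g[[3]][, , , 2]; j33 <- g[[3]][, , , 3] + 1
  det <- j11 * (j22 * j33 - j23 * j32) -
    j12 * (j21 * j33 - j23 * j31) +
    j13 * (j21 * j32 - j22 * j31)
  array(det, dim = d)
}

#' Field norms
#'
#' `field_max_magnitude` is the maximum per-voxel Euclidean vector length
#' (voxels); `field_sq_norm` is the global sum of squared vector components
#' over all voxels (the field energy used by the shrinkage objective).
#'
#' @param field an [hg_field].
#' @return A scalar.
#' @export
field_max_magnitude <- function(field) cpp_max_magnitude(field$vectors)

#' @rdname field_max_magnitude
#' @export
field_sq_norm <- function(field) sum(field$vectors^2)
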