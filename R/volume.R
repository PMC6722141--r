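#' @useDynLib hgshrink, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Scalar image volume
#'
#' A 3D scalar image on a regular voxel grid. Intensities are stored as a
#' numeric `D x H x W` array; the voxel spacing (mm) and the grid-to-world
#' affine are carried as metadata only — all registration math in this
#' package is performed in voxel-index space, which is appropriate because
#' inputs are assumed linearly pre-aligned onto one common grid.
#'
#' @param data numeric 3D array of intensities; must be finite everywhere.
#' @param spacing positive numeric vector of length 3, voxel size per axis.
#' @param affine 4x4 grid-to-world matrix (metadata only).
#' @return An object of class `hg_volume` with elements `data`, `spacing`,
#'   `affine`.
#' @export
hg_volume <- function(data, spacing = c(1, 1, 1), affine = diag(4)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (got ", length(dim(data)), " dims)")
  if (anyNA(data) || any(!is.finite(data)))
    stop("image contains NaN/Inf voxels")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values")
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = as.numeric(spacing),
                 affine = affine),
            class = "hg_volume")
}

#' @export
print.hg_volume <- function(x, ...) {
  cat("<hg_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, range [", signif(min(x$data), 5), ", ",
      signif(max(x$data), 5), "]\n", sep = "")
  invisible(x)
}

#' Vector field on an image grid
#'
#' Displacement or stationary-velocity field: a `D x H x W x 3` numeric array
#' of per-voxel vectors in voxel units (per unit time for velocities), on the
#' same grid as its reference [hg_volume]. The identity displacement field is
#' all zeros.
#'
#' @param vectors numeric 4D array with last dimension 3.
#' @param spacing,affine grid metadata, as for [hg_volume].
#' @param kind `"displacement"` or `"velocity"`.
#' @return An object of class `hg_field`.
#' @export
hg_field <- function(vectors, spacing = c(1, 1, 1), affine = diag(4),
                     kind = c("displacement", "velocity")) {
  kind <- match.arg(kind)
  d <- dim(vectors)
  if (length(d) != 4L || d[4] != 3L)
    stop("`vectors` must be a D x H x W x 3 array")
  if (anyNA(vectors) || any(!is.finite(vectors)))
    stop("field contains non-finite vectors")
  storage.mode(vectors) <- "double"
  structure(list(vectors = vectors, spacing = as.numeric(spacing),
                 affine = affine, kind = kind),
            class = "hg_field")
}

# Internal constructor for hot paths: skips the finiteness scan, which is
# a measurable fraction of demons runtime on full-size grids. Only for
# vectors produced by kernels that cannot introduce non-finite values.
new_field <- function(vectors, spacing = c(1, 1, 1), affine = diag(4),
                      kind = "displacement") {
  structure(list(vectors = vectors, spacing = spacing, affine = affine,
                 kind = kind),
            class = "hg_field")
}

#' @export
print.hg_field <- function(x, ...) {
  cat("<hg_field> ", x$kind, ", ", paste(dim(x$vectors)[1:3], collapse = " x "),
      " voxels, max |u| = ", signif(cpp_max_magnitude(x$vectors), 5),
      " voxels\n", sep = "")
  invisible(x)
}

#' Identity displacement field on the grid of a volume
#' @param ref an [hg_volume] (or anything with a `data`/`vectors` 3D grid).
#' @return All-zero `hg_field` of kind `"displacement"`.
#' @export
identity_field <- function(ref) {
  d <- grid_dim(ref)
  hg_field(array(0, dim = c(d, 3L)), spacing = ref$spacing,
           affine = ref$affine, kind = "displacement")
}

#' Integer label mask
#'
#' @param labels integer-valued 3D array, 0 = background.
#' @param spacing,affine grid metadata.
#' @return An object of class `hg_labels`.
#' @export
hg_labels <- function(labels, spacing = c(1, 1, 1), affine = diag(4)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array")
  if (anyNA(labels) || any(labels < 0) || any(labels != round(labels)))
    stop("labels must be non-negative integers")
  storage.mode(labels) <- "double"
  structure(list(labels = labels, spacing = as.numeric(spacing),
                 affine = affine),
            class = "hg_labels")
}

grid_dim <- function(x) {
  if (inherits(x, "hg_volume")) dim(x$data)
  else if (inherits(x, "hg_labels")) dim(x$labels)
  else if (inherits(x, "hg_field")) dim(x$vectors)[1:3]
  else stop("not a grid-bearing object")
}

check_same_grid <- function(a, b) {
  if (!identical(as.integer(grid_dim(a)), as.integer(grid_dim(b))))
    stop("grid mismatch: ", paste(grid_dim(a), collapse = "x"), " vs ",
         paste(grid_dim(b), collapse = "x"))
  invisible(TRUE)
}

#' Read a NIfTI-1 volume
#'
#' Reads `.nii`/`.nii.gz`. 3D scalar data becomes an [hg_volume]; 5D data of
#' shape `D x H x W x 1 x 3` (the displacement-vector layout written by
#' [write_field]) becomes an [hg_field]. Non-finite voxels are rejected.
#'
#' @param path path to a NIfTI-1 file.
#' @param labels if `TRUE`, return an [hg_labels] mask instead.
#' @return [hg_volume], [hg_labels] or [hg_field].
#' @export
read_volume <- function(path, labels = FALSE) {
  if (!file.exists(path)) stop("cannot read NIfTI file: ", path)
  nim <- RNifti::readNifti(path)
  a <- as.array(nim)
  d <- dim(a)
  attributes(a) <- list(dim = d)   # drop RNifti's image attributes
  spacing <- abs(RNifti::pixdim(nim))[seq_len(min(3L, length(d)))]
  if (length(spacing) < 3L) spacing <- c(spacing, rep(1, 3L - length(spacing)))
  aff <- unclass(RNifti::xform(nim))
  if (length(d) == 5L && d[4] == 1L && d[5] == 3L) {
    return(hg_field(array(a, dim = c(d[1:3], 3L)), spacing = spacing,
                    affine = aff))
  }
  if (length(d) == 4L && d[4] == 1L) {
    a <- array(a, dim = d[1:3]); d <- dim(a)
  }
  if (length(d) != 3L)
    stop("expected a 3D volume, got ", length(d), "D data in ", path)
  if (labels) hg_labels(a, spacing = spacing, affine = aff)
  else hg_volume(a, spacing = spacing, affine = aff)
}

#' Write a volume, mask or field as NIfTI-1
#'
#' Fields are written as 5D `D x H x W x 1 x 3` vector images (one volume per
#' displacement component, in voxel units along the array axes).
#'
#' @param x [hg_volume], [hg_labels] or [hg_field].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "hg_field")) {
    d <- dim(x$vectors)
    a <- array(x$vectors, dim = c(d[1:3], 1L, 3L))
  } else if (inherits(x, "hg_labels")) {
    a <- x$labels
  } else {
    a <- x$data
  }
  nim <- RNifti::asNifti(a, pixdim = x$spacing)
  nim <- RNifti::`sform<-`(nim, structure(x$affine, code = 2L))
  RNifti::writeNifti(nim, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
write_field <- function(x, path) {
  stopifnot(inherits(x, "hg_field"))
  write_volume(x, path)
}
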