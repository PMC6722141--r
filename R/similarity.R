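#' Sum of squared differences between two volumes
#'
#' @param a,b [hg_volume]s on a common grid.
#' @return Non-negative scalar `sum((a - b)^2)`.
#' @export
ssd <- function(a, b) {
  check_same_grid(a, b)
  sum((a$data - b$data)^2)
}

#' Select the population template by minimum total SSD
#'
#' Returns the index of the image minimising the sum of squared differences
#' to all other images — the most central image of the population in the
#' SSD sense. Ties are broken by the lowest index.
#'
#' @param images list of [hg_volume]s on one grid.
#' @return Integer index into `images`.
#' @export
select_template <- function(images) {
  n <- length(images)
  if (n == 0) stop("empty image list")
  if (n == 1) return(1L)
  d <- ssd_matrix(images)
  which.min(rowSums(d))
}

#' Pairwise SSD distance matrix
#'
#' @param images list of [hg_volume]s on one grid.
#' @return Symmetric N x N matrix of pairwise SSD values, zero diagonal.
#' @export
ssd_matrix <- function(images) {
  n <- length(images)
  d <- matrix(0, n, n)
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- ssd(images[[i]], images[[j]])
    }
  }
  d
}

#' Build the affinity-propagation similarity matrix
#'
#' Off-diagonal entries are negative pairwise SSD, `s(i, j) = -SSD(i, j)`;
#' all diagonal entries (the shared AP preference) are set to the median of
#' the `N(N-1)/2` unique off-diagonal similarities, so that no image is
#' a-priori favoured as an exemplar.
#'
#' @param images list of at least two [hg_volume]s, or a precomputed SSD
#'   distance matrix (as from [ssd_matrix]).
#' @param rescale if `TRUE`, linearly rescale all intensities to `[0, 100]`
#'   jointly before computing SSD (off by default).
#' @return N x N similarity matrix of class `hg_similarity`.
#' @export
build_similarity <- function(images, rescale = FALSE) {
  if (is.matrix(images)) {
    d <- images
  } else {
    if (length(images) < 2) stop("need at least 2 images")
    if (rescale) {
      rng <- range(vapply(images, function(v) range(v$data),
                          numeric(2)))
      span <- diff(rng)
      if (span > 0)
        images <- lapply(images, function(v)
          hg_volume((v$data - rng[1]) / span * 100, v$spacing, v$affine))
    }
    d <- ssd_matrix(images)
  }
  s <- -d
  pref <- stats::median(s[upper.tri(s)])
  diag(s) <- pref
  structure(s, class = c("hg_similarity", "matrix", "array"))
}
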