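#' Hierarchical cluster tree by recursive affinity propagation
#'
#' Runs affinity propagation on the population similarity matrix and
#' recursively re-clusters any cluster larger than `max_cluster_size`,
#' recomputing the AP preference from the sub-matrix median at every round.
#' Leaves therefore satisfy the size bound; an interior node records the
#' partition of its members into children. Levels are assigned bottom-up
#' with leaves at level 1.
#'
#' If AP fails to split an oversized cluster, a deterministic 2-medoid
#' bisection on the SSD distances is used as a fallback so that the
#' recursion always terminates.
#'
#' @param images list of [hg_volume]s, or a precomputed SSD distance matrix.
#' @param max_cluster_size maximum number of images allowed in a leaf
#'   (default 10).
#' @param damping,max_iter,conv_iter AP parameters, see
#'   [affinity_propagation].
#' @return An `hg_cluster_tree`: a list with `root` (recursive node
#'   structure: `members`, `exemplar`, `children`, `level`), `n`, `depth`.
#' @export
build_cluster_tree <- function(images, max_cluster_size = 10L,
                               damping = 0.5, max_iter = 500L,
                               conv_iter = 50L) {
  if (max_cluster_size < 2) stop("`max_cluster_size` must be >= 2")
  d <- if (is.matrix(images)) images else ssd_matrix(images)
  n <- nrow(d)
  root <- split_node(seq_len(n), d, max_cluster_size, damping, max_iter,
                     conv_iter)
  root <- assign_levels(root)
  structure(list(root = root, n = n, depth = root$level),
            class = "hg_cluster_tree")
}

split_node <- function(members, d, max_size, damping, max_iter, conv_iter) {
  m <- length(members)
  sub <- d[members, members, drop = FALSE]
  if (m == 1) {
    return(list(members = members, exemplar = members[1], children = list()))
  }
  S <- build_similarity(sub)
  ap <- affinity_propagation(S, damping = damping, max_iter = max_iter,
                             conv_iter = conv_iter)
  exemplar <- members[ap$exemplars[which.min(vapply(
    ap$exemplars, function(e) sum(sub[e, ]), numeric(1)))]]
  if (m <= max_size) {
    return(list(members = members, exemplar = exemplar, children = list()))
  }
  parts <- ap$clusters
  if (length(parts) < 2 || any(lengths(parts) == m)) {
    parts <- bisect_medoids(sub)
  }
  children <- lapply(parts, function(p)
    split_node(members[p], d, max_size, damping, max_iter, conv_iter))
  list(members = members, exemplar = exemplar, children = children)
}

# Deterministic 2-medoid bisection on a distance matrix: seeds are the most
# distant pair; points join the nearer seed; medoids refined once.
bisect_medoids <- function(d) {
  n <- nrow(d)
  ij <- which(d == max(d), arr.ind = TRUE)[1, ]
  seeds <- sort(as.integer(ij))
  for (rep in 1:2) {
    assign_idx <- ifelse(d[, seeds[1]] <= d[, seeds[2]], 1L, 2L)
    assign_idx[seeds] <- c(1L, 2L)
    for (k in 1:2) {
      mem <- which(assign_idx == k)
      seeds[k] <- mem[which.min(rowSums(d[mem, mem, drop = FALSE]))]
    }
  }
  assign_idx <- ifelse(d[, seeds[1]] <= d[, seeds[2]], 1L, 2L)
  assign_idx[seeds] <- c(1L, 2L)
  list(which(assign_idx == 1L), which(assign_idx == 2L))
}

assign_levels <- function(node) {
  if (length(node$children) == 0) {
    node$level <- 1L
  } else {
    node$children <- lapply(node$children, assign_levels)
    node$level <- max(vapply(node$children, `[[`, integer(1), "level")) + 1L
  }
  node
}

#' @export
print.hg_cluster_tree <- function(x, ...) {
  cat("<hg_cluster_tree> ", x$n, " images, depth ", x$depth, ", ",
      length(tree_leaves(x$root)), " leaves\n", sep = "")
  invisible(x)
}

#' Leaves of a cluster tree
#' @param node a tree node (typically `tree$root`).
#' @return List of leaf nodes in deterministic (depth-first) order.
#' @export
tree_leaves <- function(node) {
  if (length(node$children) == 0) return(list(node))
  do.call(c, lapply(node$children, tree_leaves))
}

#' Serialize a cluster tree to JSON
#' @param tree an `hg_cluster_tree`.
#' @param path optional file to write to.
#' @return JSON string (invisibly if written to file).
#' @export
tree_to_json <- function(tree, path = NULL) {
  strip <- function(node) {
    list(members = node$members, exemplar = node$exemplar,
         level = node$level,
         children = lapply(node$children, strip))
  }
  js <- jsonlite::toJSON(strip(tree$root), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
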