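#' Build a connected vertex-labeled graph over a set of images
#'
#' Edge rule: the union of (a) the minimum-spanning-tree edges of the
#' pairwise SSD distances — which guarantees every image is linked to the
#' rest — and (b) each vertex's `k` nearest neighbours, which add local
#' redundancy while keeping the edge count small (`|E| <= N - 1 + kN`).
#' Vertex labels are the vertex degrees; a singleton graph gets the label
#' floor 1 so that label-averaged velocities are always defined.
#'
#' @param members integer image indices (vertices).
#' @param distances pairwise SSD distance matrix over `members` (either the
#'   `|members|`-sized submatrix or the full population matrix, from which
#'   the submatrix is taken).
#' @param k number of nearest neighbours per vertex (default 2).
#' @param kind `"intra"` or `"inter"`.
#' @param level hierarchy level of the graph.
#' @return An `hg_graph`: list with `vertices` (image indices), `edges`
#'   (m x 2 matrix of image-index pairs, i < j), `labels` (named integer
#'   vector), `kind`, `level`.
#' @export
build_graph <- function(members, distances, k = 2L, kind = "intra",
                        level = 1L) {
  m <- length(members)
  if (m == 0) stop("empty member list")
  if (nrow(distances) != m)
    distances <- distances[members, members, drop = FALSE]
  if (m == 1) {
    g <- list(vertices = members, edges = matrix(integer(0), 0, 2),
              labels = stats::setNames(1L, members), kind = kind,
              level = level)
    class(g) <- "hg_graph"
    return(g)
  }
  # MST on the complete SSD-weighted graph
  ig <- igraph::graph_from_adjacency_matrix(distances, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  mst <- igraph::mst(ig, algorithm = "prim")
  e <- igraph::as_edgelist(mst, names = FALSE)
  edges <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  # k nearest neighbours per vertex
  kk <- min(k, m - 1L)
  if (kk > 0) {
    for (i in seq_len(m)) {
      nn <- order(distances[i, ])
      nn <- setdiff(nn, i)[seq_len(kk)]
      edges <- rbind(edges, cbind(pmin(i, nn), pmax(i, nn)))
    }
  }
  edges <- unique(edges)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  deg <- tabulate(as.vector(edges), nbins = m)
  g <- list(vertices = members,
            edges = cbind(members[edges[, 1]], members[edges[, 2]]),
            labels = stats::setNames(pmax(deg, 1L), members),
            kind = kind, level = level)
  class(g) <- "hg_graph"
  g
}

#' @export
print.hg_graph <- function(x, ...) {
  cat("<hg_graph> ", x$kind, " level ", x$level, ": ",
      length(x$vertices), " vertices, ", nrow(x$edges), " edges, labels [",
      paste(x$labels, collapse = ", "), "]\n", sep = "")
  invisible(x)
}

graph_degree <- function(g) {
  deg <- tabulate(match(as.vector(g$edges), g$vertices),
                  nbins = length(g$vertices))
  stats::setNames(deg, g$vertices)
}

graph_total_degree <- function(g) 2L * nrow(g$edges)

#' Assemble the hierarchical vertex-labeled graph set
#'
#' One intra-graph per leaf cluster of the tree and one inter-graph per
#' interior node, the latter over the exemplars of that node's children.
#' In every parent graph the label of a vertex that is the exemplar of a
#' child cluster is overridden to the total vertex degree (`2 |E|`, with a
#' floor of 1) of that child's own graph; this makes the representatives of
#' large, well-connected clusters move more slowly during shrinkage, which
#' counters cluster-size imbalance. Non-exemplar labels remain plain
#' degrees.
#'
#' @param tree an `hg_cluster_tree` from [build_cluster_tree].
#' @param distances full population SSD distance matrix.
#' @param k nearest-neighbour count for [build_graph].
#' @return An `hg_graph_set`: `graphs` (list ordered bottom level first;
#'   inter-graphs additionally carry `child_ids` aligned with their
#'   vertices), `root_id`, `linkage` (data.frame mapping each non-root
#'   graph id to its parent graph id and its exemplar's vertex there).
#' @export
assemble_graph_set <- function(tree, distances, k = 2L) {
  graphs <- list()
  counter <- new.env()
  counter$next_id <- 1L

  walk <- function(node) {
    id <- counter$next_id
    counter$next_id <- id + 1L
    if (length(node$children) == 0) {
      g <- build_graph(node$members, distances, k = k, kind = "intra",
                       level = node$level)
      g$id <- id
      g$members <- node$members
      g$exemplar <- node$exemplar
      graphs[[as.character(id)]] <<- g
      return(list(id = id, exemplar = node$exemplar,
                  total_degree = max(1L, graph_total_degree(g))))
    }
    kids <- lapply(node$children, walk)
    exemplars <- vapply(kids, `[[`, integer(1), "exemplar")
    g <- build_graph(exemplars, distances, k = k, kind = "inter",
                     level = node$level)
    # exemplar label override: total vertex degree of the child's graph
    for (ci in seq_along(kids))
      g$labels[as.character(exemplars[ci])] <- kids[[ci]]$total_degree
    g$id <- id
    g$members <- node$members
    g$exemplar <- node$exemplar
    g$child_ids <- vapply(kids, `[[`, integer(1), "id")
    graphs[[as.character(id)]] <<- g
    for (ci in seq_along(kids)) {
      graphs[[as.character(kids[[ci]]$id)]]$parent_id <<- id
    }
    list(id = id, exemplar = node$exemplar,
         total_degree = max(1L, graph_total_degree(g)))
  }
  root <- walk(tree$root)
  ord <- order(vapply(graphs, `[[`, integer(1), "level"),
               vapply(graphs, `[[`, integer(1), "id"))
  graphs <- graphs[ord]
  linkage <- do.call(rbind, lapply(graphs, function(g) {
    if (is.null(g$parent_id)) return(NULL)
    data.frame(graph_id = g$id, parent_id = g$parent_id,
               exemplar = g$exemplar)
  }))
  structure(list(graphs = graphs, root_id = root$id, linkage = linkage),
            class = "hg_graph_set")
}

#' @export
print.hg_graph_set <- function(x, ...) {
  cat("<hg_graph_set> ", length(x$graphs), " graphs (",
      sum(vapply(x$graphs, function(g) g$kind == "intra", logical(1))),
      " intra, ",
      sum(vapply(x$graphs, function(g) g$kind == "inter", logical(1))),
      " inter)\n", sep = "")
  invisible(x)
}

#' Serialize a graph set to JSON
#' @param gs an `hg_graph_set`.
#' @param path optional output file.
#' @return JSON string.
#' @export
graph_set_to_json <- function(gs, path = NULL) {
  out <- lapply(gs$graphs, function(g) {
    list(id = g$id, kind = g$kind, level = g$level, vertices = g$vertices,
         edges = g$edges, labels = as.integer(g$labels),
         parent_id = if (is.null(g$parent_id)) NA else g$parent_id)
  })
  js <- jsonlite::toJSON(list(graphs = unname(out), root_id = gs$root_id),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Render a graph to Graphviz DOT
#' @param g an `hg_graph`.
#' @return Character scalar of DOT source.
#' @export
graph_to_dot <- function(g) {
  nodes <- sprintf("  v%d [label=\"%d (l=%d)\"];", g$vertices, g$vertices,
                   as.integer(g$labels))
  edges <- if (nrow(g$edges) > 0)
    sprintf("  v%d -- v%d;", g$edges[, 1], g$edges[, 2]) else character(0)
  paste(c(sprintf("graph %s_%d {", g$kind, g$level), nodes, edges, "}"),
        collapse = "\n")
}
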