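#' Run configuration for groupwise registration
#'
#' @param max_cluster_size leaf size bound for hierarchical clustering.
#' @param k nearest-neighbour count for graph construction.
#' @param demons a [demons_config]. The pipeline default uses 15 update
#'   iterations per call rather than the standalone default of 30: inside
#'   the shrinkage loop every edge is re-estimated from scratch at each
#'   time point, so per-call convergence beyond the step size actually
#'   taken is wasted work.
#' @param shrink_tol relative objective-decrease stopping tolerance per
#'   graph.
#' @param shrink_max_iters maximum shrinkage iterations per graph.
#' @param schedule down-sampling factors, coarse to fine, strictly
#'   decreasing with the last equal to 1 (native resolution).
#' @param mode `"HMRML"` (full hierarchy + multi-resolution), `"HML"`
#'   (hierarchy only; the schedule is forced to `1`), or `"HUGS"` (one flat
#'   graph over the whole population, no hierarchy).
#' @param seed integer recorded in the manifest (registration itself is
#'   deterministic; the seed matters only to upstream simulation).
#' @param output_dir optional directory for NIfTI/CSV/JSON outputs.
#' @return A `hg_run_config` list.
#' @export
run_config <- function(max_cluster_size = 10L, k = 2L,
                       demons = demons_config(iterations_per_level = 15L,
                                              pyramid_levels = 3L),
                       shrink_tol = 1e-3,
                       shrink_max_iters = 20L, schedule = c(4, 2, 1),
                       mode = c("HMRML", "HML", "HUGS"), seed = 1L,
                       output_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "HML") schedule <- 1
  if (any(diff(schedule) >= 0) || schedule[length(schedule)] != 1)
    stop("`schedule` must be strictly decreasing and end at 1")
  structure(list(max_cluster_size = as.integer(max_cluster_size),
                 k = as.integer(k), demons = demons,
                 shrink_tol = shrink_tol,
                 shrink_max_iters = as.integer(shrink_max_iters),
                 schedule = schedule, mode = mode, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "hg_run_config")
}

#' Promote the exemplar of a shrunken graph
#'
#' After a graph has been shrunk, the warped image attached to the vertex
#' with the highest degree in the local graph is promoted to represent the
#' cluster at the next hierarchy level; ties are broken by the lowest image
#' index. The promoted object is always one of the warped images, never a
#' mean image.
#'
#' @param state the final `hg_shrinkage_state` of the graph.
#' @param graph the `hg_graph` that was shrunk.
#' @return The promoted vertex's image index.
#' @export
promote_exemplar <- function(state, graph) {
  deg <- graph_degree(graph)
  verts <- graph$vertices
  best <- verts[deg == max(deg)]
  min(best)
}

#' Compose a per-image deformation path
#'
#' Left-to-right composition in apply order: the first field of the path
#' (the image's own bottom-level deformation) is applied first, then each
#' higher level's field, so
#' `warp(img, compose_path(list(f, g))) == warp(warp(img, f), g)` up to
#' interpolation.
#'
#' @param path non-empty list of displacement [hg_field]s on one grid.
#' @return Composed displacement [hg_field].
#' @export
compose_path <- function(path) {
  if (length(path) == 0) stop("empty deformation path")
  acc <- path[[1]]
  for (p in seq_along(path)[-1]) acc <- compose_fields(path[[p]], acc)
  acc
}

#' Shrink the whole hierarchical graph set at one resolution
#'
#' Shrinks every bottom-level intra-graph, promotes the highest-degree
#' warped image of each as its cluster's representative, shrinks the parent
#' inter-graphs on those warped representatives, and repeats up to the root.
#' Every image inherits, for each ancestor node above its leaf, the field
#' earned there by the representative of the child subtree it belongs to,
#' yielding the per-image deformation path `{phi_i^p, p = 1..P(i)}`.
#'
#' @param images list of [hg_volume]s (indexed by image index).
#' @param tree `hg_cluster_tree` (consistent with `graph_set`).
#' @param graph_set `hg_graph_set` from [assemble_graph_set].
#' @param cfg a [run_config].
#' @param counter optional environment counting demons calls.
#' @return List with `paths` (per image: list of fields, bottom level
#'   first), `states` (per graph id), `promoted` (per graph id: promoted
#'   image index).
#' @export
run_level_hierarchy <- function(images, tree, graph_set,
                                cfg = run_config(), counter = NULL) {
  graphs <- graph_set$graphs  # ordered bottom level first
  n_img <- tree$n
  paths <- vector("list", n_img)
  states <- list()
  promoted <- list()
  rep_image <- list()  # per graph id: the warped image representing it

  for (g in graphs) {
    gid <- as.character(g$id)
    if (g$kind == "intra") {
      imgs_in <- images
    } else {
      # vertices are the tree exemplars of the children; each carries the
      # promoted warped image of its child's graph
      imgs_in <- vector("list", max(g$vertices))
      for (ci in seq_along(g$child_ids)) {
        v <- g$vertices[ci]
        imgs_in[[v]] <- rep_image[[as.character(g$child_ids[ci])]]
      }
    }
    # the adaptive step moves a vertex at rate ~1/label, so graphs whose
    # vertices carry large (exemplar) labels need proportionally more
    # iterations to close the same gap
    iters_g <- max(cfg$shrink_max_iters, 3L * as.integer(max(g$labels)))
    st <- shrink_graph(imgs_in, g, demons_cfg = cfg$demons,
                       tol = cfg$shrink_tol,
                       max_iters = iters_g, counter = counter)
    states[[gid]] <- st
    pv <- promote_exemplar(st, g)
    promoted[[gid]] <- pv
    rep_image[[gid]] <- st$warped_images[[as.character(pv)]]
    if (g$kind == "intra") {
      for (i in g$vertices)
        paths[[i]] <- list(st$fields[[as.character(i)]])
    } else {
      for (ci in seq_along(g$child_ids)) {
        v <- g$vertices[ci]
        f <- st$fields[[as.character(v)]]
        child <- graph_set$graphs[[as.character(g$child_ids[ci])]]
        for (i in child$members)
          paths[[i]] <- c(paths[[i]], list(f))
      }
    }
  }
  list(paths = paths, states = states, promoted = promoted)
}

#' Multi-resolution hierarchical groupwise registration
#'
#' The full method: hierarchical affinity-propagation clustering and graph
#' construction at the coarsest resolution, then coarse-to-fine graph-set
#' shrinkage. Per-image deformations estimated at each resolution are
#' upsampled (with vector rescaling) to initialise the next finer level, so
#' native-resolution registration never starts from scratch; clustering and
#' graph topology are computed once at the coarsest level and reused.
#'
#' @param images list of [hg_volume]s on one common grid, or a character
#'   vector of NIfTI paths.
#' @param cfg a [run_config].
#' @return An `hg_registration_result`: `psi` (per-image final displacement
#'   [hg_field]s at native resolution), `group_center` (mean of the finally
#'   warped images), `warped` (the finally warped images), `levels`
#'   (per-resolution shrinkage states and traces), `tree`, `graph_set`,
#'   `manifest` (config echo, seed, template index, demons call counts per
#'   resolution).
#' @export
run_multiresolution <- function(images, cfg = run_config()) {
  if (is.character(images)) images <- lapply(images, read_volume)
  n <- length(images)
  if (n < 2) stop("need at least 2 images")
  for (i in seq_len(n - 1)) check_same_grid(images[[i]], images[[i + 1]])
  schedule <- cfg$schedule
  f0 <- schedule[1]

  imgs_at <- function(f) {
    if (f == 1) images
    else lapply(images, resample_image, factor = 1 / f)
  }
  coarse <- imgs_at(f0)
  dist_coarse <- ssd_matrix(coarse)
  template_idx <- which.min(rowSums(dist_coarse))
  mcs <- if (cfg$mode == "HUGS") n else cfg$max_cluster_size
  tree <- build_cluster_tree(dist_coarse, max_cluster_size = max(2L, mcs))
  graph_set <- assemble_graph_set(tree, dist_coarse, k = cfg$k)

  psi <- NULL
  prev_dim <- NULL
  levels <- list()
  calls <- integer(0)
  for (f in schedule) {
    imgs_f <- if (f == f0) coarse else imgs_at(f)
    dim_f <- grid_dim(imgs_f[[1]])
    if (!is.null(psi)) {
      fac <- dim_f / prev_dim
      psi <- lapply(psi, resample_field, factor = fac)
      warped0 <- lapply(seq_len(n), function(i)
        warp_image(imgs_f[[i]], psi[[i]]))
    } else {
      warped0 <- imgs_f
    }
    counter <- new.env()
    counter$calls <- 0
    # the coarsest level does the bulk of the work from scratch; finer
    # levels start from the upsampled solution and only polish, so their
    # iteration budget is halved per level (floor 8)
    lvl_idx <- match(f, schedule)
    cfg_f <- cfg
    cfg_f$shrink_max_iters <-
      max(10L, as.integer(ceiling(cfg$shrink_max_iters / 2^(lvl_idx - 1))))
    lev <- run_level_hierarchy(warped0, tree, graph_set, cfg_f,
                               counter = counter)
    delta <- lapply(lev$paths, compose_path)
    psi <- if (is.null(psi)) delta
    else lapply(seq_len(n), function(i) compose_fields(delta[[i]], psi[[i]]))
    states_slim <- lapply(lev$states, function(st)
      st[c("trace", "dt_history", "iterations", "converged")])
    levels[[paste0("factor_", f)]] <- list(
      states = states_slim, promoted = lev$promoted, factor = f,
      demons_calls = counter$calls)
    calls[paste0("factor_", f)] <- counter$calls
    prev_dim <- dim_f
  }

  warped <- lapply(seq_len(n), function(i) warp_image(images[[i]], psi[[i]]))
  gc_img <- hg_volume(Reduce(`+`, lapply(warped, `[[`, "data")) / n,
                      images[[1]]$spacing, images[[1]]$affine)
  manifest <- list(
    package = "hgshrink",
    version = as.character(utils::packageVersion("hgshrink")),
    n_images = n, mode = cfg$mode, schedule = schedule,
    max_cluster_size = cfg$max_cluster_size, k = cfg$k,
    seed = cfg$seed, template_index = template_idx,
    tree_depth = tree$depth,
    n_leaves = length(tree_leaves(tree$root)),
    demons_calls = as.list(calls),
    demons = unclass(cfg$demons),
    shrink_tol = cfg$shrink_tol, shrink_max_iters = cfg$shrink_max_iters)
  res <- structure(list(psi = psi, group_center = gc_img, warped = warped,
                        levels = levels, tree = tree, graph_set = graph_set,
                        manifest = manifest),
                   class = "hg_registration_result")
  if (!is.null(cfg$output_dir)) write_result(res, cfg$output_dir)
  res
}

#' @export
print.hg_registration_result <- function(x, ...) {
  cat("<hg_registration_result> ", x$manifest$n_images, " images, mode ",
      x$manifest$mode, ", schedule [",
      paste(x$manifest$schedule, collapse = ", "), "], ",
      x$manifest$n_leaves, " leaf cluster(s)\n", sep = "")
  invisible(x)
}

#' Write registration outputs to a directory
#'
#' Writes `psi_<id>.nii.gz`, `group_center.nii.gz`, `manifest.json` and one
#' `trace_level<factor>.csv` per resolution level (objective and time-step
#' history per graph).
#'
#' @param result an `hg_registration_result`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(result$psi))
    write_field(result$psi[[i]],
                file.path(dir, sprintf("psi_%03d.nii.gz", i)))
  write_volume(result$group_center, file.path(dir, "group_center.nii.gz"))
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (lev in result$levels) {
    rows <- do.call(rbind, lapply(names(lev$states), function(gid) {
      st <- lev$states[[gid]]
      if (length(st$trace) == 0) return(NULL)
      data.frame(graph_id = gid, step = seq_along(st$trace) - 1L,
                 objective = st$trace,
                 dt = c(NA, st$dt_history)[seq_along(st$trace)])
    }))
    if (!is.null(rows))
      utils::write.csv(rows,
                       file.path(dir, sprintf("trace_level%g.csv",
                                              lev$factor)),
                       row.names = FALSE)
  }
  invisible(dir)
}

#' Mean pairwise SSD of a set of volumes
#'
#' Convenience population-compactness measure: the mean of the `N(N-1)/2`
#' pairwise SSD values.
#'
#' @param images list of [hg_volume]s.
#' @return Scalar.
#' @export
mean_pairwise_ssd <- function(images) {
  d <- ssd_matrix(images)
  mean(d[upper.tri(d)])
}
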