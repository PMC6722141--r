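#' Configuration for stationary-velocity diffeomorphic demons
#'
#' @param iterations_per_level maximum update iterations per pyramid level.
#' @param fluid_sigma Gaussian sigma (voxels) applied to each update field
#'   before composition ("fluid" regularisation).
#' @param diffusion_sigma Gaussian sigma (voxels) applied to the velocity
#'   field after each update ("diffusion" regularisation).
#' @param step_cap maximum per-voxel update displacement (voxels); also the
#'   normalisation scale of the demons force denominator.
#' @param intensity_tolerance relative SSD improvement below which the
#'   iteration stops early.
#' @param pyramid_levels number of internal resolution levels (level `k`
#'   runs at downsampling factor `2^(k-1)`); warm-started calls skip the
#'   pyramid and refine at full resolution only.
#' @return A `demons_config` list.
#' @export
demons_config <- function(iterations_per_level = 30L, fluid_sigma = 1.0,
                          diffusion_sigma = 1.5, step_cap = 1.0,
                          intensity_tolerance = 2e-3, pyramid_levels = 2L) {
  if (iterations_per_level < 1) stop("iterations must be >= 1")
  if (fluid_sigma < 0 || diffusion_sigma < 0) stop("sigmas must be >= 0")
  if (step_cap <= 0) stop("step_cap must be > 0")
  structure(list(iterations_per_level = as.integer(iterations_per_level),
                 fluid_sigma = fluid_sigma,
                 diffusion_sigma = diffusion_sigma,
                 step_cap = step_cap,
                 intensity_tolerance = intensity_tolerance,
                 pyramid_levels = as.integer(pyramid_levels)),
            class = "demons_config")
}

#' Pairwise diffeomorphic demons registration (stationary velocity)
#'
#' Estimates a stationary velocity field `v` such that warping `moving` by
#' `exp(v)` approximates `fixed`. Each iteration computes the symmetric
#' demons force — the intensity difference normalised by the mean of the
#' fixed and warped-moving gradients — caps it at `step_cap` voxels,
#' fluid-smooths it, adds it to the velocity in the zeroth-order log-domain
#' approximation, and diffusion-smooths the velocity. Iteration stops early
#' once the relative SSD improvement falls below
#' `cfg$intensity_tolerance`.
#'
#' @param moving,fixed [hg_volume]s on one grid.
#' @param cfg a [demons_config].
#' @param init optional initial velocity [hg_field] (warm start).
#' @return A velocity [hg_field] with attribute `"ssd_trace"` (SSD after
#'   each accepted iteration, starting with the initial SSD) and attribute
#'   `"no_signal"` set when both images are gradient-free but unequal.
#' @export
demons_velocity <- function(moving, fixed, cfg = demons_config(),
                            init = NULL) {
  check_same_grid(moving, fixed)
  d <- grid_dim(moving)
  # cold start: coarse-to-fine internal pyramid; warm start: refine directly
  if (is.null(init) && cfg$pyramid_levels > 1 && min(d) >= 16) {
    nlev <- cfg$pyramid_levels
    while (min(d) / 2^(nlev - 1) < 8) nlev <- nlev - 1
    v <- NULL
    for (lv in rev(seq_len(nlev))) {
      f <- 2^(lv - 1)
      if (f > 1) {
        mv <- resample_image(moving, 1 / f)
        fx <- resample_image(fixed, 1 / f)
      } else {
        mv <- moving
        fx <- fixed
      }
      if (!is.null(v)) v <- resample_field(v, grid_dim(mv) / grid_dim(v))
      v <- demons_single_level(mv, fx, cfg, v)
    }
    return(v)
  }
  demons_single_level(moving, fixed, cfg, init)
}

demons_single_level <- function(moving, fixed, cfg, init = NULL) {
  d <- grid_dim(moving)
  gfix <- cpp_gradient(fixed$data)
  v <- if (is.null(init)) array(0, dim = c(d, 3L)) else init$vectors
  flat <- max(abs(gfix)) == 0 && max(abs(cpp_gradient(moving$data))) == 0
  if (flat) {
    out <- hg_field(array(0, dim = c(d, 3L)), moving$spacing, moving$affine,
                    kind = "velocity")
    if (any(moving$data != fixed$data)) {
      warning("flat images with unequal intensities: no demons signal")
      attr(out, "no_signal") <- TRUE
    }
    attr(out, "ssd_trace") <- ssd(moving, fixed)
    return(out)
  }
  warped <- moving$data
  ssd_cur <- sum((warped - fixed$data)^2)
  if (!is.null(init) && cpp_max_magnitude(v) > 0) {
    # accept the warm start only if it actually brings the images closer
    vf <- new_field(v, moving$spacing, moving$affine, kind = "velocity")
    warped_init <- cpp_warp_trilinear(moving$data,
                                      exponentiate_velocity(vf)$vectors)
    ssd_init <- sum((warped_init - fixed$data)^2)
    if (ssd_init < ssd_cur) {
      warped <- warped_init
      ssd_cur <- ssd_init
    } else {
      v <- array(0, dim = c(d, 3L))
    }
  }
  trace <- ssd_cur
  for (it in seq_len(cfg$iterations_per_level)) {
    gwarp <- cpp_gradient(warped)
    u <- cpp_demons_force(fixed$data, warped, gfix, gwarp, cfg$step_cap)
    if (cfg$fluid_sigma > 0) u <- cpp_gaussian_smooth(u, cfg$fluid_sigma)
    v_new <- v + u
    if (cfg$diffusion_sigma > 0)
      v_new <- cpp_gaussian_smooth(v_new, cfg$diffusion_sigma)
    phi <- exponentiate_velocity(
      new_field(v_new, moving$spacing, moving$affine, kind = "velocity"))
    warped_new <- cpp_warp_trilinear(moving$data, phi$vectors)
    ssd_new <- sum((warped_new - fixed$data)^2)
    if (ssd_new > ssd_cur) break        # regularised step no longer helps
    improved <- (ssd_cur - ssd_new) / max(ssd_cur, .Machine$double.eps)
    v <- v_new
    warped <- warped_new
    ssd_cur <- ssd_new
    trace <- c(trace, ssd_cur)
    if (improved < cfg$intensity_tolerance) break
  }
  out <- hg_field(v, moving$spacing, moving$affine, kind = "velocity")
  attr(out, "ssd_trace") <- trace
  out
}

#' Edge velocities of a labeled graph
#'
#' Runs one pairwise demons registration per undirected edge `{i, j}`
#' (computed in the `i < j` direction) between the current warped vertex
#' images; the reverse velocity is the antisymmetric `v_ji = -v_ij`. The
#' returned map covers exactly the graph's edge set, keyed `"i-j"` with
#' `i < j`.
#'
#' @param warped_images list of [hg_volume]s indexed by image index (the
#'   current warped images; only the graph's vertices are accessed).
#' @param graph an `hg_graph`.
#' @param cfg a [demons_config].
#' @param warm optional previous edge-velocity map used as warm starts.
#' @param counter optional environment with a numeric `calls` field,
#'   incremented once per pairwise registration (used for efficiency
#'   accounting).
#' @return Named list of velocity [hg_field]s, one per undirected edge.
#' @export
edge_velocities <- function(warped_images, graph, cfg = demons_config(),
                            warm = NULL, counter = NULL) {
  out <- list()
  if (nrow(graph$edges) == 0) return(out)
  for (r in seq_len(nrow(graph$edges))) {
    i <- graph$edges[r, 1]
    j <- graph$edges[r, 2]
    key <- paste0(i, "-", j)
    init <- if (!is.null(warm)) warm[[key]] else NULL
    v <- demons_velocity(warped_images[[i]], warped_images[[j]], cfg,
                         init = init)
    if (!is.null(counter)) counter$calls <- counter$calls + 1
    out[[key]] <- v
  }
  out
}

# Velocity on the directed edge i -> j from the undirected store.
edge_velocity_of <- function(velocities, i, j) {
  if (i < j) return(velocities[[paste0(i, "-", j)]])
  v <- velocities[[paste0(j, "-", i)]]
  if (is.null(v)) return(NULL)
  new_field(-v$vectors, v$spacing, v$affine, kind = "velocity")
}
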