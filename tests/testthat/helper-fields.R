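# Shared fixtures: all synthetic, built in code at test time.

# Smooth random velocity field with a centred Gaussian window, so that the
# field decays well inside the grid (as demons fields do over an object) and
# its flow never interacts with the grid boundary. `max_mag` in voxels.
smooth_test_field <- function(n = 32, max_mag = 2, sigma = n / 4.5,
                              seed = 1) {
  set.seed(seed)
  d <- c(n, n, n)
  ax <- seq_len(n) - (n + 1) / 2
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  dim(r2) <- d
  w <- exp(-r2 / (2 * (n / 4)^2))
  a <- hgshrink:::cpp_gaussian_smooth(array(stats::rnorm(prod(d) * 3),
                                            dim = c(d, 3L)), 0.22 * n)
  for (cc in 1:3) a[, , , cc] <- a[, , , cc] * w
  m <- hgshrink:::cpp_max_magnitude(a)
  hg_field(a * (max_mag / m), kind = "velocity")
}

# Smooth random scalar image on an n^3 grid, intensities roughly in [0, 100].
smooth_test_image <- function(n = 16, seed = 1) {
  set.seed(seed)
  a <- hgshrink:::cpp_gaussian_smooth(array(stats::runif(n^3) * 100,
                                            dim = c(n, n, n)), 2)
  hg_volume(a)
}

# Gaussian blob of width `sd` voxels centred at `centre` (offset from the
# grid midpoint), peak intensity 100.
blob_volume <- function(n = 32, centre = c(0, 0, 0), sd = 4) {
  ax <- seq_len(n) - (n + 1) / 2
  r2 <- outer(outer((ax - centre[1])^2, (ax - centre[2])^2, "+"),
              (ax - centre[3])^2, "+")
  dim(r2) <- c(n, n, n)
  hg_volume(100 * exp(-r2 / (2 * sd^2)))
}

# "Images" that are single voxels holding one scalar each: SSD between two
# such images is the squared scalar difference, which makes similarity and
# clustering behaviour hand-checkable.
scalar_images <- function(values) {
  lapply(values, function(v) hg_volume(array(v, dim = c(1, 1, 1))))
}

# Constant displacement/velocity field on an n^3 grid.
constant_field <- function(n, u, kind = "displacement") {
  a <- array(0, dim = c(n, n, n, 3))
  for (cc in 1:3) a[, , , cc] <- u[cc]
  hg_field(a, kind = kind)
}

# Forward-Euler integration of a stationary velocity field (independent
# oracle for the scaling-and-squaring exponential).
euler_flow <- function(v, steps = 256) {
  u <- v$vectors * 0
  h <- 1 / steps
  for (s in seq_len(steps))
    u <- hgshrink:::cpp_compose_fields(u, v$vectors * h)
  hg_field(u)
}

# Reference trilinear warp written as plain R loops (zero background),
# independent of the C++ kernel.
warp_oracle <- function(img, field) {
  d <- dim(img$data)
  out <- array(0, dim = d)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    p <- c(x, y, z) + field$vectors[x, y, z, ]
    p0 <- floor(p)
    f <- p - p0
    acc <- 0
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      q <- p0 + c(dx, dy, dz)
      if (all(q >= 1) && all(q <= d)) {
        w <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
        acc <- acc + w * img$data[q[1], q[2], q[3]]
      }
    }
    out[x, y, z] <- acc
  }
  hg_volume(out)
}

# Small phantom population for pipeline tests (cheap: 32^3 or smaller).
small_population <- function(seed = 1, n = 32, n_clusters = 2,
                             images_per_cluster = 3, inter = 3, intra = 1,
                             noise = 1) {
  generate_population(phantom_spec(grid_size = n, n_clusters = n_clusters,
                                   images_per_cluster = images_per_cluster,
                                   inter_mag = inter, intra_mag = intra,
                                   smoothness = n / 8, noise_sigma = noise,
                                   seed = seed))
}
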