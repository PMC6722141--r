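test_that("identity warp returns the image unchanged", {
  img <- smooth_test_image(12, seed = 2)
  out <- warp_image(img, identity_field(img))
  expect_identical(out$data, img$data)
})

test_that("constant field translates an impulse the expected way", {
  img <- hg_volume(array(0, dim = c(9, 9, 9)))
  img$data[6, 5, 5] <- 1
  out <- warp_image(img, constant_field(9, c(1, 0, 0)))
  # pull-back: out(x) = img(x + 1) so the impulse appears one voxel lower
  expect_equal(out$data[5, 5, 5], 1)
  expect_equal(sum(out$data), 1)
})

test_that("warp matches a brute-force interpolation oracle", {
  img <- smooth_test_image(12, seed = 4)
  f <- smooth_test_field(n = 12, max_mag = 2, seed = 5)
  got <- warp_image(img, f)
  ref <- warp_oracle(img, f)
  expect_lt(max(abs(got$data - ref$data)),
            1e-6 * diff(range(img$data)))
  expect_error(warp_image(img, identity_field(hg_volume(
    array(0, dim = c(8, 8, 8))))), "grid mismatch")
})

test_that("composition has the identity element and adds translations", {
  f <- smooth_test_field(n = 12, max_mag = 1.5, seed = 6)
  id <- identity_field(hg_volume(array(0, dim = c(12, 12, 12))))
  expect_identical(compose_fields(id, f)$vectors, f$vectors)
  expect_identical(compose_fields(f, id)$vectors, f$vectors)
  a <- constant_field(12, c(1, -0.5, 0.25))
  b <- constant_field(12, c(0.5, 0.5, -0.25))
  comp <- compose_fields(b, a)
  interior <- comp$vectors[4:9, 4:9, 4:9, ]
  expect_equal(max(abs(interior - rep(c(1.5, 0, 0),
                                      each = 6^3))), 0, tolerance = 1e-12)
})

test_that("warping by a composition equals sequential warping", {
  img <- blob_volume(24, centre = c(2, -1, 0), sd = 5)
  f <- smooth_test_field(n = 24, max_mag = 1.5, seed = 7)
  g <- smooth_test_field(n = 24, max_mag = 1.5, seed = 8)
  seq2 <- warp_image(warp_image(img, f), g)
  comp <- warp_image(img, compose_fields(g, f))
  expect_lt(max(abs(seq2$data - comp$data)),
            3e-2 * diff(range(img$data)))
})

test_that("exponential of zero velocity is identity, of constant velocity a translation", {
  z <- hg_field(array(0, dim = c(10, 10, 10, 3)), kind = "velocity")
  expect_identical(exponentiate_velocity(z, 1)$vectors, z$vectors)
  u <- constant_field(16, c(1.7, -0.4, 0.9), kind = "velocity")
  phi <- exponentiate_velocity(u, 0.8)
  interior <- phi$vectors[5:12, 5:12, 5:12, ]
  expect_equal(interior,
               array(rep(0.8 * c(1.7, -0.4, 0.9), each = 8^3),
                     dim = c(8, 8, 8, 3)),
               tolerance = 1e-12)
  expect_error(exponentiate_velocity(u, 0), "positive")
})

test_that("scaling-and-squaring agrees with a 256-step Euler flow oracle", {
  for (seed in 1:2) {
    v <- smooth_test_field(n = 32, max_mag = 2, seed = seed)
    ss <- exponentiate_velocity(v, 1)
    eu <- euler_flow(v, 256)
    expect_lt(hgshrink:::cpp_max_magnitude(ss$vectors - eu$vectors), 0.05)
  }
})

test_that("exp(v) composed with exp(-v) is near identity and diffeomorphic", {
  v <- smooth_test_field(n = 32, max_mag = 1, seed = 11)
  fw <- exponentiate_velocity(v, 1)
  bw <- exponentiate_velocity(hg_field(-v$vectors, kind = "velocity"), 1)
  expect_lt(hgshrink:::cpp_max_magnitude(
    compose_fields(fw, bw)$vectors), 0.1)
  big <- exponentiate_velocity(smooth_test_field(n = 32, max_mag = 2,
                                                 seed = 12), 1)
  expect_gt(min(jacobian_determinant(big)), 0)
})

test_that("field resampling preserves physical displacement", {
  id <- identity_field(hg_volume(array(0, dim = c(8, 8, 8))))
  up <- resample_field(id, 2)
  expect_true(all(up$vectors == 0))
  expect_identical(dim(up$vectors)[1:3], c(16L, 16L, 16L))
  cf <- constant_field(8, c(0.5, -1, 2))
  up <- resample_field(cf, 2)
  expect_equal(as.vector(up$vectors[8, 8, 8, ]), c(1, -2, 4),
               tolerance = 1e-12)
  f <- smooth_test_field(n = 32, max_mag = 2, seed = 13)
  rt <- resample_field(resample_field(f, 0.5), 2)
  rel_rms <- sqrt(mean((rt$vectors - f$vectors)^2)) /
    sqrt(mean(f$vectors^2))
  expect_lt(rel_rms, 0.1)
  expect_error(resample_field(f, 0.01), "degenerate")
})
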