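box_mask <- function(n, from, to, label = 1) {
  a <- array(0, dim = c(n, n, n))
  a[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- label
  hg_labels(a)
}

test_that("dice matches hand-countable cases", {
  m <- box_mask(8, c(2, 2, 2), c(3, 3, 3))
  expect_equal(dice(m, m, 1), 1)
  disjoint <- box_mask(8, c(6, 6, 6), c(7, 7, 7))
  expect_equal(dice(m, disjoint, 1), 0)
  # |A| = 4, |B| = 4, overlap 2 -> 0.5
  a <- hg_labels(array(c(rep(1, 4), rep(0, 4)), dim = c(8, 1, 1)))
  b <- hg_labels(array(c(0, 0, 1, 1, 1, 1, 0, 0), dim = c(8, 1, 1)))
  expect_equal(dice(a, b, 1), 0.5)
  # absent label is flagged, never silently perfect
  expect_true(is.na(dice(m, m, 9)))
  # symmetry on random masks
  set.seed(14)
  for (rep in 1:5) {
    x <- hg_labels(array(sample(0:2, 64, replace = TRUE), dim = c(4, 4, 4)))
    y <- hg_labels(array(sample(0:2, 64, replace = TRUE), dim = c(4, 4, 4)))
    for (l in 1:2) expect_equal(dice(x, y, l), dice(y, x, l))
  }
})

test_that("weighted overall dice is a size-weighted mean", {
  expect_equal(weighted_overall_dice(
    data.frame(dice = c(0.7, 0.7, 0.7), size = c(1, 5, 20))), 0.7)
  expect_equal(weighted_overall_dice(
    data.frame(dice = c(1, 0), size = c(3, 1))), 0.75)
  expect_equal(weighted_overall_dice(
    data.frame(dice = c(0.2, 0.4, 0.9), size = c(2, 2, 2))),
    mean(c(0.2, 0.4, 0.9)))
  expect_equal(weighted_overall_dice(
    data.frame(dice = c(0.5, NA), size = c(2, 99))), 0.5)
  expect_error(weighted_overall_dice(
    data.frame(dice = NA_real_, size = 1)), "undefined")
})

test_that("majority vote takes the modal label with smallest-label ties", {
  one <- box_mask(4, c(1, 1, 1), c(2, 2, 2))
  expect_identical(majority_vote(list(one))$labels, one$labels)
  two <- box_mask(4, c(1, 1, 1), c(2, 2, 2), label = 2)
  vote <- majority_vote(list(one, one, two))
  expect_equal(vote$labels[1, 1, 1], 1)        # votes {1,1,2} -> 1
  tie <- majority_vote(list(one, two))
  expect_equal(tie$labels[1, 1, 1], 1)         # votes {1,2} -> smaller label
  bg_tie <- majority_vote(list(one, box_mask(4, c(3, 3, 3), c(4, 4, 4))))
  expect_equal(bg_tie$labels[1, 1, 1], 0)      # votes {1,0} -> background
})

test_that("degenerate generator settings reproduce the template exactly", {
  spec <- phantom_spec(grid_size = 16, n_clusters = 1,
                       images_per_cluster = 3, inter_mag = 0, intra_mag = 0,
                       noise_sigma = 0, seed = 5)
  pop <- generate_population(spec)
  for (img in pop$images)
    expect_equal(img$data, pop$template$data, tolerance = 1e-12)
  for (m in pop$label_masks)
    expect_identical(m$labels, pop$template_labels$labels)
})

test_that("generated displacements respect the magnitude bound", {
  pop <- small_population(seed = 6, n = 24, inter = 3, intra = 1)
  for (f in pop$truth$fields)
    expect_lte(field_max_magnitude(f), 1.5 * (3 + 1))
  expect_error(phantom_spec(n_clusters = 2, inter_mag = 1, intra_mag = 2),
               "intra_mag")
})

test_that("inverting the true deformation recovers the template labels", {
  # standard benchmark conditions: at 64^3 the ROI surfaces are resolved
  # well enough that the double nearest-neighbour resampling stays mild
  pop <- standard_population(0)
  labs <- sort(setdiff(unique(as.vector(pop$template_labels$labels)), 0))
  for (i in seq_along(pop$images)[1:4]) {
    inv <- exponentiate_velocity(
      hg_field(-pop$truth$velocities[[i]]$vectors, kind = "velocity"))
    back <- warp_labels(pop$label_masks[[i]], inv)
    per_label <- data.frame(
      dice = vapply(labs, function(l)
        dice(back, pop$template_labels, l), numeric(1)),
      size = vapply(labs, function(l)
        sum(pop$template_labels$labels == l), numeric(1)))
    expect_gte(weighted_overall_dice(per_label), 0.95)
  }
})

test_that("evaluation reports have the expected structure", {
  pop <- small_population(seed = 4, n = 24, n_clusters = 1,
                          images_per_cluster = 3, inter = 2, intra = 1,
                          noise = 0)
  rep0 <- evaluate_run(NULL, pop$label_masks)
  n_labels <- length(setdiff(unique(as.vector(
    rep0$group_labels$labels)), 0))
  expect_equal(nrow(rep0$per_image), 3 * (n_labels + 1))
  expect_true(all(rep0$per_image$dice >= 0 & rep0$per_image$dice <= 1,
                  na.rm = TRUE))
  # identical masks => perfect agreement with their vote
  same <- list(pop$label_masks[[1]], pop$label_masks[[1]],
               pop$label_masks[[1]])
  rep1 <- evaluate_run(NULL, same)
  expect_equal(rep1$overall, 1)
  tmp <- withr::local_tempdir()
  write_report(rep0, tmp)
  expect_true(file.exists(file.path(tmp, "dice_report.csv")))
  expect_true(file.exists(file.path(tmp, "report.json")))
})
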