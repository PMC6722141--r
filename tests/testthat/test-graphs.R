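test_that("single-vertex graphs get the label floor", {
  g <- build_graph(7L, matrix(0, 1, 1))
  expect_equal(nrow(g$edges), 0)
  expect_equal(unname(g$labels), 1L)
  expect_error(build_graph(integer(0), matrix(0, 0, 0)), "empty")
})

test_that("MST plus kNN reproduces the hand-worked collinear case", {
  # three 1-voxel images with values {0, 1, 3}
  d <- as.matrix(stats::dist(c(0, 1, 3)))^2
  g <- build_graph(1:3, d, k = 1)
  expect_equal(g$edges, cbind(c(1, 2), c(2, 3)))
  expect_equal(unname(g$labels), c(1L, 2L, 1L))
})

test_that("graphs are connected with bounded edge count for random distances", {
  set.seed(10)
  for (rep in 1:10) {
    n <- sample(3:12, 1)
    k <- sample(1:3, 1)
    x <- matrix(stats::rnorm(n * 3), n)
    d <- as.matrix(stats::dist(x))^2
    g <- build_graph(seq_len(n), d, k = k)
    expect_lte(nrow(g$edges), n - 1 + k * n)
    ig <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
    expect_true(igraph::is_connected(ig))
    expect_true(all(g$edges[, 1] < g$edges[, 2]))   # no self loops / dups
    expect_equal(nrow(unique(g$edges)), nrow(g$edges))
    expect_equal(unname(g$labels),
                 pmax(tabulate(as.vector(g$edges), nbins = n), 1L))
  }
})

test_that("graph set overrides exemplar labels with the child's total degree", {
  # two planted groups of 3 collinear values each; leaves become path graphs
  vals <- c(0, 1, 3, 100, 101, 103)
  d <- as.matrix(stats::dist(vals))^2
  tr <- build_cluster_tree(scalar_images(vals), max_cluster_size = 3)
  gs <- assemble_graph_set(tr, d, k = 1)
  kinds <- vapply(gs$graphs, `[[`, character(1), "kind")
  expect_equal(sort(unname(kinds)), c("inter", "intra", "intra"))
  inter <- gs$graphs[[which(kinds == "inter")]]
  intras <- gs$graphs[kinds == "intra"]
  # a path graph of 3 has degrees (1,2,1): total degree 4 becomes the
  # exemplar's label in the parent graph
  for (ig in intras) {
    expect_equal(sort(unname(ig$labels)), c(1L, 2L, 1L)[order(c(1, 2, 1))])
    expect_equal(unname(inter$labels[as.character(ig$exemplar)]),
                 2L * nrow(ig$edges))
  }
  # bottom-level vertices partition the population
  bottom <- unlist(lapply(intras, `[[`, "vertices"))
  expect_setequal(bottom, 1:6)
})

test_that("single-cluster trees give a one-graph set", {
  vals <- c(0, 1, 2)
  tr <- build_cluster_tree(scalar_images(vals), max_cluster_size = 5)
  gs <- assemble_graph_set(tr, as.matrix(stats::dist(vals))^2, k = 1)
  expect_length(gs$graphs, 1)
  expect_equal(gs$graphs[[1]]$kind, "intra")
})

test_that("a larger label slows the averaged velocity proportionally", {
  # exemplar with label 4 and two neighbours pulling with equal constant
  # velocity u: the average is u/2, half what a plain degree-2 average gives
  n <- 6
  g <- list(vertices = 1:3,
            edges = cbind(c(1, 1), c(2, 3)),
            labels = stats::setNames(c(4L, 1L, 1L), 1:3),
            kind = "intra", level = 1L)
  class(g) <- "hg_graph"
  u <- c(0.8, 0, 0)
  vel <- list("1-2" = constant_field(n, u, kind = "velocity"),
              "1-3" = constant_field(n, u, kind = "velocity"))
  vhat <- averaged_velocity(1, vel, g)
  expect_equal(vhat$vectors, constant_field(n, u / 2)$vectors,
               tolerance = 1e-12)
  g$labels[["1"]] <- 8L   # doubling the label halves the averaged velocity
  vhat2 <- averaged_velocity(1, vel, g)
  expect_equal(vhat2$vectors * 2, vhat$vectors, tolerance = 1e-12)
})

test_that("graph-set JSON and DOT serialisations are well formed", {
  vals <- c(0, 1, 3, 50, 51, 53)
  tr <- build_cluster_tree(scalar_images(vals), max_cluster_size = 3)
  gs <- assemble_graph_set(tr, as.matrix(stats::dist(vals))^2, k = 1)
  js <- jsonlite::fromJSON(graph_set_to_json(gs), simplifyVector = FALSE)
  expect_length(js$graphs, 3)
  dot <- graph_to_dot(gs$graphs[[1]])
  expect_match(dot, "graph intra_1 \\{")
})
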