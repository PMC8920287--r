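test_that("spatial graph construction dedups, sorts and validates", {
  g <- spatial_graph(rbind(c("A", "B")))
  expect_identical(g$nodes, c("A", "B"))
  expect_equal(n_edges(g), 1L)
  expect_equal(g$lengths, 1)

  # unordered duplicate collapses
  g2 <- spatial_graph(rbind(c("A", "B"), c("B", "A")))
  expect_equal(n_edges(g2), 1L)

  # orientation is always lexicographic tail -> head
  g3 <- spatial_graph(rbind(c("Z", "A"), c("B", "A")))
  expect_identical(g3$tails, c("A", "A"))
  expect_identical(g3$heads, c("Z", "B"))

  expect_error(spatial_graph(rbind(c("A", "A"))), "self-loop")
  expect_error(spatial_graph(rbind(c("A", "B")), lengths = 0), "positive")
  expect_error(spatial_graph(rbind(c("A", "B")), lengths = -1), "positive")
  expect_error(spatial_graph(matrix(character(0), 0, 2)), "empty")
})

test_that("graphs rebuild exactly from their own edge lists", {
  set.seed(11)
  for (i in 1:20) {
    g <- random_connected_graph(sample(3:12, 1), p = 0.4,
                                random_lengths = TRUE)
    g2 <- spatial_graph(cbind(g$tails, g$heads), g$lengths)
    expect_identical(g2, g)
  }
})

test_that("largest-component restriction keeps the right nodes", {
  g <- spatial_graph(rbind(c("A", "B"), c("C", "D")))
  # equal-size components: tie broken towards the lexicographically
  # smallest member
  r <- restrict_to_largest_component(g, c("A", "B", "C", "D"))
  expect_identical(r$nodes, c("A", "B"))

  g2 <- spatial_graph(rbind(c("A", "B"), c("B", "C"), c("D", "E")))
  r2 <- restrict_to_largest_component(g2)
  expect_identical(r2$nodes, c("A", "B", "C"))
  expect_true(is_connected_graph(r2))

  expect_error(restrict_to_largest_component(g, "Z"), "no overlap")
})

test_that("largest-component restriction is idempotent", {
  set.seed(7)
  for (i in 1:10) {
    g <- random_connected_graph(sample(4:10, 1), p = 0.3)
    keep <- sample(g$nodes, max(2, floor(0.7 * n_nodes(g))))
    r1 <- tryCatch(restrict_to_largest_component(g, keep),
                   error = function(e) NULL)
    if (is.null(r1)) next
    expect_identical(restrict_to_largest_component(r1, r1$nodes), r1)
  }
})

test_that("incidence matrix has the +1/-1 column structure", {
  g <- spatial_graph(rbind(c("A", "B")))
  D <- incidence_matrix(g)
  expect_equal(unname(D[, 1]), c(1, -1))

  p <- spatial_graph(rbind(c("A", "B"), c("B", "C")))
  Dp <- incidence_matrix(p)
  expect_equal(dim(Dp), c(3L, 2L))
  expect_equal(unname(colSums(Dp)), c(0, 0))
  expect_true(all(colSums(Dp == 1) == 1 & colSums(Dp == -1) == 1))

  # layer graphs share the operator
  F <- layer_graph(c("expression", "cnv"), preset = "pair")
  expect_equal(unname(colSums(incidence_matrix(F))), 0)
})

test_that("layer-graph presets produce the study topologies", {
  two <- layer_graph(c("expression", "cnv"), preset = "pair")
  expect_equal(length(two$tails), 1L)

  # three layers: expression is the hub, no CNV-methylation edge
  three <- layer_graph(c("expression", "cnv", "methylation"),
                       preset = "expression-star")
  expect_equal(length(three$tails), 2L)
  pairs <- paste(three$tails, three$heads)
  expect_true(all(grepl("expression", pairs)))
  expect_false(any(grepl("cnv.*methylation|methylation.*cnv", pairs)))

  one <- layer_graph("expression")
  expect_equal(length(one$tails), 0L)

  expect_error(layer_graph(c("a", "a"), preset = "pair"), "unique")
  expect_error(layer_graph(c("a", "b"), connections = list(c("a", "zz"))),
               "unknown layer")
})

test_that("super-graph satisfies the product counting identities", {
  G <- spatial_graph(rbind(c("A", "B")))
  F <- layer_graph(c("x", "y"), connections = list(c("x", "y")))
  sg <- build_super_graph(G, F, gamma = 0.5)
  expect_equal(n_nodes(sg), 4L)
  expect_equal(n_edges(sg), 2L + 2L)

  set.seed(23)
  for (i in 1:10) {
    G <- random_connected_graph(sample(3:9, 1), p = 0.4)
    m <- sample(1:3, 1)
    F <- random_layer_graph(m)
    sg <- build_super_graph(G, F, gamma = 2)
    expect_equal(n_nodes(sg), n_nodes(G) * m)
    expect_equal(n_edges(sg), n_edges(G) * m + n_nodes(G) * length(F$tails))
  }

  # no layer edges: m disjoint copies of G
  F0 <- layer_graph(c("x", "y"), connections = list())
  sg0 <- build_super_graph(G, F0, gamma = 1)
  expect_equal(n_edges(sg0), n_edges(G) * 2L)
  expect_false(is_connected_graph(sg0))

  # gamma = 0 keeps zero-length cross-layer edges
  Fp <- layer_graph(c("x", "y"), preset = "pair")
  sgz <- build_super_graph(G, Fp, gamma = 0)
  expect_true(any(sgz$lengths == 0))
  expect_error(build_super_graph(G, Fp, gamma = -1), "nonnegative")
})
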