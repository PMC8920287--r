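delta <- function(g, at) {
  setNames(as.numeric(g$nodes == at), g$nodes)
}

test_that("scalar W1 on small graphs matches forced-path values", {
  two <- spatial_graph(rbind(c("A", "B")))
  expect_equal(w1_graph(delta(two, "A"), delta(two, "B"), two), 1)
  expect_equal(w1_graph(delta(two, "A"), delta(two, "A"), two), 0)

  path <- spatial_graph(rbind(c("A", "B"), c("B", "C")))
  expect_equal(w1_graph(delta(path, "A"), delta(path, "C"), path), 2)

  # edge lengths are the unit costs
  wpath <- spatial_graph(rbind(c("A", "B"), c("B", "C")), c(0.5, 3))
  expect_equal(w1_graph(delta(wpath, "A"), delta(wpath, "C"), wpath), 3.5)

  expect_error(
    w1_graph(c(A = 1, B = 0), c(A = 0.5, B = 0.4), two), "masses differ")
  disc <- structure(list(nodes = c("A", "B", "C", "D"),
                         tails = c("A", "C"), heads = c("B", "D"),
                         lengths = c(1, 1)), class = "spatial_graph")
  expect_error(w1_graph(c(1, 0, 0, 0), c(0, 0, 1, 0), disc), "infeasible")
})

test_that("flow solutions satisfy divergence and objective identities", {
  set.seed(71)
  for (i in 1:25) {
    g <- random_connected_graph(sample(4:10, 1), p = 0.4,
                                random_lengths = TRUE)
    r0 <- random_probability(n_nodes(g))
    r1 <- random_probability(n_nodes(g))
    sol <- w1_graph(r0, r1, g, details = TRUE)
    expect_lt(sol$residual, 1e-8)
    expect_equal(sol$objective, sum(g$lengths * abs(sol$flux)),
                 tolerance = 1e-9)
  }
})

test_that("vector W1 prices pure cross-layer moves at gamma", {
  G <- spatial_graph(rbind(c("A", "B")))
  F <- layer_graph(c("x", "y"), preset = "pair")
  # all mass at gene A; move it from layer x to layer y
  rho0 <- matrix(c(1, 0, 0, 0), 2, 2, dimnames = list(c("A", "B"),
                                                      c("x", "y")))
  rho1 <- matrix(c(0, 0, 1, 0), 2, 2, dimnames = list(c("A", "B"),
                                                      c("x", "y")))
  expect_equal(w1_vector(rho0, rho1, G, F, gamma = 0.5), 0.5)
  expect_equal(w1_vector(rho0, rho1, G, F, gamma = 3), 3)
  expect_equal(w1_vector(rho0, rho0, G, F, gamma = 1), 0)

  sol <- w1_vector(rho0, rho1, G, F, gamma = 0.5, details = TRUE)
  expect_lt(sol$residual, 1e-8)
  expect_equal(unname(sol$w["A", "x--y"]), 1)
  expect_equal(unname(sol$u["A--B", ]), c(0, 0), tolerance = 1e-12)

  expect_error(w1_vector(rho0, rho1, G, F, gamma = -0.1), "nonnegative")
})

test_that("vector W1 equals scalar W1 on the weighted super-graph", {
  set.seed(101)
  for (i in 1:20) {
    G <- random_connected_graph(sample(3:8, 1), p = 0.5,
                                random_lengths = TRUE)
    F <- random_layer_graph(sample(1:3, 1))
    gamma <- sample(c(0.5, 1, 2), 1)
    rho0 <- random_vd(G, F)
    rho1 <- random_vd(G, F)
    dv <- w1_vector(rho0, rho1, G, F, gamma)
    super <- build_super_graph(G, F, gamma)
    ds <- w1_graph(as_super_marginal(rho0, super),
                   as_super_marginal(rho1, super), super)
    expect_equal(dv, ds, tolerance = 1e-6)
  }
})

test_that("free cross-layer flow collapses layers to the scalar problem", {
  set.seed(113)
  for (i in 1:10) {
    G <- random_connected_graph(sample(3:8, 1), p = 0.5)
    F <- random_layer_graph(sample(2:3, 1))
    rho0 <- random_vd(G, F)
    rho1 <- random_vd(G, F)
    d0 <- w1_vector(rho0, rho1, G, F, gamma = 0)
    dsum <- w1_graph(rowSums(rho0), rowSums(rho1), G)
    expect_equal(d0, dsum, tolerance = 1e-6)
  }
})

test_that("vector W1 is non-decreasing in the cross-layer cost", {
  set.seed(127)
  for (i in 1:8) {
    G <- random_connected_graph(6, p = 0.4)
    F <- random_layer_graph(2)
    rho0 <- random_vd(G, F)
    rho1 <- random_vd(G, F)
    d <- vapply(c(0, 0.5, 1, 2, 10),
                function(g) w1_vector(rho0, rho1, G, F, g), numeric(1))
    expect_true(all(diff(d) >= -1e-9))
  }
})

test_that("distances are invariant to edge orientation and scale linearly", {
  set.seed(131)
  for (i in 1:10) {
    g <- random_connected_graph(sample(4:9, 1), p = 0.4,
                                random_lengths = TRUE)
    r0 <- random_probability(n_nodes(g))
    r1 <- random_probability(n_nodes(g))
    d <- w1_graph(r0, r1, g)
    # shuffling the edge list redraws every internal orientation
    perm <- sample(n_edges(g))
    flip <- sample(c(TRUE, FALSE), n_edges(g), replace = TRUE)
    e2 <- cbind(ifelse(flip, g$heads, g$tails),
                ifelse(flip, g$tails, g$heads))[perm, , drop = FALSE]
    g2 <- spatial_graph(e2, g$lengths[perm])
    expect_equal(w1_graph(setNames(r0, g$nodes), setNames(r1, g$nodes), g2),
                 d, tolerance = 1e-9)
    # scaling every length by c scales the distance by c
    g3 <- spatial_graph(cbind(g$tails, g$heads), 2.5 * g$lengths)
    expect_equal(w1_graph(r0, r1, g3), 2.5 * d, tolerance = 1e-8)
  }
})

test_that("disconnected layer graphs demand balanced per-component mass", {
  G <- spatial_graph(rbind(c("A", "B")))
  F <- layer_graph(c("x", "y"), connections = list())
  bal0 <- matrix(c(0.5, 0, 0, 0.5), 2, 2,
                 dimnames = list(c("A", "B"), c("x", "y")))
  bal1 <- matrix(c(0, 0.5, 0.5, 0), 2, 2,
                 dimnames = list(c("A", "B"), c("x", "y")))
  expect_equal(w1_vector(bal0, bal1, G, F, gamma = 1), 1)

  unb0 <- matrix(c(0.8, 0, 0, 0.2), 2, 2,
                 dimnames = list(c("A", "B"), c("x", "y")))
  expect_error(w1_vector(unb0, bal1, G, F, gamma = 1), "unequal mass")
})

test_that("pairwise distance matrix is consistent, symmetric and ordered", {
  set.seed(139)
  G <- random_connected_graph(7, p = 0.5)
  F <- layer_graph(c("x", "y"), preset = "pair")
  samples <- replicate(5, random_vd(G, F), simplify = FALSE)
  names(samples) <- paste0("s", 1:5)
  D <- pairwise_distance_matrix(samples, G, F, gamma = 1)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 5))
  expect_true(all(D >= 0))
  expect_equal(D["s2", "s4"],
               w1_vector(samples$s2, samples$s4, G, F, gamma = 1),
               tolerance = 1e-9)
  # identical samples give a zero matrix
  same <- samples[c(1, 1, 1)]
  names(same) <- paste0("t", 1:3)
  expect_lt(max(pairwise_distance_matrix(same, G, F)), 1e-10)
  # worker count does not change the result
  D4 <- pairwise_distance_matrix(samples, G, F, gamma = 1, workers = 2L)
  expect_equal(D4, D, tolerance = 1e-9)
})

test_that("the vector W1 behaves as a metric on random triples", {
  set.seed(149)
  for (i in 1:20) {
    G <- random_connected_graph(sample(3:7, 1), p = 0.5)
    F <- random_layer_graph(2)
    a <- random_vd(G, F)
    b <- random_vd(G, F)
    cc <- random_vd(G, F)
    dab <- w1_vector(a, b, G, F)
    dba <- w1_vector(b, a, G, F)
    expect_lt(w1_vector(a, a, G, F), 1e-10)
    expect_lt(abs(dab - dba), 1e-8)
    expect_lte(w1_vector(a, cc, G, F),
               dab + w1_vector(b, cc, G, F) + 1e-8)
  }
})
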