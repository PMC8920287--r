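# Fixture factories used across the suite.  Everything is generated in code
# under explicit seeds; no binary fixtures exist anywhere.

# random connected graph with n nodes, edge kept with probability p,
# optionally random lengths; falls back to adding a random spanning path
# when the draw is disconnected
random_connected_graph <- function(n, p = 0.5, random_lengths = FALSE) {
  stopifnot(n >= 2)
  el <- t(combn(n, 2))
  keep <- stats::runif(nrow(el)) < p
  # a random hamiltonian path guarantees connectivity
  perm <- sample(n)
  path <- cbind(perm[-n], perm[-1])
  el <- rbind(el[keep, , drop = FALSE], path)
  ids <- sprintf("n%02d", 1:n)
  lengths <- if (random_lengths) stats::runif(nrow(el), 0.2, 2) else NULL
  spatial_graph(cbind(ids[el[, 1]], ids[el[, 2]]), lengths)
}

random_probability <- function(n, names = NULL) {
  x <- stats::runif(n, 0.05, 1)
  x <- x / sum(x)
  if (!is.null(names)) names(x) <- names
  x
}

# random layer graph over m layers: random spanning tree plus extras,
# or disconnected when connected = FALSE and m > 1
random_layer_graph <- function(m, connected = TRUE) {
  layers <- paste0("L", seq_len(m))
  if (m == 1) return(layer_graph(layers))
  if (!connected) {
    if (m == 2) return(layer_graph(layers, connections = list()))
    return(layer_graph(layers,
                       connections = list(c(layers[1], layers[2]))))
  }
  perm <- sample(m)
  conns <- lapply(seq_len(m - 1),
                  function(i) c(layers[perm[i]], layers[perm[i + 1]]))
  layer_graph(layers, connections = conns)
}

# random vector-valued distribution on (G, F) with total mass 1
random_vd <- function(G, F) {
  m <- length(F$layers)
  per_layer <- lapply(F$layers, function(l) {
    random_probability(n_nodes(G), names = G$nodes)
  })
  names(per_layer) <- F$layers
  vector_distribution(per_layer, F)
}
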