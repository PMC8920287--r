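#' Preprocess one omics layer to strictly positive node weights
#'
#' The Markov-chain construction needs a strictly positive weight at every
#' node, so each omics type gets the minimal transform that guarantees it:
#' \describe{
#'   \item{expression}{left as-is, clipped below at `epsilon` (zeros occur in
#'     RNA-seq counts).}
#'   \item{cnv}{exponentiated elementwise, `base^x`, turning signed
#'     copy-number scores into positive weights (default natural base).}
#'   \item{methylation}{beta values in \[0, 1\] become `1 - beta` (methylation
#'     tends to suppress expression, so high methylation should mean low
#'     weight), clipped below at `epsilon`.}
#' }
#'
#' @param x numeric matrix, genes in rows, samples in columns, with dimnames.
#' @param kind one of `"expression"`, `"cnv"`, `"methylation"`.
#' @param epsilon positivity floor (default `1e-6`).
#' @param base base of the CNV exponentiation (default `exp(1)`).
#' @return Numeric matrix of the same shape, all entries `> 0`.
#' @export
preprocess_layer <- function(x, kind = c("expression", "cnv", "methylation"),
                             epsilon = 1e-6, base = exp(1)) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("omics matrix must be numeric")
  if (any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop("non-finite value at gene '", rownames(x)[bad[1L]],
         "', sample '", colnames(x)[bad[2L]], "'")
  }
  stopifnot(is.numeric(epsilon), epsilon > 0)
  out <- switch(kind,
    expression = pmax(x, epsilon),
    cnv = base^x,
    methylation = {
      if (any(x < 0 | x > 1)) {
        bad <- which(x < 0 | x > 1, arr.ind = TRUE)[1L, ]
        stop("methylation beta outside [0, 1] at gene '",
             rownames(x)[bad[1L]], "', sample '", colnames(x)[bad[2L]], "'")
      }
      pmax(1 - x, epsilon)
    }
  )
  out <- matrix(out, nrow(x), ncol(x), dimnames = dimnames(x))
  out
}

# neighbour weight sums S_i = sum_{k in N(i)} g_k; errors on isolated nodes
neighbor_sums <- function(graph, g) {
  g <- align_node_values(graph, g)
  ti <- match(graph$tails, graph$nodes)
  hi <- match(graph$heads, graph$nodes)
  s <- as.vector(tapply(c(g[hi], g[ti]), factor(c(ti, hi),
                        levels = seq_len(n_nodes(graph))), sum))
  s[is.na(s)] <- 0
  if (any(s == 0)) {
    stop("isolated node '", graph$nodes[which(s == 0)[1L]],
         "' has no neighbors")
  }
  s
}

align_node_values <- function(graph, g) {
  if (!is.null(names(g))) {
    if (!setequal(names(g), graph$nodes)) {
      stop("names of node values do not match the graph's nodes")
    }
    g <- g[graph$nodes]
  } else if (length(g) != n_nodes(graph)) {
    stop("need one value per node (", n_nodes(graph), ")")
  }
  as.numeric(g)
}

#' Random-walk transition matrix from node weights
#'
#' The walk at node *i* steps to neighbour *j* with probability proportional
#' to the neighbour's weight: \eqn{p_{ij} = g_j / \sum_{k \in N(i)} g_k}.
#'
#' @param graph a connected `spatial_graph`.
#' @param g strictly positive node weights (named, or in node order).
#' @return Row-stochastic matrix with the graph's node order on both axes.
#' @export
transition_matrix <- function(graph, g) {
  g <- align_node_values(graph, g)
  if (any(g <= 0)) stop("node weights must be strictly positive")
  s <- neighbor_sums(graph, g)
  n <- n_nodes(graph)
  p <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
  ti <- match(graph$tails, graph$nodes)
  hi <- match(graph$heads, graph$nodes)
  p[cbind(ti, hi)] <- g[hi] / s[ti]
  p[cbind(hi, ti)] <- g[ti] / s[hi]
  p
}

#' Stationary distribution of the weighted random walk (closed form)
#'
#' For the walk of [transition_matrix()] the stationary distribution is
#' \eqn{\pi_i \propto g_i \sum_{k \in N(i)} g_k}; it satisfies detailed
#' balance \eqn{\pi_i p_{ij} = g_i g_j / Z}. This is the invariant measure
#' used to place each sample's omics values on the network: it blends a
#' gene's own weight with its neighbourhood, and is invariant to rescaling
#' all weights, which removes the scale differences between omics types.
#'
#' @inheritParams transition_matrix
#' @return Probability vector named by node, summing to one.
#' @export
stationary_distribution <- function(graph, g) {
  g <- align_node_values(graph, g)
  if (any(g <= 0)) stop("node weights must be strictly positive")
  s <- neighbor_sums(graph, g)
  pi <- g * s
  setNames(pi / sum(pi), graph$nodes)
}

#' Stationary distribution by lazy power iteration
#'
#' Iterates \eqn{\pi^{t+1} = \pi^t (I + p)/2} from the uniform distribution
#' until the L1 change drops below `tol`. The lazy half-step makes the chain
#' aperiodic (bipartite graphs included) without changing its stationary
#' distribution. Serves as an independent cross-check of the closed form of
#' [stationary_distribution()].
#'
#' @inheritParams transition_matrix
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration cap.
#' @return Probability vector named by node.
#' @export
stationary_by_iteration <- function(graph, g, tol = 1e-13,
                                    max_iter = 100000L) {
  p <- transition_matrix(graph, g)
  n <- nrow(p)
  lazy <- (diag(n) + p) / 2
  pi <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    nxt <- as.vector(pi %*% lazy)
    if (sum(abs(nxt - pi)) < tol) {
      return(setNames(nxt / sum(nxt), graph$nodes))
    }
    pi <- nxt
  }
  stop("power iteration did not converge within ", max_iter,
       " steps (residual ", format(sum(abs(nxt - pi))), ")")
}

#' Assemble per-layer measures into a vector-valued distribution
#'
#' Stacks one probability vector per omics layer into a genes x layers mass
#' array and divides by the number of layers, so the joint total mass is
#' exactly one. Layers share mass equally.
#'
#' @param per_layer named list (or list in layer order) of probability
#'   vectors, one per layer of `F`, each named by gene and summing to one.
#' @param F a `layer_graph`.
#' @return A `vector_distribution`: nonnegative matrix (genes x layers) with
#'   total mass 1, genes sorted in spatial-graph node order.
#' @export
vector_distribution <- function(per_layer, F) {
  stopifnot(inherits(F, "layer_graph"))
  m <- length(F$layers)
  if (length(per_layer) != m) {
    stop("need ", m, " per-layer measures, got ", length(per_layer))
  }
  if (!is.null(names(per_layer))) {
    if (!setequal(names(per_layer), F$layers)) {
      stop("per-layer names do not match the layer graph")
    }
    per_layer <- per_layer[F$layers]
  }
  genes <- names(per_layer[[1L]])
  if (is.null(genes)) stop("per-layer measures must be named by gene")
  mat <- matrix(0, length(genes), m, dimnames = list(genes, F$layers))
  for (j in seq_len(m)) {
    v <- per_layer[[j]]
    if (!setequal(names(v), genes)) {
      stop("layer '", F$layers[j], "' is on a different gene set")
    }
    v <- v[genes]
    if (any(v < 0)) stop("layer '", F$layers[j], "' has negative mass")
    if (abs(sum(v) - 1) > 1e-9) {
      stop("layer '", F$layers[j], "' does not sum to 1 (got ",
           format(sum(v)), ")")
    }
    mat[, j] <- v
  }
  mat <- mat / m
  structure(mat, class = c("vector_distribution", "matrix", "array"))
}

#' Invariant measures for every sample of a multi-layer dataset
#'
#' For each sample, computes the stationary distribution of the weighted
#' random walk on `graph` separately in every (preprocessed, strictly
#' positive) omics layer, and stacks them into one `vector_distribution`.
#'
#' @param graph a connected `spatial_graph`.
#' @param layers named list of positive genes x samples matrices, one per
#'   layer of `F`, all with identical gene and sample sets.
#' @param F a `layer_graph` whose layer names match `names(layers)`.
#' @return Named list of `vector_distribution`s, one per sample.
#' @export
invariant_measures <- function(graph, layers, F) {
  stopifnot(inherits(graph, "spatial_graph"), inherits(F, "layer_graph"))
  if (!setequal(names(layers), F$layers)) {
    stop("layer matrices do not match the layer graph")
  }
  layers <- layers[F$layers]
  samples <- colnames(layers[[1L]])
  for (nm in F$layers) {
    if (!identical(colnames(layers[[nm]]), samples)) {
      stop("sample columns of layer '", nm, "' do not match")
    }
  }
  # precompute: pi = g * S(g) needs only neighbor sums per sample
  out <- lapply(samples, function(s) {
    per_layer <- lapply(F$layers, function(nm) {
      g <- layers[[nm]][, s]
      names(g) <- rownames(layers[[nm]])
      stationary_distribution(graph, g)
    })
    names(per_layer) <- F$layers
    vector_distribution(per_layer, F)
  })
  names(out) <- samples
  out
}
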