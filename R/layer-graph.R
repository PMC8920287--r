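#' Build the layer graph connecting omics types
#'
#' The layer graph \eqn{F = (V_F, E_F)} has one node per omics layer; an edge
#' permits direct mass transfer between two layers at the same gene, at cost
#' `gamma` per unit mass in the vector-valued transport problem. Two presets
#' cover the usual study designs:
#' \describe{
#'   \item{`"pair"`}{two layers joined by a single edge.}
#'   \item{`"expression-star"`}{three layers in which the first (hub) layer,
#'     conventionally gene expression, is connected to each of the other two,
#'     with no edge between those two. This encodes the biological reading
#'     that copy number and methylation each act on expression but not
#'     directly on one another.}
#' }
#'
#' @param layers character vector of unique layer names, in the order used
#'   for the columns of every vector-valued distribution.
#' @param connections optional two-column matrix / list of layer-name pairs
#'   giving explicit edges; overrides `preset`.
#' @param preset `"pair"` or `"expression-star"`; ignored when `connections`
#'   is given. A single layer needs neither (the scalar case, zero edges).
#' @return An object of class `layer_graph` with fields `layers`, `tails`,
#'   `heads` (tail precedes head in layer order).
#' @examples
#' layer_graph(c("expression", "cnv"), preset = "pair")
#' layer_graph(c("expression", "cnv", "methylation"),
#'             preset = "expression-star")
#' @export
layer_graph <- function(layers, connections = NULL, preset = NULL) {
  layers <- as.character(layers)
  if (anyDuplicated(layers)) stop("layer names must be unique")
  if (length(layers) == 0L) stop("at least one layer is required")

  if (is.null(connections)) {
    if (is.null(preset)) {
      if (length(layers) == 1L) {
        connections <- matrix(character(0), 0, 2)
      } else {
        stop("give explicit connections or a preset for >1 layer")
      }
    } else {
      preset <- match.arg(preset, c("pair", "expression-star"))
      connections <- switch(preset,
        "pair" = {
          if (length(layers) != 2L) stop("preset 'pair' needs 2 layers")
          matrix(layers, 1, 2)
        },
        "expression-star" = {
          if (length(layers) != 3L) {
            stop("preset 'expression-star' needs 3 layers")
          }
          rbind(c(layers[1L], layers[2L]), c(layers[1L], layers[3L]))
        }
      )
    }
  } else {
    if (is.list(connections) && !is.data.frame(connections)) {
      connections <- do.call(rbind, lapply(connections, as.character))
    }
    if (is.null(connections) || length(connections) == 0L) {
      connections <- matrix(character(0), 0, 2)
    }
    connections <- as.matrix(connections)
    if (ncol(connections) != 2L) {
      stop("connections must be pairs of layer names")
    }
    storage.mode(connections) <- "character"
  }

  if (nrow(connections)) {
    unknown <- setdiff(as.vector(connections), layers)
    if (length(unknown)) {
      stop("unknown layer name(s) in connections: ",
           paste(unknown, collapse = ", "))
    }
    if (any(connections[, 1L] == connections[, 2L])) {
      stop("self-loop in layer connections")
    }
    # orient each edge by layer order; drop duplicates (unordered)
    i1 <- match(connections[, 1L], layers)
    i2 <- match(connections[, 2L], layers)
    tails <- layers[pmin(i1, i2)]
    heads <- layers[pmax(i1, i2)]
    keep <- !duplicated(paste(tails, heads, sep = "\r"))
    tails <- tails[keep]
    heads <- heads[keep]
  } else {
    tails <- heads <- character(0)
  }

  structure(list(layers = layers, tails = tails, heads = heads),
            class = "layer_graph")
}

#' @export
print.layer_graph <- function(x, ...) {
  cat("<layer_graph> layers: ", paste(x$layers, collapse = ", "), "\n", sep = "")
  if (length(x$tails)) {
    cat("  edges: ", paste(x$tails, x$heads, sep = "--", collapse = ", "),
        "\n", sep = "")
  } else cat("  edges: none\n")
  invisible(x)
}

# connected components of the layer graph as a list of layer-name vectors;
# used to check feasibility of the vector transport problem
layer_components <- function(F) {
  if (length(F$layers) == 1L) return(list(F$layers))
  ig <- igraph::graph_from_data_frame(
    data.frame(from = F$tails, to = F$heads),
    directed = FALSE, vertices = F$layers
  )
  comp <- igraph::components(ig)
  unname(split(F$layers, comp$membership))
}

#' Build the weighted super-graph of a spatial and a layer graph
#'
#' The product construction on which the vector-valued W1 distance reduces to
#' an ordinary scalar W1: one copy of the gene network per layer (edges keep
#' their original lengths) plus, for every gene, a copy of the layer graph
#' whose edges get length `gamma`. Node ids are `gene@layer`. With
#' `gamma = 0` the cross-layer edges are free; they are retained with length
#' zero.
#'
#' @param G a `spatial_graph`.
#' @param F a `layer_graph`.
#' @param gamma nonnegative cross-layer cost per unit mass.
#' @return A `spatial_graph` over the product node set, satisfying
#'   `n_nodes = n_nodes(G) * n_layers` and
#'   `n_edges = n_edges(G) * n_layers + n_nodes(G) * n_edges(F)`.
#' @export
build_super_graph <- function(G, F, gamma = 1) {
  stopifnot(inherits(G, "spatial_graph"), inherits(F, "layer_graph"))
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma < 0) {
    stop("gamma must be a single nonnegative number")
  }
  if (any(grepl("@", c(G$nodes, F$layers), fixed = TRUE))) {
    stop("gene and layer names must not contain '@'")
  }
  m <- length(F$layers)
  sp_tails <- paste0(rep(G$tails, m), "@", rep(F$layers, each = n_edges(G)))
  sp_heads <- paste0(rep(G$heads, m), "@", rep(F$layers, each = n_edges(G)))
  sp_len <- rep(G$lengths, m)
  la_tails <- if (length(F$tails)) {
    paste0(rep(G$nodes, length(F$tails)), "@",
           rep(F$tails, each = n_nodes(G)))
  } else character(0)
  la_heads <- if (length(F$heads)) {
    paste0(rep(G$nodes, length(F$heads)), "@",
           rep(F$heads, each = n_nodes(G)))
  } else character(0)
  la_len <- rep(gamma, length(la_tails))
  sg <- new_spatial_graph(
    cbind(c(sp_tails, la_tails), c(sp_heads, la_heads)),
    c(sp_len, la_len),
    allow_zero = TRUE
  )
  # isolated product nodes cannot occur: every G node meets a spatial edge
  sg
}

#' Flatten a vector-valued distribution onto super-graph node order
#'
#' @param vd a `vector_distribution` (genes x layers matrix).
#' @param super a super-graph built from the same `G` and `F`.
#' @return Named numeric vector aligned with `super$nodes`.
#' @export
as_super_marginal <- function(vd, super) {
  flat <- setNames(
    as.vector(vd),
    paste0(rep(rownames(vd), ncol(vd)), "@", rep(colnames(vd), each = nrow(vd)))
  )
  if (!setequal(names(flat), super$nodes)) {
    stop("distribution does not match the super-graph's node set")
  }
  flat[super$nodes]
}
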