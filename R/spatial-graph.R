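#' Build an undirected gene-interaction graph
#'
#' Constructs the spatial graph \eqn{G = (V_G, E_G)} on which per-sample
#' distributions live. Edges are undirected; duplicates (in either order) are
#' collapsed, node identifiers are sorted lexicographically so that
#' distribution vectors from different code paths align, and every edge is
#' stored with the lexicographically smaller endpoint as its tail. The
#' orientation is pure bookkeeping for the flux variables of the transport
#' solver; all distances are invariant to it.
#'
#' @param edges two-column character matrix or data frame of node-id pairs.
#' @param lengths optional positive edge lengths aligned with `edges`
#'   (recycled if length one); default 1 for every edge, i.e. an unweighted
#'   interaction network.
#' @return An object of class `spatial_graph`: a list with `nodes` (sorted
#'   character vector), `tails`, `heads` (character, per edge) and `lengths`.
#' @examples
#' g <- spatial_graph(rbind(c("TP53", "MDM2"), c("MDM2", "TP53")))
#' n_edges(g) # duplicates collapse to one undirected edge
#' @export
spatial_graph <- function(edges, lengths = NULL) {
  edges <- as.matrix(edges)
  if (nrow(edges) == 0L) stop("edge list is empty")
  if (ncol(edges) != 2L) stop("edges must have exactly two columns")
  storage.mode(edges) <- "character"
  if (anyNA(edges)) stop("edge list contains missing node ids")
  if (any(edges[, 1L] == edges[, 2L])) {
    bad <- edges[edges[, 1L] == edges[, 2L], 1L][1L]
    stop("self-loop at node '", bad, "' is not allowed")
  }
  if (is.null(lengths)) lengths <- rep(1, nrow(edges))
  lengths <- rep_len(as.numeric(lengths), nrow(edges))
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("edge lengths must all be positive and finite")
  }
  new_spatial_graph(edges, lengths, allow_zero = FALSE)
}

# Internal constructor; allow_zero permits zero-length edges, used only for
# the cross-layer edges of a super-graph at gamma = 0.
new_spatial_graph <- function(edges, lengths, allow_zero = FALSE) {
  if (allow_zero && any(lengths < 0)) stop("edge lengths must be >= 0")
  tails <- pmin(edges[, 1L], edges[, 2L])
  heads <- pmax(edges[, 1L], edges[, 2L])
  key <- paste(tails, heads, sep = "\r")
  keep <- !duplicated(key)
  g <- structure(
    list(
      nodes = sort(unique(c(tails, heads))),
      tails = unname(tails[keep]),
      heads = unname(heads[keep]),
      lengths = unname(lengths[keep])
    ),
    class = "spatial_graph"
  )
  g
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat("<spatial_graph> ", n_nodes(x), " nodes, ", n_edges(x), " edges\n",
      sep = "")
  invisible(x)
}

#' Number of nodes / edges of a graph
#' @param graph a `spatial_graph` or `layer_graph`.
#' @return Integer count.
#' @export
n_nodes <- function(graph) {
  length(if (inherits(graph, "layer_graph")) graph$layers else graph$nodes)
}

#' @rdname n_nodes
#' @export
n_edges <- function(graph) length(graph$tails)

as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    data.frame(from = graph$tails, to = graph$heads),
    directed = FALSE,
    vertices = graph$nodes
  )
}

#' Test whether a spatial graph is connected
#' @param graph a `spatial_graph`.
#' @return Logical scalar.
#' @export
is_connected_graph <- function(graph) {
  n_nodes(graph) == 1L || igraph::is_connected(as_igraph(graph))
}

# adjacency list: integer node indices of the neighbours of each node
adjacency_list <- function(graph) {
  ti <- match(graph$tails, graph$nodes)
  hi <- match(graph$heads, graph$nodes)
  adj <- vector("list", n_nodes(graph))
  idx <- c(ti, hi)
  nbr <- c(hi, ti)
  split_idx <- split(nbr, factor(idx, levels = seq_len(n_nodes(graph))))
  for (i in seq_along(adj)) adj[[i]] <- split_idx[[i]]
  adj
}

#' Restrict a graph to the largest connected component of a gene set
#'
#' Takes the subgraph induced by `keep_genes` (intersected with the graph's
#' nodes) and returns its largest connected component, mirroring the usual
#' restriction of an interaction database to the genes actually measured.
#' Components of equal size are disambiguated by the lexicographically
#' smallest member node, so the result is reproducible.
#'
#' @param graph a `spatial_graph`.
#' @param keep_genes character vector of gene ids to retain; default all.
#' @return A connected `spatial_graph`.
#' @export
restrict_to_largest_component <- function(graph, keep_genes = NULL) {
  if (is.null(keep_genes)) keep_genes <- graph$nodes
  keep_genes <- unique(as.character(keep_genes))
  if (length(keep_genes) == 0L) stop("keep_genes is empty")
  present <- intersect(graph$nodes, keep_genes)
  if (length(present) == 0L) {
    stop("no overlap between keep_genes and the graph's nodes")
  }
  in_set <- graph$tails %in% present & graph$heads %in% present
  if (!any(in_set)) {
    stop("the induced subgraph on keep_genes has no edges")
  }
  sub <- new_spatial_graph(
    cbind(graph$tails[in_set], graph$heads[in_set]),
    graph$lengths[in_set]
  )
  comp <- igraph::components(as_igraph(sub))
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # tie: component containing the smallest node id
    firsts <- vapply(best, function(b) min(sub$nodes[comp$membership == b]),
                     character(1))
    best <- best[order(firsts)][1L]
  }
  members <- sub$nodes[comp$membership == best]
  keep_e <- sub$tails %in% members
  new_spatial_graph(cbind(sub$tails[keep_e], sub$heads[keep_e]),
                    sub$lengths[keep_e])
}

#' Signed incidence matrix of a graph
#'
#' The discrete divergence operator: one column per edge with +1 at the tail
#' row and -1 at the head row, rows in the graph's fixed node order. Every
#' column sums to zero, which is the algebraic form of mass conservation in
#' the flow formulation of the W1 distance.
#'
#' @param graph a `spatial_graph` or `layer_graph`.
#' @return A numeric matrix (#nodes x #edges) with row names (and, for
#'   spatial graphs, edge names `tail--head` as column names).
#' @export
incidence_matrix <- function(graph) {
  nodes <- if (inherits(graph, "layer_graph")) graph$layers else graph$nodes
  m <- matrix(0, length(nodes), length(graph$tails),
              dimnames = list(nodes, paste0(graph$tails, "--", graph$heads)))
  if (length(graph$tails)) {
    m[cbind(match(graph$tails, nodes), seq_along(graph$tails))] <- 1
    m[cbind(match(graph$heads, nodes), seq_along(graph$heads))] <- -1
  }
  m
}
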